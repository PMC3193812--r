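test_that("SNP caller enforces strict depth and fraction boundaries", {
  g <- genome_seq("t", strrep("ACGT", 100))
  mk <- function(pos, n) data.table::data.table(pos = pos, base = "T", n = n)
  depth <- rep(0L, 400)
  # depth 6, 5 alt (83.3%): called (5/6 > 0.8 and 6 > 5)
  depth[11] <- 6L
  s1 <- call_snps_from_pileup(mk(10L, 5L), depth, g)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$pos, 10L)
  expect_equal(s1$af, 5 / 6, tolerance = 1e-9)
  # depth 5, 5 alt: NOT called (depth not > 5)
  depth[11] <- 5L
  expect_equal(nrow(call_snps_from_pileup(mk(10L, 5L), depth, g)), 0L)
  # depth 10, 8 alt (exactly 80%): NOT called (fraction not > 0.8)
  depth[11] <- 10L
  expect_equal(nrow(call_snps_from_pileup(mk(10L, 8L), depth, g)), 0L)
  # depth 10, 9 alt: called
  expect_equal(nrow(call_snps_from_pileup(mk(10L, 9L), depth, g)), 1L)
  # masked position suppressed
  mask <- rep(FALSE, 400); mask[11] <- TRUE
  expect_equal(nrow(call_snps_from_pileup(mk(10L, 9L), depth, g,
                                          mask = mask)), 0L)
})

test_that("read-based SNP calling is exact on a panel accession", {
  mini <- get_mini()
  ref <- mini$sim$ref
  spec <- ecotype_panel_spec(n_ecotypes = 6L, n_groups = 2L,
                             stem_events = c("DEL", "NHEJ"),
                             n_terminal_events = 0L, coverage = 20)
  panel <- make_ecotype_panel(ref, spec, seed = 67L)
  mask <- ambiguity_mask(ref$truth, ref$genome$length)
  for (eco in names(panel$genomes)[1:3]) {
    lib <- simulate_panel_library(panel$genomes[[eco]], spec,
                                  seed = derive_seed(67L, 500L +
                                                       match(eco, names(panel$genomes))))
    pl <- map_reads(lib$pairs, ref$genome)
    snps <- call_snps(pl, lib$pairs, ref$genome, mask = mask)
    truth <- panel$snp_truth[ecotype == eco & !mask[pos + 1]]
    # exclude truth positions lost to this accession's deletions
    expect_setequal(snps$pos, truth$pos)
    m <- merge(snps, truth, by = "pos")
    expect_identical(m$alt.x, m$alt.y)
  }
})

test_that("SV classification recovers planted NHEJ/REC/DEL exactly", {
  mini <- get_mini()
  ref <- mini$sim$ref
  spec <- ecotype_panel_spec(n_ecotypes = 3L, n_groups = 3L,
                             stem_events = c("REC", "NHEJ", "DEL"),
                             n_terminal_events = 0L, coverage = 20)
  panel <- make_ecotype_panel(ref, spec, seed = 73L)
  mask <- ambiguity_mask(ref$truth, ref$genome$length)
  found <- find_repeat_pairs(ref$genome)
  confusion <- table(character(), character())
  for (eco in names(panel$genomes)) {
    truth_ev <- panel$sv_truth[grepl(paste0("(^|,)", eco, "(,|$)"),
                                     carriers)]
    lib <- simulate_panel_library(panel$genomes[[eco]], spec,
                                  seed = derive_seed(73L, 600L +
                                                       match(eco, names(panel$genomes))))
    pl <- map_reads(lib$pairs, ref$genome)
    depth <- coverage_track(pl, ref$genome)
    cd <- cluster_discordant(pl, ref$genome$length)
    sel <- filter_clusters(cd$clusters, require_libraries = "all",
                           wt_library = NA)
    svs <- classify_svs(sel, depth, found, ref$genome, mask = mask)
    svs <- svs[type %in% c("REC", "NHEJ", "DEL")]
    expect_equal(nrow(svs), nrow(truth_ev), info = eco)
    for (j in seq_len(nrow(truth_ev))) {
      tv <- truth_ev[j]
      hit <- svs[abs(svs$start - tv$start) <= 260 + 50]
      expect_equal(nrow(hit), 1L, info = paste(eco, tv$type))
      expect_equal(hit$type, tv$type)
      # coverage-based deletion sizing is exact up to junction bleed
      # (reads overhanging a breakpoint by <= the mismatch allowance)
      if (tv$type == "DEL") expect_lte(abs(hit$size - tv$size), 10)
      if (tv$type == "REC") {
        expect_false(is.na(hit$repeat_name))
        expect_lte(abs(hit$start - tv$start), 10)
      }
    }
  }
})

test_that("stoichiometry bands follow the expected-spanning-pairs scale", {
  # expected spanning pairs at median 200x: 200 * 148 / 72 ~ 411
  expect_equal(label_stoichiometry(2, 200), "substoichiometric")
  expect_equal(label_stoichiometry(411, 200), "predominant")
  expect_equal(label_stoichiometry(0.2 * 411, 200), "intermediate")
  # boundary: fraction exactly at the predominant threshold
  expect_equal(label_stoichiometry(0.5 * 200 * 148 / 72, 200),
               "predominant")
  expect_error(label_stoichiometry(5, 0), "positive")
})

test_that("TN93 distances match a closed-form oracle on a small case", {
  m <- rbind(a = c("A", "C", "G", "T", "A", "C", "G", "T", "A", "C"),
             b = c("A", "C", "G", "T", "A", "C", "G", "T", "G", "C"),
             c = c("A", "T", "G", "C", "A", "C", "G", "T", "G", "A"))
  dn <- ape::as.DNAbin(apply(tolower(m), c(1, 2), identity))
  d <- ape::dist.dna(dn, model = "TN93")
  # oracle for pair a-b: one transition (A<->G) in 10 sites
  p1 <- 1 / 10  # A<->G transitions
  # base frequencies over the whole alignment (the ape convention)
  fr <- table(factor(m, levels = c("A", "C", "G", "T"))) / length(m)
  gA <- fr[["A"]]; gC <- fr[["C"]]; gG <- fr[["G"]]; gT <- fr[["T"]]
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  oracle_ab <- -k1 * log(1 - p1 / k1) -
    2 * (gR * gY - 0) * log(1)  # no transversions, no C<->T transitions
  expect_equal(as.matrix(d)["a", "b"], oracle_ab, tolerance = 1e-8)
})

test_that("NJ recovers additive distances and canonicalises taxon order", {
  # additive 4-taxon metric: ((a,b),(c,d)) with internal edge 3
  D <- matrix(c(0, 2 + 2, 2 + 3 + 1, 2 + 3 + 2,
                4, 0, 2 + 3 + 1, 2 + 3 + 2,
                6, 6, 0, 1 + 2,
                7, 7, 3, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  D <- as.dist(pmax(D, t(D)))
  tr <- ape::nj(D)
  expect_true(ape::is.monophyletic(tr, c("a", "b")))
  expect_true(ape::is.monophyletic(tr, c("c", "d")))

  # build_phylogeny: input row order cannot change the result
  set.seed(9)
  base <- t(replicate(6, sample(c("A", "C", "G", "T"), 40, replace = TRUE)))
  base[2, 1:10] <- base[1, 1:10]
  rownames(base) <- sprintf("E%02d", 1:6)
  colnames(base) <- seq_len(ncol(base))
  p1 <- build_phylogeny(base, nboot = 10, seed = 1)
  p2 <- build_phylogeny(base[sample(6), ], nboot = 10, seed = 1)
  expect_equal(ape::write.tree(p1$tree), ape::write.tree(p2$tree))
  # distance matrix symmetric, zero diagonal, triangle inequality
  dm <- as.matrix(p1$dist)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)

  # identical accessions sit as zero-distance sisters
  base2 <- base; base2[3, ] <- base2[4, ]
  p3 <- build_phylogeny(base2, nboot = 0, seed = 1)
  expect_equal(as.matrix(p3$dist)["E03", "E04"], 0)

  # all-identical: star tree with a warning
  base3 <- matrix(rep(base[1, ], 4), 4, byrow = TRUE,
                  dimnames = list(sprintf("E%02d", 1:4), colnames(base)))
  expect_warning(p4 <- build_phylogeny(base3, nboot = 0), "star")
  expect_equal(length(p4$tree$tip.label), 4L)
})

test_that("group assignment cuts the longest internal edges", {
  tr <- ape::read.tree(
    text = "(((a:1,b:1):10,(c:1,d:1):10):1,((e:1,f:1):10,g:11):1);")
  g2 <- assign_groups(tr, k = 2L)
  expect_equal(length(unique(g2$group)), 2L)
  g1 <- assign_groups(tr, k = 1L)
  expect_equal(unique(g1$group), 1L)
  expect_error(assign_groups(tr, k = 99L), "exceeds")
  star <- ape::stree(5, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  expect_error(assign_groups(star, k = 3L), "star-like")
})

test_that("concordance report flags split events", {
  groups <- data.table::data.table(ecotype = sprintf("E%02d", 1:6),
                                   group = rep(1:2, each = 3))
  carriers <- data.table::data.table(
    event_id = c(1L, 1L, 1L, 2L, 3L, 3L),
    ecotype = c("E01", "E02", "E03",   # nested in group 1
                "E05",                 # single carrier
                "E01", "E04"))         # split across groups
  rep <- concordance_report(carriers, groups)
  expect_equal(rep$per_event$nested, c(TRUE, TRUE, FALSE))
  expect_equal(rep$per_event$fraction_in_modal[3], 0.5)
  expect_equal(rep$panel_concordance, 2 / 3)
})

test_that("SNP alignment export round-trips through FASTA", {
  m <- rbind(E01 = c("A", "C", "G"), E02 = c("A", "T", "G"))
  colnames(m) <- 1:3
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_snp_alignment(m, tmp)
  back <- read_fasta(tmp, circular = FALSE)
  expect_equal(vapply(back, `[[`, "", "name"), c("E01", "E02"))
  expect_equal(back[[2]]$sequence, "ATG")
  tmp2 <- withr::local_tempfile(fileext = ".phy")
  write_snp_alignment(m, tmp2, format = "phylip")
  expect_equal(readLines(tmp2)[1], "2 3")
})
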