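test_that("reference builder plants pairs at the target identity", {
  set.seed(1)
  # identical 100-bp pair: the two windows are equal strings
  cat1 <- repeat_spec("X", 100L, 100, fate_class = "I",
                      frac_gen1 = 0.3, frac_adv = 0.6)
  ref <- build_reference(20000L, cat1, seed = 3)
  r <- ref$truth[1]
  expect_identical(substr(ref$genome$sequence, r$start1 + 1, r$end1),
                   substr(ref$genome$sequence, r$start2 + 1, r$end2))

  # 86 bp at 96.5%: exactly round(86 * 0.035) = 3 mismatched columns,
  # verified by exhaustive global alignment
  cat2 <- repeat_spec("Y", 86L, 96.5, fate_class = "I",
                      frac_gen1 = 0.3, frac_adv = 0.6)
  ref2 <- build_reference(20000L, cat2, seed = 4)
  r2 <- ref2$truth[1]
  s1 <- substr(ref2$genome$sequence, r2$start1 + 1, r2$end1)
  s2 <- substr(ref2$genome$sequence, r2$start2 + 1, r2$end2)
  st <- mitorecomb:::align_stats(s1, s2, type = "global")
  expect_equal(st$mismatches, 3L)
  expect_equal(st$columns, 86L)
})

test_that("the packaged catalog matches the documented structure", {
  cat0 <- default_repeat_catalog()
  inter <- cat0[!is.na(cat0$fate_class)]
  expect_equal(nrow(inter), 47L)
  expect_equal(sum(inter$novel), 14L)
  expect_equal(range(inter$length), c(50L, 556L))
  expect_equal(range(inter[inter$novel == TRUE]$length), c(50L, 250L))
  expect_gte(min(inter$identity), 85)
  expect_equal(round(min(inter$identity)), 85)
  expect_lte(max(inter[inter$novel == TRUE]$identity), 98)
  # smallest novel repeats are the most identical
  nov <- inter[inter$novel == TRUE]
  expect_lt(cor(nov$length, nov$identity), -0.9)
  expect_true(any(cat0$length >= 1000))       # large identical pair
  expect_true(any(cat0$length < 50))          # decoys
  cc <- cat0[cat0$name == "CC"]
  expect_equal(cc$n_sub, 3L)
  expect_equal(cc$n_indels, 1L)
})

test_that("planted identity is recomputed within 0.5 points (property)", {
  mini <- get_mini()
  ref <- mini$sim$ref
  for (i in which(ref$truth$length >= 50)) {
    r <- ref$truth[i]
    s1 <- substr(ref$genome$sequence, r$start1 + 1, r$end1)
    s2 <- substr(ref$genome$sequence, r$start2 + 1, r$end2)
    st <- mitorecomb:::align_stats(s1, s2, type = "global")
    expect_lt(abs(st$identity - r$identity), 0.5)
  }
})

test_that("recombinant construction is asymmetric and donor-templated", {
  mini <- get_mini()
  ref <- mini$sim$ref
  expect_error(make_recombinant(ref, "ID1", product = "both"), "asymmetric")
  expect_error(make_recombinant(ref, "DEC"), "50-bp")
  expect_error(make_recombinant(ref, "nope"), "not in catalog")

  # identical pair: clean junction, flanks from recipient-up / donor-down
  m <- make_recombinant(ref, "ID1")
  r <- ref$truth[ref$truth$name == "ID1"]
  L <- ref$genome$length
  dc <- m$donor
  rc <- m$recipient
  r_start <- if (rc == 1) r$start1 else r$start2
  d_end <- if (dc == 1) r$end1 else r$end2
  expect_equal(substr(m$sequence, 1, m$flank_len),
               substr(ref$genome$sequence, r_start - m$flank_len + 1,
                      r_start))
  expect_equal(substr(m$sequence, m$repeat_start + m$repeat_len + 1,
                      m$repeat_start + m$repeat_len + m$flank_len),
               substr(ref$genome$sequence, d_end + 1, d_end + m$flank_len))

  # CC-like pair: repeat interval carries donor alleles at all sites
  mcc <- make_recombinant(ref, "CCX")
  rcc <- ref$truth[ref$truth$name == "CCX"]
  donor_seq <- substr(ref$genome$sequence,
                      (if (mcc$donor == 1) rcc$start1 else rcc$start2) + 1,
                      if (mcc$donor == 1) rcc$end1 else rcc$end2)
  expect_equal(substr(mcc$sequence, mcc$repeat_start + 1,
                      mcc$repeat_start + mcc$repeat_len), donor_seq)
  expect_equal(unique(mcc$site_origin$origin), "donor")
})

test_that("library simulation honours coverage, geometry and truth tags", {
  mini <- get_mini()
  sim <- mini$sim
  L <- sim$ref$genome$length
  lib <- sim$libraries$msh1_gen1
  total_bases <- 2 * 36 * nrow(lib$pairs)
  expect_lt(abs(total_bases / (50 * L) - 1), 0.05)

  # every read attributable to a molecule; insert sizes within bounds
  expect_true(all(lib$truth$molecule %in%
                    c("parental", sim$ref$truth$name)))
  expect_true(all(lib$truth$insert >= 72 & lib$truth$insert <= 300))

  # WT: zero junction-straddling pairs at fraction 0
  wt <- sim$libraries$WT
  expect_equal(sum(wt$truth$straddles), 0L)
  expect_true(all(wt$truth$molecule == "parental"))

  # recombinant fraction recovered from truth-tagged reads: straddling
  # pairs ~ f * lambda * E[(I - 2 rl)+] within 3 binomial sd
  tr <- lib$truth[lib$truth$molecule == "ID1"]
  r <- sim$ref$truth[sim$ref$truth$name == "ID1"]
  lam <- (50 * L / 72) / L
  expected <- r$frac_gen1 * lam * (220 - 72 - r$length)
  got <- sum(tr$straddles)
  expect_lt(abs(got - expected), 3 * sqrt(expected) + 1)
})

test_that("identical seed and spec give byte-identical FASTQ", {
  cat1 <- mini_catalog()
  cfg <- run_config(list(seed = 99L, genome_length = 30000L))
  s1 <- cmd_simulate(cfg, catalog = cat1)
  s2 <- cmd_simulate(cfg, catalog = cat1)
  expect_identical(s1$libraries$msh1_adv$pairs, s2$libraries$msh1_adv$pairs)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fastq(s1$libraries$WT, file.path(d1, "wt"))
  write_fastq(s2$libraries$WT, file.path(d2, "wt"))
  expect_identical(tools::md5sum(file.path(d1, "wt_1.fastq"))[[1]],
                   tools::md5sum(file.path(d2, "wt_1.fastq"))[[1]])
  # FASTQ round trip preserves pairs
  back <- read_fastq_pairs(file.path(d1, "wt_1.fastq"),
                           file.path(d1, "wt_2.fastq"))
  data.table::setorder(back, qname)
  orig <- data.table::copy(s1$libraries$WT$pairs)
  data.table::setorder(orig, qname)
  expect_equal(as.data.frame(back), as.data.frame(orig))
})

test_that("ecotype panel: per-branch SNPs, suppression, clade structure", {
  mini <- get_mini()
  ref <- mini$sim$ref
  spec <- ecotype_panel_spec(n_ecotypes = 12L, n_groups = 3L,
                             n_terminal_events = 3L)
  panel <- make_ecotype_panel(ref, spec, seed = 31L)
  expect_equal(length(panel$genomes), 12L)
  expect_setequal(unique(panel$groups$group), 1:3)
  # guide tree clades match group assignment
  for (g in 1:3)
    expect_true(ape::is.monophyletic(panel$tree,
                                     panel$groups[group == g, ecotype]))
  # every planted SNP is attributable: alt differs from ref base
  expect_true(all(panel$snp_truth$alt != panel$snp_truth$ref))
  # truth-table completeness: each event has carriers and coordinates
  expect_true(all(nchar(panel$sv_truth$carriers) > 0))
  expect_true(all(panel$sv_truth$size == panel$sv_truth$end -
                    panel$sv_truth$start))
  # genomes actually carry their deletions
  ev <- panel$sv_truth[1]
  carrier <- strsplit(ev$carriers, ",")[[1]][1]
  expect_equal(nchar(panel$genomes[[carrier]]$sequence),
               ref$genome$length -
                 sum(panel$sv_truth[grepl(paste0("(^|,)", carrier, "(,|$)"),
                                          carriers), size]) +
                 0L)
  # two-ecotype sanity: one SNP on one branch
  spec2 <- ecotype_panel_spec(n_ecotypes = 2L, n_groups = 2L,
                              stem_events = character(0)[0],
                              n_terminal_events = 0L)
  # with no events requested the truth table is empty and each genome
  # differs from the reference at exactly its planted SNP count
  panel2 <- make_ecotype_panel(ref, ecotype_panel_spec(
    n_ecotypes = 2L, n_groups = 2L, n_terminal_events = 0L,
    stem_events = "DEL", del_range = c(2L, 2L)), seed = 5L)
  for (eco in names(panel2$genomes)) {
    n_snp <- nrow(panel2$snp_truth[ecotype == eco])
    g_e <- panel2$genomes[[eco]]$sequence
    # compare against reference with this ecotype's deletions applied
    dels <- panel2$sv_truth[grepl(eco, carriers)]
    g_r <- ref$genome$sequence
    if (nrow(dels)) {
      data.table::setorder(dels, -start)
      for (i in seq_len(nrow(dels)))
        g_r <- paste0(substr(g_r, 1, dels$start[i]),
                      substr(g_r, dels$end[i] + 1, nchar(g_r)))
    }
    diffs <- sum(strsplit(g_e, "")[[1]] != strsplit(g_r, "")[[1]])
    expect_equal(diffs, n_snp, info = eco)
  }
})

test_that("SNP suppression inside the large repeat is ~66-fold (Poisson)", {
  # aggregate over several panels on a genome dominated by one large pair
  cat_l <- data.table::rbindlist(list(
    repeat_spec("BIG", 6500L, 100),
    repeat_spec("P1", 100L, 100, fate_class = "I",
                frac_gen1 = 0.3, frac_adv = 0.6)))
  ref <- build_reference(60000L, cat_l, seed = 9)
  spec <- ecotype_panel_spec(n_ecotypes = 6L, n_groups = 2L,
                             suppression = 66,
                             stem_events = "DEL", n_terminal_events = 0L)
  inside <- 0; outside <- 0
  big <- ref$truth[ref$truth$name == "BIG"]
  bigbp <- 2 * 6500; outbp <- 60000 - bigbp
  for (sd in 1:8) {
    p <- make_ecotype_panel(ref, spec, seed = sd)
    pos <- unique(p$snp_truth$pos)
    inb <- pos >= big$start1 & pos < big$end1 |
      pos >= big$start2 & pos < big$end2
    inside <- inside + sum(inb); outside <- outside + sum(!inb)
  }
  rate_out <- outside / outbp
  lambda_in <- rate_out * bigbp / 66 * 1  # expected if suppression holds
  # Poisson consistency: observed inside count within the central 99.9%
  expect_lte(inside, qpois(0.9995, lambda_in * 8))
  # and clearly below the unsuppressed expectation
  expect_lt(inside, 0.2 * rate_out * bigbp * 8)
})
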