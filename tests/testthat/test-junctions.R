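test_that("clustering groups junction pairs and keeps libraries aligned", {
  res <- get_mini_results()
  mini <- get_mini()
  sim <- mini$sim
  active_names <- sim$ref$truth[!is.na(fate_class), name]
  # one cluster per planted junction, none beyond
  sel <- res$selected
  expect_equal(nrow(sel), length(active_names))
  # cluster members are exactly recombinant-derived pairs (phasing
  # specificity)
  adv_truth <- sim$libraries$msh1_adv$truth
  mem <- merge(res$members[library == "msh1_adv"], adv_truth, by = "qname")
  expect_true(all(mem$molecule != "parental"))
  # support counts are per library on shared windows
  expect_true(all(c("support_WT", "support_msh1_gen1",
                    "support_msh1_adv") %in% names(sel)))
  expect_true(all(sel$support_WT == 0L))
  # zero discordant pairs in an error-free WT library: empty cluster set
  wt_only <- cluster_discordant(mini$placements$WT, sim$ref$genome$length)
  expect_equal(nrow(wt_only$clusters), 0L)
})

test_that("two junctions far apart form two clusters", {
  # constructed placements: two junction loci 50 kb apart
  mk <- function(qname, p1, p2)
    data.table::data.table(qname = qname, pos1 = p1, strand1 = "+",
                           mm1 = 0L, nbest1 = 1L, pos2 = p2,
                           strand2 = "-", mm2 = 0L, nbest2 = 1L,
                           span = NA_real_, circ_span = 5000,
                           concordance = "discordant", reason = "distance",
                           rescued1 = FALSE, rescued2 = FALSE)
  pl <- rbind(mk(sprintf("a%d", 1:15), 10000L + (1:15) * 3L, 15000L + (1:15) * 3L),
              mk(sprintf("b%d", 1:12), 60000L + (1:12) * 3L, 65000L + (1:12) * 3L))
  cl <- cluster_discordant(pl, 100000L)
  expect_equal(nrow(cl$clusters), 2L)
  expect_setequal(cl$clusters$support, c(15L, 12L))
})

test_that("support filter applies strict >10 after WT subtraction", {
  base <- data.table::data.table(
    cluster_id = 1:3, w1_start = c(1000L, 5000L, 9000L),
    w1_end = c(1200L, 5200L, 9200L), w2_start = c(20000L, 25000L, 29000L),
    w2_end = c(20200L, 25200L, 29200L), orientation = "+-",
    support = c(51L, 50L, 63L),
    support_WT = c(0L, 0L, 4L),
    support_msh1_gen1 = c(11L, 10L, 14L),
    support_msh1_adv = c(40L, 40L, 45L))
  sel <- filter_clusters(base)
  # {11, 40} kept; {10, 40} discarded (strict); {14-4, 45-4} = {10, 41}
  # discarded after subtraction
  expect_equal(sel$cluster_id, 1L)
  expect_equal(sel$net_support_msh1_gen1, 11L)
  expect_error(filter_clusters(base, require_libraries = "nope"),
               "no support column")
})

test_that("active set equals the planted set; WT-only yields nothing", {
  res <- get_mini_results()
  mini <- get_mini()
  tr <- mini$sim$ref$truth[!is.na(fate_class)]
  expect_equal(nrow(res$active), nrow(tr))
  for (i in seq_len(nrow(tr)))
    expect_equal(nrow(match_truth(res$active[i],
                                  data.table::as.data.table(tr))), 1L)
  expect_length(res$anomalies, 0)     # asymmetry faithfulness
  expect_equal(sum(res$assignments$call == "NHEJ-candidate"), 0L)

  # WT-only: no discordant clusters at all
  sim <- mini$sim
  wt_sim <- list(ref = sim$ref,
                 libraries = list(
                   WT = c(sim$libraries$WT,
                          list(placements = mini$placements$WT)),
                   msh1_gen1 = c(sim$libraries$WT,
                                 list(placements = mini$placements$WT)),
                   msh1_adv = c(sim$libraries$WT,
                                list(placements = mini$placements$WT))))
  res_wt <- cmd_recombination(wt_sim, sim$config)
  expect_equal(nrow(res_wt$active), 0L)
})

test_that("monotonicity: higher support thresholds select fewer repeats", {
  res <- get_mini_results()
  mini <- get_mini()
  found <- res$catalog
  sets <- lapply(c(5, 10, 25, 40), function(thr) {
    sel <- filter_clusters(res$clusters, min_support = thr)
    act <- call_active_repeats(sel, found, mini$sim$ref$genome)
    sort(act$active$name)
  })
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("planted NHEJ junction lands in the candidate list, not active", {
  # an accession genome with a pure NHEJ deletion, single-library mode
  mini <- get_mini()
  ref <- mini$sim$ref
  spec <- ecotype_panel_spec(n_ecotypes = 2L, n_groups = 2L,
                             stem_events = "NHEJ", n_terminal_events = 0L)
  panel <- make_ecotype_panel(ref, spec, seed = 41L)
  ev <- panel$sv_truth[type == "NHEJ"][1]
  eco <- strsplit(ev$carriers, ",")[[1]][1]
  lib <- simulate_panel_library(panel$genomes[[eco]], spec,
                                seed = derive_seed(41L, 300L))
  pl <- map_reads(lib$pairs, ref$genome)
  cl <- cluster_discordant(pl, ref$genome$length)
  sel <- filter_clusters(cl$clusters, require_libraries = "all",
                         wt_library = NA)
  expect_gte(nrow(sel), 1L)
  found <- find_repeat_pairs(ref$genome)
  act <- call_active_repeats(sel, found, ref$genome)
  expect_equal(nrow(act$active), 0L)
  expect_true(any(act$assignments$call == "NHEJ-candidate"))
})

test_that("reciprocal-product simulation raises the symmetry anomaly flag", {
  mini <- get_mini()
  sim <- mini$sim
  ref <- sim$ref
  # plant BOTH crossover products of ID1 (violating the asymmetric model)
  m1 <- make_recombinant(ref, "ID1", product = "primary")
  m2 <- make_recombinant(ref, "ID1", product = "reciprocal")
  spec <- library_spec("msh1_adv", coverage = 50)
  lib <- simulate_library(ref, list(m1, m2), spec, seed = 57L,
                          fractions = c(ID1 = 0.5))
  pl <- map_reads(lib$pairs, ref$genome)
  pl[, library := "msh1_adv"]
  plw <- data.table::copy(mini$placements$WT)
  plg <- data.table::copy(pl)[, library := "msh1_gen1"]
  cl <- cluster_discordant(rbind(plw, plg, pl), ref$genome$length)
  sel <- filter_clusters(cl$clusters)
  found <- find_repeat_pairs(ref$genome)
  act <- call_active_repeats(sel, found, ref$genome)
  r <- ref$truth[name == "ID1"]
  hit <- data.table::as.data.table(act$active)[abs(start1 - r$start1) <= 5]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$name %in% act$anomalies)
})

test_that("chained secondary junction is annotated as secondary", {
  mini <- get_mini()
  ref <- mini$sim$ref
  # build a chained molecule: the primary product of NI1 recombined again
  # at ID1 whose donor flank lies inside the new environment; emulate by
  # fusing the recipient-upstream flank of NI1 to the donor-downstream
  # flank of ID1 with a short spacer carrying both junctions in one
  # insert span
  r1 <- ref$truth[name == "NI1"]; r2 <- ref$truth[name == "ID1"]
  m1 <- make_recombinant(ref, "NI1")
  m2 <- make_recombinant(ref, "ID1")
  left <- substr(m1$sequence, 1, m1$repeat_start)        # NI1 recipient-up
  right <- substr(m2$sequence, m2$repeat_start + m2$repeat_len + 1,
                  nchar(m2$sequence))                    # ID1 donor-down
  chained <- list(name = "ID1", sequence = paste0(left, right),
                  donor = m2$donor, recipient = m1$recipient,
                  repeat_start = nchar(left), repeat_len = 0L,
                  flank_len = 400L, site_origin = NULL)
  spec <- library_spec("msh1_adv", coverage = 60)
  # ordinary products make NI1 and ID1 active; the chained molecule is
  # simulated separately (its reads renamed) and pooled
  lib_ord <- simulate_library(ref, list(m1, m2), spec, seed = 71L,
                              fractions = c(NI1 = 0.5, ID1 = 0.5))
  lib_ch <- simulate_library(ref, list(chained), spec, seed = 72L,
                             fractions = c(ID1 = 0.6))
  lib_ch$pairs[, qname := paste0("ch_", qname)]
  pl <- map_reads(rbind(lib_ord$pairs, lib_ch$pairs), ref$genome)
  pl[, library := "msh1_adv"]
  plg <- data.table::copy(pl)[, library := "msh1_gen1"]
  plw <- data.table::copy(mini$placements$WT)
  cl <- cluster_discordant(rbind(plw, plg, pl), ref$genome$length)
  sel <- filter_clusters(cl$clusters)
  found <- find_repeat_pairs(ref$genome)
  # make NI1 and ID1 active via the ordinary products plus the chained
  # cluster: the chained junction joins NI1-side and ID1-side windows
  act <- call_active_repeats(sel, found, ref$genome)
  expect_true(any(act$assignments$call == "secondary"))
})

test_that("circle-plot table mirrors windows and support", {
  res <- get_mini_results()
  tab <- cluster_circle_table(res$selected)
  expect_equal(nrow(tab), nrow(res$selected))
  expect_equal(tab$radius, res$selected$support)
  expect_equal(tab$x, (res$selected$w1_start + res$selected$w1_end) / 2)
})
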