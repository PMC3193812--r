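# Shared fixtures, built once per test run and memoised.  All fixtures
# are generated in code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# compact catalog: mixes short identical, long nonidentical, a CC-like
# worked-example pair, an inactive large pair and a decoy
mini_catalog <- function() {
  data.table::rbindlist(list(
    repeat_spec("ID1", 100L, 100, fate_class = "I", donor = 1L,
                frac_gen1 = 0.32, frac_adv = 0.65),
    repeat_spec("ID2", 120L, 100, fate_class = "II", donor = 2L,
                frac_gen1 = 0.30, frac_adv = 0.45),
    repeat_spec("NI1", 200L, 96, fate_class = "I", donor = 2L,
                frac_gen1 = 0.32, frac_adv = 0.68),
    repeat_spec("CCX", 200L, 100 * 197 / 201, n_indels = 1L,
                fate_class = "I", donor = 1L,
                frac_gen1 = 0.32, frac_adv = 0.65),
    repeat_spec("NI2", 300L, 94, fate_class = "II", donor = 1L,
                frac_gen1 = 0.30, frac_adv = 0.42),
    repeat_spec("DEC", 40L, 100)))
}

mini_sim <- function(seed = 11L, coverage = 50) {
  cfg <- run_config(list(seed = seed, genome_length = 30000L,
                         coverage_wt = coverage, coverage_gen1 = coverage,
                         coverage_adv = coverage))
  cmd_simulate(cfg, catalog = mini_catalog())
}

get_mini <- function() fixture("mini", function() {
  sim <- mini_sim()
  placements <- lapply(names(sim$libraries), function(cond) {
    p <- map_reads(sim$libraries[[cond]]$pairs, sim$ref$genome)
    p[, library := cond]
    p
  })
  names(placements) <- names(sim$libraries)
  list(sim = sim, placements = placements)
})

get_mini_results <- function() fixture("mini_results", function() {
  mini <- get_mini()
  sim <- mini$sim
  for (cond in names(sim$libraries))
    sim$libraries[[cond]]$placements <- mini$placements[[cond]]
  cmd_recombination(sim, sim$config)
})

# deep-coverage fixture for polarity / fate recovery (flank statistics
# need a few hundred pairs per region; see the methods vignette)
fate_catalog <- function() {
  # short repeats (robust junction support at any fraction), graded
  # recombinant fractions so the gain/loss gradient is visible
  fg1 <- c(0.25, 0.30, 0.32, 0.35); fa1 <- c(0.55, 0.65, 0.70, 0.75)
  fg2 <- c(0.20, 0.22, 0.25, 0.27); fa2 <- c(0.40, 0.42, 0.45, 0.48)
  rows <- list()
  for (j in 1:4) {
    rows[[2 * j - 1]] <- repeat_spec(
      sprintf("FI%d", j), c(80L, 88L, 96L, 104L)[j],
      identity = if (j > 2) 96 else 100, fate_class = "I",
      donor = if (j %% 2L) 1L else 2L, frac_gen1 = fg1[j],
      frac_adv = fa1[j])
    rows[[2 * j]] <- repeat_spec(
      sprintf("FII%d", j), c(80L, 96L, 112L, 128L)[j],
      identity = if (j > 2) 96 else 100, fate_class = "II",
      donor = if (j %% 2L) 2L else 1L, frac_gen1 = fg2[j],
      frac_adv = fa2[j])
  }
  data.table::rbindlist(rows)
}

get_fate_run <- function() fixture("fate_run", function() {
  cfg <- run_config(list(seed = 23L, genome_length = 25000L,
                         coverage_wt = 240, coverage_gen1 = 240,
                         coverage_adv = 240))
  sim <- cmd_simulate(cfg, catalog = fate_catalog())
  res <- cmd_recombination(sim, cfg)
  list(sim = sim, res = res)
})

# truth table keyed the way tests want it: coordinate-frame donor copy
truth_with_coord_donor <- function(ref) {
  tr <- data.table::copy(ref$truth)
  tr[, donor_coord := ifelse(copy1_is_spec_copy1, donor, 3L - donor)]
  tr
}

# match an active-catalog row to a truth row by interval identity
match_truth <- function(active_row, truth) {
  truth[abs(truth$start1 - active_row$start1) <= 10L &
          abs(truth$start2 - active_row$start2) <= 10L]
}
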