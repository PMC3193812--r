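test_that("flank depths are symmetric in wild type and shrink on collision", {
  mini <- get_mini()
  sim <- mini$sim
  r <- sim$ref$truth[sim$ref$truth$name == "ID1"]
  fd <- flank_depth(mini$placements$WT, r, sim$ref$truth,
                    sim$ref$genome$length)
  expect_equal(nrow(fd), 4L)
  expect_equal(fd$region, 1:4)
  expect_equal(fd$side, c("up", "down", "up", "down"))
  # equal stoichiometry: four depths agree within binomial noise
  expect_lt(diff(range(fd$count)) / mean(fd$count), 0.45)
  expect_false(any(fd$shrunk))

  # a window overlapping another catalog repeat is shrunk and flagged
  fake <- data.table::copy(r)
  fake_cat <- rbind(sim$ref$truth,
                    data.table::copy(r)[, `:=`(name = "INTRUDER",
                                               start1 = r$start1 - 100L,
                                               end1 = r$start1 - 60L,
                                               start2 = r$start2 + 5000L,
                                               end2 = r$start2 + 5040L)],
                    fill = TRUE)
  fd2 <- flank_depth(mini$placements$WT, r, fake_cat,
                     sim$ref$genome$length)
  expect_true(fd2$shrunk[1])
  expect_equal(fd2$win_start[1], r$start1 - 60L)
})

test_that("class I mixture arithmetic shows up in the flank table", {
  fr <- get_fate_run()
  res <- fr$res
  tr <- truth_with_coord_donor(fr$sim$ref)
  # class I at fraction 0.7: donor-upstream region depleted to ~(1-f),
  # class II repeats keep every region near wild type
  for (i in seq_len(nrow(res$active))) {
    arow <- res$active[i]
    trow <- match_truth(arow, tr)
    tab <- res$fate_tables[[arow$name]]
    dreg <- if (trow$donor_coord == 1L) 1L else 3L
    if (trow$fate_class == "I") {
      expect_lt(tab$change_msh1_adv[dreg], -0.5)
      expect_equal(tab$change_msh1_adv[dreg], -trow$frac_adv,
                   tolerance = 0.25)
      # monotone progression
      expect_lt(tab$change_msh1_adv[dreg], tab$change_msh1_gen1[dreg])
    } else {
      expect_gt(min(tab$change_msh1_adv), -0.25)
    }
  }
})

test_that("polarity and fate recover the planted truth on the deep fixture", {
  fr <- get_fate_run()
  res <- fr$res
  tr <- truth_with_coord_donor(fr$sim$ref)
  expect_equal(nrow(res$active), nrow(tr[!is.na(fate_class)]))
  n_pol <- 0L; n_fate <- 0L
  for (i in seq_len(nrow(res$active))) {
    arow <- res$active[i]
    trow <- match_truth(arow, tr)
    prow <- res$polarity[res$polarity$repeat_name == arow$name]
    if (prow$donor_copy == trow$donor_coord) n_pol <- n_pol + 1L
    if (prow$fate_class == trow$fate_class) n_fate <- n_fate + 1L
  }
  expect_equal(n_pol, nrow(res$active))   # 100% polarity recovery
  expect_equal(n_fate, nrow(res$active))  # 100% fate recovery
})

test_that("fate classification boundary semantics", {
  tab <- function(g1, g2) data.table::data.table(
    region = 1:4, copy = c(1L, 1L, 2L, 2L), side = c("up", "down"),
    change_msh1_gen1 = g1, change_msh1_adv = g2)
  # (-0.2, -0.8): class I
  f1 <- classify_fate(tab(c(-0.2, 0, 0, 0), c(-0.8, 0, 0.1, 0)), 10L, 40L)
  expect_equal(f1$class, "I")
  # flat parental signal with growing support: class II
  f2 <- classify_fate(tab(c(0.02, 0, 0.05, 0), c(-0.04, 0, 0.2, 0)),
                      15L, 60L)
  expect_equal(f2$class, "II")
  # no progression (-0.3 -> -0.3): indeterminate
  f3 <- classify_fate(tab(c(-0.3, 0, 0, 0), c(-0.3, 0, 0, 0)), 10L, 40L)
  expect_equal(f3$class, "indeterminate")
  # depletion beyond the band without reaching class I: indeterminate
  f4 <- classify_fate(tab(c(-0.3, 0, 0, 0), c(-0.4, 0, 0, 0)), 10L, 40L)
  expect_equal(f4$class, "indeterminate")
})

test_that("polarity call combines coverage and junction votes", {
  tab <- data.table::data.table(
    region = 1:4, copy = c(1L, 1L, 2L, 2L),
    side = c("up", "down", "up", "down"),
    change_msh1_adv = c(-0.7, 0.02, 0.65, -0.03))
  jun <- data.table::data.table(donor_copy = 1L, recipient_copy = 2L)
  p <- call_polarity(tab, jun)
  expect_equal(p$donor, 1L)
  expect_equal(p$depleted_region, 1L)   # region 1 depleted ...
  expect_equal(p$increased_region, 3L)  # ... region 3 increased
  expect_equal(p$method, "coverage+junction")
  # conflicting votes: indeterminate with both reported
  jun2 <- data.table::data.table(donor_copy = 2L, recipient_copy = 1L)
  p2 <- call_polarity(tab, jun2)
  expect_true(is.na(p2$donor))
  expect_equal(p2$method, "conflict")
  expect_equal(unname(p2$votes), c(1L, 2L))
  # flat coverage, no junction: nothing to call
  flat <- data.table::copy(tab)[, change_msh1_adv := c(-0.05, 0.02, 0.04, -0.01)]
  p3 <- call_polarity(flat, NULL)
  expect_true(is.na(p3$donor))
  expect_equal(p3$method, "none")
  # flat coverage with junction: junction-only polarity (class II path)
  p4 <- call_polarity(flat, jun)
  expect_equal(p4$donor, 1L)
  expect_equal(p4$method, "junction")
})

test_that("median normalisation makes calls scale-invariant", {
  fr <- get_fate_run()
  res <- fr$res
  sim <- fr$sim
  nm <- res$active$name[1]
  pair <- res$active[1]
  placements <- lapply(names(sim$libraries), function(cond)
    data.table::copy(sim$libraries[[cond]]$placements %||%
                       map_reads(sim$libraries[[cond]]$pairs,
                                 sim$ref$genome)))
  names(placements) <- names(sim$libraries)
  md <- res$medians
  tab1 <- flank_change_table(placements, md, pair, res$catalog,
                             sim$ref$genome$length)
  # multiply every depth by 3 (triplicate placements): identical changes
  placements3 <- lapply(placements, function(p)
    data.table::rbindlist(list(p, p, p)))
  md3 <- md * 3
  tab3 <- flank_change_table(placements3, md3, pair, res$catalog,
                             sim$ref$genome$length)
  expect_equal(tab3$change_msh1_adv, tab1$change_msh1_adv, tolerance = 1e-9)
})

test_that("generation trend couples gain and loss for class I repeats", {
  fr <- get_fate_run()
  res <- fr$res
  tr <- truth_with_coord_donor(fr$sim$ref)
  classI <- vapply(seq_len(nrow(res$active)), function(i)
    match_truth(res$active[i], tr)$fate_class == "I", TRUE)
  tabs <- res$fate_tables[res$active$name[classI]]
  sup <- data.table::rbindlist(lapply(names(tabs), function(nm) {
    a <- res$assignments[res$assignments$repeat_name == nm &
                           res$assignments$call == "repeat-mediated"][1]
    data.table::data.table(repeat_name = nm,
                           support_msh1_gen1 = a$net_support_msh1_gen1,
                           support_msh1_adv = a$net_support_msh1_adv)
  }))
  tro <- generation_trend(tabs, sup, as.list(res$medians))
  expect_lt(tro$correlation, -0.8)
  # single repeat: report but no correlation
  tr1 <- generation_trend(tabs[1], sup[1], as.list(res$medians))
  expect_true(is.na(tr1$correlation))
  expect_equal(nrow(tr1$per_repeat), 2L)
})
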