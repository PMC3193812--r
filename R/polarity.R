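# polarity_class: flanking-coverage quantification, strand-invasion
# polarity, and class I/II parental-form fate.
#
# Regions are numbered 1-4 as (copy1 upstream, copy1 downstream, copy2
# upstream, copy2 downstream) in genome orientation.  Under the
# break-induced-replication model the recombinant joins the recipient
# copy's upstream flank to the donor copy's downstream flank, so the
# donor's upstream environment is the one depleted when the invading
# strand's parental form is lost (class I), while class II repeats keep
# all parental environments near wild-type level.

#' Flanking-region read-pair depth for one repeat
#'
#' Counts read pairs (not bases) with one end overlapping the repeat copy
#' and the mate fully inside the flank window.  A window truncated by a
#' neighbouring catalog repeat is shrunk to the free gap and flagged.
#'
#' @param placements placement table of one library.
#' @param pair one catalog/truth row (with `start1`/`end1`/`start2`/`end2`).
#' @param catalog full catalog used to detect window collisions.
#' @param L genome length.
#' @param window flank window length (insert mean: the mate of a
#'   repeat-anchored read falls within one insert of the repeat edge).
#' @param read_len read length.
#' @return data.table with `region` (1-4), `copy`, `side`, `win_start`,
#'   `win_end`, `count`, `shrunk`.
#' @export
flank_depth <- function(placements, pair, catalog = NULL, L,
                        window = 220L, read_len = 36L) {
  p <- data.table::as.data.table(placements)
  p <- p[concordance %in% c("concordant", "discordant")]
  regions <- data.table(
    region = 1:4, copy = c(1L, 1L, 2L, 2L),
    side = c("up", "down", "up", "down"),
    cs = c(pair$start1, pair$start1, pair$start2, pair$start2),
    ce = c(pair$end1, pair$end1, pair$end2, pair$end2))
  regions[, `:=`(win_start = ifelse(side == "up", cs - window, ce),
                 win_end = ifelse(side == "up", cs, ce + window))]
  regions[, shrunk := FALSE]
  if (!is.null(catalog) && nrow(catalog)) {
    ivals <- rbind(
      data.table(s = catalog$start1, e = catalog$end1, nm = catalog$name),
      data.table(s = catalog$start2, e = catalog$end2, nm = catalog$name))
    for (i in 1:4) {
      ws <- regions$win_start[i]; we <- regions$win_end[i]
      own <- ivals$s == regions$cs[i] & ivals$e == regions$ce[i]
      hit <- !own & intervals_overlap(ivals$s, ivals$e, ws, we)
      if (!any(hit)) next
      if (regions$side[i] == "up") {
        regions$win_start[i] <- max(ivals$e[hit])
      } else {
        regions$win_end[i] <- min(ivals$s[hit])
      }
      regions$shrunk[i] <- TRUE
    }
  }
  counts <- vapply(1:4, function(i) {
    cs <- regions$cs[i]; ce <- regions$ce[i]
    ws <- regions$win_start[i]; we <- regions$win_end[i]
    in_rep1 <- p$pos1 < ce & p$pos1 + read_len > cs
    in_rep2 <- p$pos2 < ce & p$pos2 + read_len > cs
    in_win1 <- p$pos1 >= ws & p$pos1 + read_len <= we
    in_win2 <- p$pos2 >= ws & p$pos2 + read_len <= we
    sum((in_rep1 & in_win2) | (in_rep2 & in_win1), na.rm = TRUE)
  }, numeric(1))
  regions[, count := counts]
  regions[, c("cs", "ce") := NULL]
  regions[]
}

#' Flank-coverage change table across libraries for one repeat
#'
#' Depths are normalised by each library's genome-wide median depth;
#' relative change versus wild type is `(norm mutant / norm WT) - 1`.
#'
#' @param placements_by_lib named list of placement tables; must include
#'   `WT` plus at least one mutant library.
#' @param median_depth named numeric vector of genome-wide median depths
#'   per library (same names).
#' @param pair catalog/truth row.
#' @param catalog full catalog (collision detection).
#' @param L genome length.
#' @param window,read_len geometry.
#' @return data.table with one row per region: window coordinates,
#'   `count_<lib>`, `norm_<lib>`, and `change_<lib>` for each mutant
#'   library.
#' @export
flank_change_table <- function(placements_by_lib, median_depth, pair,
                               catalog = NULL, L, window = 220L,
                               read_len = 36L) {
  stopifnot("WT" %in% names(placements_by_lib))
  base <- NULL
  for (lb in names(placements_by_lib)) {
    fd <- flank_depth(placements_by_lib[[lb]], pair, catalog, L,
                      window, read_len)
    if (is.null(base)) {
      base <- fd[, .(region, copy, side, win_start, win_end, shrunk)]
    }
    base[, (paste0("count_", lb)) := fd$count]
    base[, (paste0("norm_", lb)) := fd$count / median_depth[[lb]]]
  }
  for (lb in setdiff(names(placements_by_lib), "WT")) {
    base[, (paste0("change_", lb)) :=
           base[[paste0("norm_", lb)]] / pmax(base[["norm_WT"]], 1e-9) - 1]
  }
  base[]
}

#' Call strand-invasion polarity for one active repeat
#'
#' Combines two votes: the coverage vote (the depleted region, when
#' depletion beyond the retention band exists, belongs to the donor copy
#' and must be an upstream region under the BIR model) and the junction
#' vote (which copy's upstream flank is fused in the observed product
#' identifies the recipient).  When no parental depletion is measurable
#' (class II pattern) polarity comes from the junction alone.
#' Conflicting votes yield `indeterminate` with both votes reported.
#'
#' @param table flank-change table from [flank_change_table()].
#' @param junction one row of the assignment table from
#'   [call_active_repeats()] (for its `recipient_copy`/`donor_copy`), or
#'   `NULL` when no junction is available.
#' @param generation which `change_<lib>` column drives the coverage vote
#'   (default the advanced generation).
#' @param depletion_threshold relative change at or below which a region
#'   counts as depleted.
#' @return list: `donor`, `recipient`, `depleted_region`,
#'   `increased_region`, `fate_hint`, `confidence`, `method`, `votes`.
#' @export
call_polarity <- function(table, junction = NULL,
                          generation = "msh1_adv",
                          depletion_threshold = -0.25) {
  ch <- table[[paste0("change_", generation)]]
  if (is.null(ch)) stop("no change column for generation ", generation)
  dep <- which.min(ch); inc <- which.max(ch)
  cov_vote <- NA_integer_
  if (ch[dep] <= depletion_threshold && table$side[dep] == "up")
    cov_vote <- table$copy[dep]
  jun_vote <- if (!is.null(junction) && !is.na(junction$donor_copy))
    as.integer(junction$donor_copy) else NA_integer_
  votes <- c(coverage = cov_vote, junction = jun_vote)
  if (all(is.na(votes)))
    return(list(donor = NA_integer_, recipient = NA_integer_,
                depleted_region = dep, increased_region = inc,
                confidence = 0, method = "none", votes = votes))
  if (!is.na(cov_vote) && !is.na(jun_vote) && cov_vote != jun_vote)
    return(list(donor = NA_integer_, recipient = NA_integer_,
                depleted_region = dep, increased_region = inc,
                confidence = 0, method = "conflict", votes = votes))
  donor <- if (!is.na(cov_vote)) cov_vote else jun_vote
  method <- if (!is.na(cov_vote) && !is.na(jun_vote)) "coverage+junction"
  else if (!is.na(cov_vote)) "coverage" else "junction"
  conf <- if (!is.na(cov_vote))
    abs(ch[dep]) - abs(depletion_threshold) else NA_real_
  list(donor = donor, recipient = 3L - donor, depleted_region = dep,
       increased_region = inc, confidence = conf, method = method,
       votes = votes)
}

#' Classify the parental-form fate of a repeat (class I / class II)
#'
#' Class I: the depleted region's relative change passes the depletion
#' threshold in the advanced generation and worsens monotonically from
#' the first generation.  Class II: no region drops below the retention
#' band in either generation while junction support grows.  Anything else
#' is indeterminate.
#'
#' @param table flank-change table with `change_msh1_gen1` and
#'   `change_msh1_adv` columns.
#' @param support_gen1,support_adv junction cluster support per
#'   generation.
#' @param class1_threshold depletion threshold for class I (relative
#'   change in the advanced generation).
#' @param retention_band maximum depletion compatible with parental
#'   retention (applied one-sided: gains at junction-fused flanks are
#'   expected and grow with the recombinant fraction, so only losses
#'   discriminate the classes).
#' @return list `class` (`"I"`, `"II"`, `"indeterminate"`),
#'   `depleted_region`, `change_gen1`, `change_adv`.
#' @export
classify_fate <- function(table, support_gen1 = NA_integer_,
                          support_adv = NA_integer_,
                          class1_threshold = -0.5, retention_band = 0.25) {
  ch1 <- table$change_msh1_gen1
  ch2 <- table$change_msh1_adv
  if (is.null(ch1) || is.null(ch2))
    stop("both generations required for fate classification")
  dep <- which.min(ch2)
  if (ch2[dep] <= class1_threshold && ch2[dep] < ch1[dep]) {
    cls <- "I"
  } else if (min(ch1) > -retention_band && min(ch2) > -retention_band &&
             !is.na(support_gen1) && !is.na(support_adv) &&
             support_adv > support_gen1) {
    cls <- "II"
  } else {
    cls <- "indeterminate"
  }
  list(class = cls, depleted_region = dep,
       change_gen1 = ch1[dep], change_adv = ch2[dep])
}

#' Gain/loss gradient across generations
#'
#' For each repeat, pairs the recombinant gain series (junction support
#' normalised to expected junction-spanning pairs at the library's median
#' depth) with the parental loss series (depleted-region relative
#' change), and reports the cross-repeat correlation.
#'
#' @param fate_tables named list (by repeat) of flank-change tables.
#' @param supports data.table `repeat_name`, `support_msh1_gen1`,
#'   `support_msh1_adv`.
#' @param median_depth named vector of median depths per library.
#' @param insert_mean,read_len geometry for the expected-support scale.
#' @return list: `per_repeat` table (gain and loss per generation) and
#'   `correlation` (Pearson r across repeat-generation points; `NA` for a
#'   single repeat).
#' @export
generation_trend <- function(fate_tables, supports, median_depth,
                             insert_mean = 220, read_len = 36L) {
  exp_span <- function(lib)
    median_depth[[lib]] * (insert_mean - 2 * read_len) / (2 * read_len)
  rows <- lapply(names(fate_tables), function(nm) {
    tab <- fate_tables[[nm]]
    s <- supports[supports$repeat_name == nm]
    if (!nrow(s)) return(NULL)
    dep <- which.min(tab$change_msh1_adv)
    data.table(
      repeat_name = nm,
      generation = c("msh1_gen1", "msh1_adv"),
      gain = c(s$support_msh1_gen1 / exp_span("msh1_gen1"),
               s$support_msh1_adv / exp_span("msh1_adv")),
      loss = c(tab$change_msh1_gen1[dep], tab$change_msh1_adv[dep]))
  })
  per_repeat <- data.table::rbindlist(rows)
  correlation <- if (length(unique(per_repeat$repeat_name)) > 1L)
    cor(per_repeat$gain, per_repeat$loss) else NA_real_
  list(per_repeat = per_repeat, correlation = correlation)
}
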