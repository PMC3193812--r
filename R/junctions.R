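# junction_detect: cluster discordant pairs into junctions, apply the
# support filter, and call recombination-active repeats.

#' Cluster discordant read pairs into putative junctions
#'
#' Single-linkage clustering of pairs whose circular span exceeds
#' `min_span`: two pairs join when both corresponding endpoints lie
#' within `radius` (default insert mean + 3 sd) and their orientation
#' signatures match.  Endpoint windows are the union span of member read
#' placements.
#'
#' @param placements placement table (from [map_reads()] or
#'   [placements_from_sam()]), optionally carrying a `library` column
#'   when several libraries are pooled.
#' @param L genome length.
#' @param min_span circular span threshold in bp (strict `>`); junctions
#'   are defined by ends mapping more than 1 kb apart.
#' @param radius cluster joining radius in bp.
#' @param read_len read length.
#' @return list: `clusters` (data.table `cluster_id`, `w1_start`/`w1_end`,
#'   `w2_start`/`w2_end`, `orientation`, `support`, per-library
#'   `support_<lib>` columns when a `library` column is present) and
#'   `members` (data.table `cluster_id`, `qname`, `library`).
#' @export
cluster_discordant <- function(placements, L, min_span = 1000,
                               radius = 280, read_len = 36L) {
  all_libs <- if ("library" %in% names(placements))
    unique(placements[["library"]]) else "all"
  d <- placements[placements$concordance == "discordant" &
                    !is.na(placements$circ_span) &
                    placements$circ_span > min_span &
                    placements$reason == "distance", ]
  d <- data.table::as.data.table(d)
  if (!"library" %in% names(d)) d[, library := "all"]
  if (!nrow(d)) return(list(clusters = empty_cluster_table(),
                            members = data.table(cluster_id = integer(),
                                                 qname = character(),
                                                 library = character())))
  # order endpoints: lo = smaller coordinate
  lo_first <- d$pos1 <= d$pos2
  d[, `:=`(lo = ifelse(lo_first, pos1, pos2),
           hi = ifelse(lo_first, pos2, pos1),
           lo_strand = ifelse(lo_first, strand1, strand2),
           hi_strand = ifelse(lo_first, strand2, strand1))]
  d[, sig := paste0(lo_strand, hi_strand)]
  data.table::setorder(d, sig, lo, hi)
  # two-level split: runs along lo, then sub-runs along hi
  d[, grp1 := cumsum(c(TRUE, diff(lo) > radius)), by = sig]
  data.table::setorder(d, sig, grp1, hi, lo)
  d[, grp2 := cumsum(c(TRUE, diff(hi) > radius)), by = .(sig, grp1)]
  d[, cluster_id := .GRP, by = .(sig, grp1, grp2)]
  clusters <- d[, .(
    w1_start = min(lo), w1_end = max(lo) + read_len,
    w2_start = min(hi), w2_end = max(hi) + read_len,
    orientation = sig[1], support = .N), by = cluster_id]
  for (lb in all_libs) {
    cnt <- d[library == lb, .N, by = cluster_id]
    col <- paste0("support_", lb)
    clusters[, (col) := 0L]
    clusters[cnt, (col) := cnt$N, on = "cluster_id"]
  }
  data.table::setorder(clusters, w1_start)
  list(clusters = clusters,
       members = d[, .(cluster_id, qname, library)])
}

empty_cluster_table <- function() {
  data.table(cluster_id = integer(), w1_start = integer(),
             w1_end = integer(), w2_start = integer(), w2_end = integer(),
             orientation = character(), support = integer())
}

#' Filter junction clusters by per-library support
#'
#' Wild-type support in the matched windows is treated as background and
#' subtracted first; a cluster is kept when its net support is strictly
#' greater than `min_support` in every required library ("more than 10
#' reads in both mutant lines").
#'
#' @param clusters cluster table from [cluster_discordant()] run on
#'   placements pooled across libraries (so per-library support columns
#'   are aligned on identical windows).
#' @param min_support support threshold (strict inequality).
#' @param require_libraries libraries that must each pass.
#' @param wt_library background library name, or `NA` to skip
#'   subtraction.
#' @return the selected clusters with added `net_support_<lib>` columns.
#' @export
filter_clusters <- function(clusters, min_support = 10,
                            require_libraries = c("msh1_gen1", "msh1_adv"),
                            wt_library = "WT") {
  cl <- data.table::copy(data.table::as.data.table(clusters))
  if (!nrow(cl)) return(cl)
  for (lb in require_libraries) {
    col <- paste0("support_", lb)
    if (!col %in% names(cl))
      stop("required library '", lb, "' has no support column")
  }
  wt_col <- paste0("support_", wt_library)
  wt <- if (!is.na(wt_library) && wt_col %in% names(cl)) cl[[wt_col]] else 0L
  keep <- rep(TRUE, nrow(cl))
  for (lb in require_libraries) {
    net <- cl[[paste0("support_", lb)]] - wt
    cl[, (paste0("net_support_", lb)) := net]
    keep <- keep & net > min_support
  }
  cl[keep]
}

# Which flank of each matched copy a cluster window fuses: the window
# with overhang upstream of its copy start marks the recipient's fused
# upstream flank.
window_overhang <- function(w_start, w_end, c_start, c_end, L) {
  # unwrap window relative to copy
  cand <- c(0, -L, L)
  best <- which.min(abs((w_start + cand) + (w_end + cand) -
                          (c_start + c_end)) / 2)
  ws <- w_start + cand[best]; we <- w_end + cand[best]
  c(up = max(0, c_start - ws), down = max(0, we - c_end))
}

#' Assign filtered clusters to repeats and call the active set
#'
#' Each selected cluster is assigned to the best-matching catalog pair
#' via [assign_junction_to_repeat()]; a repeat is active when at least
#' one selected cluster assigns to it.  Clusters explained by no pair are
#' NHEJ candidates; an NHEJ candidate whose two windows overlap copies of
#' two distinct active pairs is annotated `secondary` (an event dependent
#' on a genomic environment created by a primary recombination).  If both
#' reciprocal junction orientations of one repeat pass the filter the
#' repeat is flagged `symmetric_exchange_anomaly` (the model expects
#' asymmetric, one-product exchange).
#'
#' @param selected filtered cluster table.
#' @param catalog repeat catalog ([find_repeat_pairs()] output).
#' @param genome [genome_seq()].
#' @param pad assignment window padding (insert mean + 2 sd).
#' @return list: `assignments` (cluster table with `repeat_name`, `call`
#'   in `repeat-mediated`/`NHEJ-candidate`/`secondary`, `recipient_copy`,
#'   `donor_copy` from junction geometry), `active` (active subset of the
#'   catalog with per-repeat total support), `anomalies` (repeat names).
#' @export
call_active_repeats <- function(selected, catalog, genome, pad = 260L) {
  cl <- data.table::copy(data.table::as.data.table(selected))
  L <- genome$length
  if (!nrow(cl)) {
    return(list(assignments = cl, active = catalog[0], anomalies = character()))
  }
  if (!nrow(catalog)) {
    log_stage("call_active_repeats", "empty catalog: all ", nrow(cl),
              " clusters are NHEJ candidates")
    cl[, `:=`(repeat_name = NA_character_, call = "NHEJ-candidate",
              recipient_copy = NA_integer_, donor_copy = NA_integer_)]
    return(list(assignments = cl, active = catalog[0], anomalies = character()))
  }
  res <- lapply(seq_len(nrow(cl)), function(i) {
    a <- assign_junction_to_repeat(
      c(cl$w1_start[i], cl$w1_end[i]), c(cl$w2_start[i], cl$w2_end[i]),
      catalog, genome, pad = pad)
    if (is.na(a$index))
      return(list(repeat_name = NA_character_, call = "NHEJ-candidate",
                  recipient_copy = NA_integer_, donor_copy = NA_integer_))
    row <- catalog[a$index]
    # windows ordered: w1 matched copy1 unless flipped
    w_for_copy1 <- if (a$flip) c(cl$w2_start[i], cl$w2_end[i]) else
      c(cl$w1_start[i], cl$w1_end[i])
    w_for_copy2 <- if (a$flip) c(cl$w1_start[i], cl$w1_end[i]) else
      c(cl$w2_start[i], cl$w2_end[i])
    ov1 <- window_overhang(w_for_copy1[1], w_for_copy1[2],
                           row$start1, row$end1, L)
    ov2 <- window_overhang(w_for_copy2[1], w_for_copy2[2],
                           row$start2, row$end2, L)
    # the copy with the larger upstream-flank overhang is the recipient
    recipient <- if (ov1[["up"]] >= ov2[["up"]]) 1L else 2L
    list(repeat_name = row$name, call = "repeat-mediated",
         recipient_copy = recipient, donor_copy = 3L - recipient)
  })
  cl[, `:=`(repeat_name = vapply(res, `[[`, "", "repeat_name"),
            call = vapply(res, `[[`, "", "call"),
            recipient_copy = vapply(res, `[[`, 0L, "recipient_copy"),
            donor_copy = vapply(res, `[[`, 0L, "donor_copy"))]
  # secondary events: unexplained clusters whose windows overlap copies of
  # two distinct repeat-mediated pairs
  assigned <- unique(cl$repeat_name[cl$call == "repeat-mediated"])
  if (length(assigned) && any(cl$call == "NHEJ-candidate")) {
    act <- catalog[catalog$name %in% assigned]
    for (i in which(cl$call == "NHEJ-candidate")) {
      hit1 <- copy_overlap_names(cl$w1_start[i] - pad, cl$w1_end[i] + pad,
                                 act, L)
      hit2 <- copy_overlap_names(cl$w2_start[i] - pad, cl$w2_end[i] + pad,
                                 act, L)
      if (length(hit1) && length(hit2) &&
          length(union(hit1, hit2)) >= 2L &&
          !identical(sort(hit1), sort(hit2)))
        cl$call[i] <- "secondary"
    }
  }
  # symmetric-exchange anomaly: both recipient assignments seen
  anom <- cl[call == "repeat-mediated",
             .(both = length(unique(recipient_copy)) > 1L), by = repeat_name]
  anomalies <- anom[both == TRUE, repeat_name]
  per_rep <- cl[call == "repeat-mediated",
                .(n_clusters = .N, total_support = sum(support)),
                by = repeat_name]
  active <- merge(catalog, per_rep, by.x = "name", by.y = "repeat_name")
  data.table::setorder(active, start1)
  list(assignments = cl, active = active, anomalies = anomalies)
}

copy_overlap_names <- function(ws, we, catalog, L) {
  ov <- function(s, e) {
    intervals_overlap(ws, we, s, e) | intervals_overlap(ws + L, we + L, s, e) |
      intervals_overlap(ws - L, we - L, s, e)
  }
  catalog$name[ov(catalog$start1, catalog$end1) |
                 ov(catalog$start2, catalog$end2)]
}

#' Circle-plot style table of junction clusters
#'
#' Mirror of the cluster scatter representation: x = midpoint of window 1,
#' y = midpoint of window 2, radius = support.
#'
#' @param clusters cluster table.
#' @return data.table `x`, `y`, `radius`, `orientation`.
#' @export
cluster_circle_table <- function(clusters) {
  cl <- data.table::as.data.table(clusters)
  if (!nrow(cl)) return(data.table(x = numeric(), y = numeric(),
                                   radius = integer(),
                                   orientation = character()))
  cl[, .(x = (w1_start + w1_end) / 2, y = (w2_start + w2_end) / 2,
         radius = support, orientation = orientation)]
}
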