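# synthetic_data: multi-ecotype panel with tree-structured SNPs and
# planted NHEJ/REC/DEL structural polymorphisms.

#' Specify a synthetic ecotype panel
#'
#' @param n_ecotypes number of accessions.
#' @param n_groups number of phylogenetic groups (clades of the guide
#'   tree).
#' @param snp_rate per-bp SNP rate between distant accessions (the
#'   genome-wide average divergence, ~5 per 10 kb); tree depth is scaled
#'   so a cross-group pair differs at about this rate.
#' @param suppression factor by which SNP density is reduced inside
#'   large (> 1 kb) repeat copies (high-frequency reciprocal exchange
#'   homogenises them).
#' @param stem_frac fraction of root-to-tip depth carried by the group
#'   stem branches (deep stems make the groups well separated, as
#'   observed).
#' @param stem_events one structural event is planted on every group stem,
#'   cycling through these types.
#' @param n_terminal_events additional events on random terminal
#'   branches, cycling REC/NHEJ/DEL (default 3: one of each).
#' @param del_range size range (bp) for DEL events.
#' @param nhej_range deleted-segment size range (bp) for NHEJ joins of
#'   loci more than 1 kb apart.
#' @param coverage per-ecotype read coverage (the study's inclusion floor
#'   was >15x).
#' @param read_len,insert_mean,insert_sd library geometry.
#' @return `ecotype_panel_spec` list.
#' @export
ecotype_panel_spec <- function(n_ecotypes = 72L, n_groups = 6L,
                               snp_rate = 5e-4, suppression = 66,
                               stem_frac = 0.75,
                               stem_events = c("REC", "NHEJ", "DEL"),
                               n_terminal_events = 3L,
                               del_range = c(2L, 50L),
                               nhej_range = c(1200L, 8000L),
                               coverage = 20, read_len = 36L,
                               insert_mean = 220, insert_sd = 20) {
  stopifnot(n_ecotypes >= n_groups, n_groups >= 1L, snp_rate > 0,
            suppression >= 1)
  structure(list(n_ecotypes = as.integer(n_ecotypes),
                 n_groups = as.integer(n_groups), snp_rate = snp_rate,
                 suppression = suppression, stem_frac = stem_frac,
                 stem_events = stem_events,
                 n_terminal_events = as.integer(n_terminal_events),
                 del_range = del_range, nhej_range = nhej_range,
                 coverage = coverage, read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd),
            class = "ecotype_panel_spec")
}

#' Build the guide tree for an ecotype panel
#'
#' Six (by default) coalescent clades hang from a star root by long stem
#' branches.  Branch lengths are in expected substitutions per bp.
#'
#' @param spec an [ecotype_panel_spec()].
#' @param seed integer seed.
#' @return list: `tree` (ape `phylo`, tip labels `E01`..), `groups`
#'   (data.table `ecotype`, `group`).
#' @export
make_guide_tree <- function(spec, seed = 1L) {
  with_seed(derive_seed(seed, 11L), {
    depth <- spec$snp_rate / 2          # root-to-tip
    stem <- depth * spec$stem_frac
    within <- depth - stem
    sizes <- rep(spec$n_ecotypes %/% spec$n_groups, spec$n_groups)
    extra <- spec$n_ecotypes %% spec$n_groups
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    labels <- sprintf("E%02d", seq_len(spec$n_ecotypes))
    groups <- data.table(ecotype = labels,
                         group = rep(seq_len(spec$n_groups), sizes))
    subs <- vapply(seq_len(spec$n_groups), function(gi) {
      tips <- groups[group == gi, ecotype]
      if (length(tips) == 1L)
        return(sprintf("%s:%s", tips,
                       format(stem + within, scientific = FALSE)))
      tr <- ape::rcoal(length(tips), tip.label = sample(tips))
      d <- max(ape::node.depth.edgelength(tr))
      tr$edge.length <- tr$edge.length * within / d
      nwk_sub <- sub("; *$", "", ape::write.tree(tr))
      paste0(nwk_sub, ":", format(stem, scientific = FALSE))
    }, "")
    nwk <- paste0("(", paste0(subs, collapse = ","), ");")
    list(tree = ape::read.tree(text = nwk), groups = groups)
  })
}

# tip descendants per node, by post-order accumulation
tips_under <- function(tree) {
  ntip <- length(tree$tip.label)
  out <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) out[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

#' Generate an ecotype panel: genomes, truth tables, and a guide tree
#'
#' SNPs are dropped on branches proportionally to branch length
#' (positions weighted down by the suppression factor inside large-repeat
#' copies, infinite-sites), and inherited by all descendant accessions.
#' Structural events: `REC` = deletion between the copies of a short
#' intermediate repeat pair (the asymmetric-recombination deletion
#' product), `NHEJ` = join of two loci > 1 kb apart (a deleted internal
#' segment, with measured junction microhomology), `DEL` = 2-50 bp
#' deletion.  One event sits on every group stem (shared by the clade),
#' the rest on random terminal branches.
#'
#' @param ref reference bundle from [build_reference()].
#' @param spec an [ecotype_panel_spec()].
#' @param seed integer seed.
#' @return list: `tree`, `groups`, `genomes` (named list of
#'   [genome_seq()]), `snp_truth` (`ecotype`, `pos`, `ref`, `alt`),
#'   `sv_truth` (`event_id`, `type`, `branch`, `start`, `end`, `size`,
#'   `repeat_name`, `microhomology`, `carriers` comma-joined), `spec`.
#' @export
make_ecotype_panel <- function(ref, spec = ecotype_panel_spec(), seed = 1L) {
  g <- ref$genome
  L <- g$length
  gt <- make_guide_tree(spec, seed)
  tree <- gt$tree; groups <- gt$groups
  with_seed(derive_seed(seed, 12L), {
    # position weights: suppressed inside large repeat copies
    w <- rep(1, L)
    big <- ref$truth[ref$truth$length >= 1000L]
    if (nrow(big)) {
      for (i in seq_len(nrow(big))) {
        w[(big$start1[i] + 1L):big$end1[i]] <- 1 / spec$suppression
        w[(big$start2[i] + 1L):big$end2[i]] <- 1 / spec$suppression
      }
    }
    desc <- tips_under(tree)
    ntip <- length(tree$tip.label)
    used <- integer(0)
    snp_rows <- list()
    for (e in seq_len(nrow(tree$edge))) {
      child <- tree$edge[e, 2L]
      n_mut <- rpois(1L, tree$edge.length[e] * sum(w))
      if (n_mut == 0L) next
      pos <- integer(0)
      for (tr in 1:50) {
        cand <- sample.int(L, n_mut, prob = w)
        cand <- setdiff(cand, used)
        pos <- unique(c(pos, cand))
        if (length(pos) >= n_mut) { pos <- pos[seq_len(n_mut)]; break }
      }
      used <- c(used, pos)
      refb <- substring(g$sequence, pos, pos)
      altb <- vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      snp_rows[[length(snp_rows) + 1L]] <- data.table(
        ecotype = rep(desc[[child]], each = length(pos)),
        pos = rep(pos - 1L, length(desc[[child]])),
        ref = rep(refb, length(desc[[child]])),
        alt = rep(altb, length(desc[[child]])))
    }
    snp_truth <- if (length(snp_rows)) data.table::rbindlist(snp_rows) else
      data.table(ecotype = character(), pos = integer(), ref = character(),
                 alt = character())

    # ---- structural events (all coordinates 0-based half-open) -------
    # REC pool: short pairs (junction pairs can anchor across the hybrid
    # copy at 20x) with a desk-scale deletion span
    rec_pool <- ref$truth[!is.na(ref$truth$fate_class) &
                            ref$truth$length <= 140L]
    rec_pool <- rec_pool[(end2 - end1) >= 2500 & (end2 - end1) <= 30000]
    copies <- rbind(ref$truth[, .(s = start1, e = end1)],
                    ref$truth[, .(s = start2, e = end2)])
    ev_list <- list()
    taken <- data.table(s = integer(), e = integer(), ckey = character())
    # events may only collide when some accession carries both; events on
    # different clades never meet in one genome
    place_clear <- function(s, e, carriers, margin = 500L) {
      if (!nrow(taken)) return(TRUE)
      shared <- vapply(taken$ckey, function(k)
        length(intersect(strsplit(k, ",")[[1]], carriers)) > 0L, TRUE)
      !any(intervals_overlap(taken$s[shared] - margin,
                             taken$e[shared] + margin, s, e))
    }
    # positions at least `margin` bp from every repeat copy: breakpoints
    # placed there cannot have their junction attributed to a pair; the
    # deleted interior may still contain repeats (a copy lost wholesale)
    clear_positions <- function(margin) {
      cv <- rep(TRUE, L)
      for (i in seq_len(nrow(copies))) {
        a <- max(1L, copies$s[i] - margin + 1L)
        b <- min(L, copies$e[i] + margin)
        cv[a:b] <- FALSE
      }
      cv[c(1:1000, (L - 1000):L)] <- FALSE
      which(cv) - 1L
    }
    clear300 <- clear_positions(300L)
    clear200 <- clear_positions(200L)
    nonrep_locus <- function(size_range, margin, carriers) {
      cp <- if (margin >= 300L) clear300 else clear200
      for (tr in 1:300) {
        s <- cp[sample.int(length(cp), 1L)]
        es <- cp[cp - s >= size_range[1] & cp - s <= size_range[2]]
        if (!length(es)) next
        e <- es[sample.int(length(es), 1L)]
        if (place_clear(s, e, carriers)) return(c(s, e))
      }
      stop("cannot place structural event in size range ",
           size_range[1], "-", size_range[2], " after 300 retries (",
           length(cp), " clear positions, ", nrow(taken),
           " events already placed)")
    }
    add_event <- function(type, branch, carriers) {
      id <- length(ev_list) + 1L
      ok <- FALSE
      for (tr in 1:50) {
        if (type == "REC") {
          used <- vapply(ev_list, function(x)
            if (is.na(x$repeat_name)) "" else x$repeat_name, "")
          avail <- rec_pool[!rec_pool$name %in% used]
          if (!nrow(avail)) stop("no repeat pairs left for REC events")
          row <- avail[sample.int(nrow(avail), 1L)]
          # asymmetric-deletion product: one hybrid copy remains, the
          # segment from the end of copy1 through the end of copy2 is lost
          s <- row$end1; e <- row$end2
          rn <- row$name
        } else if (type == "NHEJ") {
          se <- nonrep_locus(spec$nhej_range, 300L, carriers)
          s <- se[1]; e <- se[2]
          rn <- NA_character_
        } else {
          se <- nonrep_locus(spec$del_range, 200L, carriers)
          s <- se[1]; e <- se[2]
          rn <- NA_character_
        }
        if (place_clear(s, e, carriers)) { ok <- TRUE; break }
      }
      if (!ok) stop("cannot place ", type, " event after 50 retries")
      taken <<- rbind(taken, data.table(s = s, e = e,
                                        ckey = paste(carriers,
                                                    collapse = ",")))
      # measured junction microhomology: longest shared suffix of the
      # kept left context and the deleted-end context (1-based compare)
      mh <- 0L
      while (mh < 10L && s - mh >= 1L &&
             substr(g$sequence, s - mh, s - mh) ==
             substr(g$sequence, e - mh, e - mh)) mh <- mh + 1L
      ev_list[[id]] <<- list(event_id = id, type = type, branch = branch,
                             start = s, end = e, size = e - s,
                             repeat_name = rn, microhomology = mh,
                             carriers = carriers)
      invisible(id)
    }
    for (gi in seq_len(spec$n_groups)) {
      type <- spec$stem_events[(gi - 1L) %% length(spec$stem_events) + 1L]
      add_event(type, paste0("stem_g", gi), groups[group == gi, ecotype])
    }
    if (spec$n_terminal_events > 0L) {
      ecos <- sample(groups$ecotype, spec$n_terminal_events)
      for (j in seq_len(spec$n_terminal_events)) {
        type <- c("REC", "NHEJ", "DEL")[(j - 1L) %% 3L + 1L]
        add_event(type, ecos[j], ecos[j])
      }
    }
    sv_truth <- data.table::rbindlist(lapply(ev_list, function(x) {
      data.table(event_id = x$event_id, type = x$type, branch = x$branch,
                 start = x$start, end = x$end, size = x$size,
                 repeat_name = x$repeat_name,
                 microhomology = x$microhomology,
                 carriers = paste(x$carriers, collapse = ","))
    }))

    # ---- build genomes ------------------------------------------------
    genomes <- list()
    for (eco in groups$ecotype) {
      seq <- g$sequence
      snps <- snp_truth[ecotype == eco]
      if (nrow(snps)) {
        ch <- strsplit(seq, "")[[1]]
        ch[snps$pos + 1L] <- snps$alt
        seq <- paste(ch, collapse = "")
      }
      dels <- sv_truth[grepl(paste0("(^|,)", eco, "(,|$)"), carriers)]
      if (nrow(dels)) {
        data.table::setorder(dels, -start)
        for (i in seq_len(nrow(dels))) {
          seq <- paste0(substr(seq, 1L, dels$start[i]),
                        substr(seq, dels$end[i] + 1L, nchar(seq)))
        }
      }
      genomes[[eco]] <- genome_seq(eco, seq, circular = g$circular)
    }
    # SNPs falling inside a carried deletion are unobservable
    if (nrow(sv_truth) && nrow(snp_truth)) {
      drop <- rep(FALSE, nrow(snp_truth))
      for (i in seq_len(nrow(sv_truth))) {
        carr <- strsplit(sv_truth$carriers[i], ",")[[1]]
        drop <- drop | (snp_truth$ecotype %in% carr &
                          snp_truth$pos >= sv_truth$start[i] &
                          snp_truth$pos < sv_truth$end[i])
      }
      snp_truth <- snp_truth[!drop]
    }
    list(tree = tree, groups = groups, genomes = genomes,
         snp_truth = snp_truth, sv_truth = sv_truth, spec = spec)
  })
}

#' Simulate a plain read library from one panel genome
#'
#' @param genome a [genome_seq()] (an ecotype genome).
#' @param spec an [ecotype_panel_spec()] (for coverage and geometry).
#' @param seed integer seed (vary per ecotype).
#' @return as [simulate_library()].
#' @export
simulate_panel_library <- function(genome, spec, seed) {
  fake_ref <- list(genome = genome,
                   truth = default_repeat_catalog()[0][, `:=`(
                     start1 = integer(), end1 = integer(),
                     start2 = integer(), end2 = integer(),
                     copy1_is_spec_copy1 = logical())])
  ls <- library_spec("WT", coverage = spec$coverage,
                     read_len = spec$read_len,
                     insert_mean = spec$insert_mean,
                     insert_sd = spec$insert_sd)
  simulate_library(fake_ref, list(), ls, seed = seed)
}
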