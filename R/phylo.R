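# ecotype_phylo: threshold SNP calling, NHEJ/REC/DEL structural-variant
# classification, stoichiometry labels, and SNP-based distance phylogeny
# with group assignment.

#' Ambiguous-placement mask over catalog repeats
#'
#' Positions deeper inside a repeat copy than mate rescue can reach
#' (insert mean + 4 sd - read length from either edge) cannot be covered
#' by confidently placed reads; pileup evidence there is suppressed as
#' poorly aligned.
#'
#' @param catalog repeat catalog or truth table.
#' @param L genome length.
#' @param insert_mean,insert_sd,read_len library geometry.
#' @return logical vector of length `L` (TRUE = masked), index i is
#'   0-based position i - 1.
#' @export
ambiguity_mask <- function(catalog, L, insert_mean = 220, insert_sd = 20,
                           read_len = 36L) {
  reach <- as.integer(insert_mean + 4 * insert_sd - read_len)
  mask <- logical(L)
  if (is.null(catalog) || !nrow(catalog)) return(mask)
  copies <- rbind(data.table(s = catalog$start1, e = catalog$end1),
                  data.table(s = catalog$start2, e = catalog$end2))
  for (i in seq_len(nrow(copies))) {
    s <- copies$s[i] + reach; e <- copies$e[i] - reach
    if (e > s) mask[(s + 1L):e] <- TRUE
  }
  mask
}

# per-position alternate-allele counts from placed reads
pileup_mismatches <- function(placements, reads, genome, read_len = 36L) {
  pl <- data.table::as.data.table(placements)
  pl <- pl[concordance %in% c("concordant", "discordant")]
  pl <- merge(pl, data.table::as.data.table(reads), by = "qname")
  ends <- rbind(
    pl[nbest1 == 1L | rescued1,
       .(pos = pos1, fseq = forward_read(seq1, strand1))],
    pl[nbest2 == 1L | rescued2,
       .(pos = pos2, fseq = forward_read(seq2, strand2))])
  if (!nrow(ends))
    return(data.table(pos = integer(), base = character(), n = integer()))
  L <- genome$length
  gext_raw <- charToRaw(paste0(genome$sequence,
                               substr(genome$sequence, 1L, read_len - 1L)))
  read_raw <- matrix(charToRaw(paste(ends$fseq, collapse = "")),
                     nrow = read_len)
  hits <- list()
  for (j in seq_len(read_len)) {
    gb <- gext_raw[ends$pos + j]
    rb <- read_raw[j, ]
    d <- which(gb != rb)
    if (length(d))
      hits[[length(hits) + 1L]] <- data.table(
        pos = (ends$pos[d] + j - 1L) %% L,
        base = rawToChar(rb[d], multiple = TRUE))
  }
  if (!length(hits))
    return(data.table(pos = integer(), base = character(), n = integer()))
  data.table::rbindlist(hits)[, .(n = .N), by = .(pos, base)]
}

#' Threshold SNP calling from a read pileup
#'
#' Emits a SNP where read depth exceeds `min_depth` (strictly) and one
#' alternate base accounts for strictly more than `min_fraction` of the
#' covering reads; positions under the ambiguity mask are suppressed.
#'
#' @param placements placement table for one accession's library.
#' @param reads its read-pair table.
#' @param genome the reference [genome_seq()].
#' @param min_depth depth must be `> min_depth` (the documented "more
#'   than 5x").
#' @param min_fraction allele fraction must be `> min_fraction` ("more
#'   than 80% of the reads").
#' @param mask optional logical mask from [ambiguity_mask()].
#' @param read_len read length.
#' @return data.table: `pos` (0-based), `ref`, `alt`, `depth`, `af`.
#' @export
call_snps <- function(placements, reads, genome, min_depth = 5L,
                      min_fraction = 0.8, mask = NULL, read_len = 36L) {
  depth <- coverage_track(placements, genome, read_len)
  mm <- pileup_mismatches(placements, reads, genome, read_len)
  call_snps_from_pileup(mm, depth, genome, min_depth, min_fraction, mask)
}

#' Threshold SNP calling from pre-computed pileup counts
#'
#' Same thresholds as [call_snps()] but takes per-position alternate
#' counts directly (`pos` 0-based, `base`, `n`) plus a depth vector, so
#' constructed pileups can exercise the boundary semantics.
#'
#' @param mismatches data.table `pos`, `base`, `n`.
#' @param depth integer vector of per-position depth.
#' @param genome reference [genome_seq()].
#' @param min_depth,min_fraction strict thresholds.
#' @param mask optional logical mask.
#' @return as [call_snps()].
#' @export
call_snps_from_pileup <- function(mismatches, depth, genome,
                                  min_depth = 5L, min_fraction = 0.8,
                                  mask = NULL) {
  if (!nrow(mismatches))
    return(data.table(pos = integer(), ref = character(),
                      alt = character(), depth = integer(), af = numeric()))
  top <- mismatches[order(pos, -n)][, head(.SD, 1L), by = pos]
  top[, d := depth[pos + 1L]]
  top[, af := n / pmax(d, 1L)]
  keep <- top$d > min_depth & top$af > min_fraction
  if (!is.null(mask)) keep <- keep & !mask[top$pos + 1L]
  out <- top[keep]
  if (!nrow(out))
    return(data.table(pos = integer(), ref = character(),
                      alt = character(), depth = integer(), af = numeric()))
  out[, ref := substring(genome$sequence, pos + 1L, pos + 1L)]
  out[, .(pos, ref, alt = base, depth = d, af)]
}

#' Classify structural variants for one accession
#'
#' Junction clusters passing the single-library support filter become
#' `REC` when [assign_junction_to_repeat()] explains them by a catalog
#' pair, otherwise `NHEJ`.  Near-zero-coverage runs with well-covered
#' flanks become deletions.  "Near zero" is depth at most
#' `max(2, 0.3 * median)`: reads overhanging a deletion junction by up
#' to the mismatch allowance still map, bleeding one or two reads of
#' depth into the first few deleted bases, so a strict zero-run would
#' clip deletion boundaries.  Runs whose breakpoints coincide (within
#' `slop`) with a pair's inter-copy interval are `REC` even without
#' junction reads; runs of 2-50 bp are `DEL`; other unexplained runs are
#' reported as `gap`.
#'
#' @param clusters selected single-library cluster table (net support
#'   already filtered).
#' @param depth coverage vector from [coverage_track()].
#' @param catalog repeat catalog.
#' @param genome reference [genome_seq()].
#' @param mask ambiguity mask (zero-coverage runs inside it are mapping
#'   artifacts, not deletions).
#' @param min_flank_depth required mean depth over 50 bp on each side of
#'   a gap.
#' @param slop breakpoint tolerance in bp.
#' @param median_depth genome-wide median depth (for stoichiometry).
#' @param insert_mean,read_len geometry.
#' @return data.table of calls: `type`, `start`, `end`, `size`,
#'   `repeat_name`, `support`, `evidence`, `stoichiometry`.
#' @export
classify_svs <- function(clusters, depth, catalog, genome, mask = NULL,
                         min_flank_depth = 10, slop = 20L,
                         median_depth = stats::median(depth),
                         insert_mean = 220, read_len = 36L) {
  L <- genome$length
  calls <- list()
  cl <- data.table::as.data.table(clusters)
  if (nrow(cl)) {
    for (i in seq_len(nrow(cl))) {
      a <- assign_junction_to_repeat(
        c(cl$w1_start[i], cl$w1_end[i]), c(cl$w2_start[i], cl$w2_end[i]),
        catalog, genome)
      sto <- label_stoichiometry(cl$support[i], median_depth,
                                 insert_mean, read_len)
      if (!is.na(a$index)) {
        row <- catalog[a$index]
        calls[[length(calls) + 1L]] <- data.table(
          type = "REC", start = row$end1, end = row$end2,
          size = row$end2 - row$end1, repeat_name = row$name,
          support = cl$support[i], evidence = "junction",
          stoichiometry = sto)
      } else {
        calls[[length(calls) + 1L]] <- data.table(
          type = "NHEJ", start = cl$w1_end[i], end = cl$w2_start[i],
          size = NA_integer_, repeat_name = NA_character_,
          support = cl$support[i], evidence = "junction",
          stoichiometry = sto)
      }
    }
  }
  # near-zero-coverage runs
  near_zero <- max(2, round(0.05 * median_depth))
  zero <- depth <= near_zero
  if (!is.null(mask)) zero <- zero & !mask
  r <- rle(zero)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths  # 0-based
  gi <- which(r$values)
  for (i in gi) {
    gs <- starts[i]; ge <- ends[i]
    if (ge - gs < 2L) next
    lo <- max(1L, gs - 50L + 1L):max(1L, gs)
    hi <- min(L, ge + 1L):min(L, ge + 50L)
    need <- max(min_flank_depth, 2 * near_zero)
    if (mean(depth[lo]) < need || mean(depth[hi]) < need) next
    # already explained by a REC junction call?
    explained <- FALSE
    for (cc in calls) {
      if (cc$type == "REC" && abs(cc$start - gs) <= slop + insert_mean &&
          abs(cc$end - ge) <= slop + insert_mean) {
        explained <- TRUE; break
      }
      if (cc$type == "NHEJ" && gs >= cc$start - insert_mean &&
          ge <= cc$end + insert_mean) {
        explained <- TRUE; break
      }
    }
    if (explained) next
    hit <- which(abs(catalog$end1 - gs) <= slop &
                   abs(catalog$start2 - ge) <= slop)
    in_copy <- any(intervals_overlap(catalog$start1, catalog$end1, gs, ge) |
                     intervals_overlap(catalog$start2, catalog$end2, gs, ge))
    if (length(hit)) {
      calls[[length(calls) + 1L]] <- data.table(
        type = "REC", start = gs, end = ge, size = ge - gs,
        repeat_name = catalog$name[hit[1]], support = 0L,
        evidence = "coverage", stoichiometry = "predominant")
    } else if (in_copy) {
      # depth dips inside repeat copies are mate-rescue artifacts of a
      # rearranged hybrid copy, not free-standing deletions
      calls[[length(calls) + 1L]] <- data.table(
        type = "gap", start = gs, end = ge, size = ge - gs,
        repeat_name = NA_character_, support = 0L,
        evidence = "coverage", stoichiometry = "predominant")
    } else if (ge - gs >= 2L && ge - gs <= 60L) {
      calls[[length(calls) + 1L]] <- data.table(
        type = "DEL", start = gs, end = ge, size = ge - gs,
        repeat_name = NA_character_, support = 0L,
        evidence = "coverage", stoichiometry = "predominant")
    } else {
      calls[[length(calls) + 1L]] <- data.table(
        type = "gap", start = gs, end = ge, size = ge - gs,
        repeat_name = NA_character_, support = 0L,
        evidence = "coverage", stoichiometry = "predominant")
    }
  }
  if (!length(calls))
    return(data.table(type = character(), start = integer(),
                      end = integer(), size = integer(),
                      repeat_name = character(), support = integer(),
                      evidence = character(), stoichiometry = character()))
  out <- data.table::rbindlist(calls)
  data.table::setorder(out, start)
  out
}

#' Stoichiometry label for a junction-supported form
#'
#' The support fraction compares observed junction support with the
#' expected number of junction-spanning pairs at the genome median
#' depth: `median * (insert - 2 * read_len) / (2 * read_len)`.
#'
#' @param support junction cluster support (read pairs).
#' @param median_depth genome-wide median read depth.
#' @param insert_mean,read_len geometry.
#' @param sub_threshold below this fraction: `substoichiometric`.
#' @param pred_threshold at or above this fraction: `predominant`.
#' @return label string; fractions between the thresholds are
#'   `intermediate`.
#' @export
label_stoichiometry <- function(support, median_depth, insert_mean = 220,
                                read_len = 36L, sub_threshold = 0.05,
                                pred_threshold = 0.5) {
  if (median_depth <= 0) stop("median depth must be positive")
  expected <- median_depth * (insert_mean - 2 * read_len) / (2 * read_len)
  f <- support / expected
  if (f < sub_threshold) "substoichiometric"
  else if (f >= pred_threshold) "predominant"
  else "intermediate"
}

#' Build the SNP presence matrix for a panel
#'
#' Columns are positions called as a SNP in at least one accession; a
#' cell holds the accession's base when confidently known (SNP called,
#' or reference supported at depth and fraction above the thresholds)
#' and `NA` otherwise.
#'
#' @param snp_sets named list (by accession) of [call_snps()] tables.
#' @param depth_sets named list of per-accession depth vectors.
#' @param genome reference [genome_seq()].
#' @param min_depth,min_fraction thresholds for accepting the reference
#'   base at a position not called in an accession.
#' @return character matrix accessions x positions (dimnames set;
#'   columns named by 1-based position).
#' @export
snp_matrix <- function(snp_sets, depth_sets, genome, min_depth = 5L,
                       min_fraction = 0.8) {
  positions <- sort(unique(unlist(lapply(snp_sets, function(s) s$pos))))
  if (!length(positions))
    return(matrix(character(), nrow = length(snp_sets), ncol = 0,
                  dimnames = list(names(snp_sets), NULL)))
  m <- matrix(NA_character_, nrow = length(snp_sets),
              ncol = length(positions),
              dimnames = list(names(snp_sets), positions + 1L))
  refb <- substring(genome$sequence, positions + 1L, positions + 1L)
  for (eco in names(snp_sets)) {
    row <- setNames(rep(NA_character_, length(positions)),
                    positions + 1L)
    d <- depth_sets[[eco]][positions + 1L]
    row[d > min_depth] <- refb[d > min_depth]
    s <- snp_sets[[eco]]
    hit <- match(s$pos, positions)
    ok <- !is.na(hit)
    row[hit[ok]] <- s$alt[ok]
    m[eco, ] <- row
  }
  m
}

#' Distance phylogeny with bootstrap from a SNP matrix
#'
#' Column exclusion: positions missing in more than half the accessions
#' are dropped, then any column still containing a missing cell.
#' Distances are TN93 (closed form, transition/transversion aware);
#' the tree is neighbour joining, unrooted, with support values from
#' bootstrap resampling of SNP columns.  Taxa are canonicalised to
#' alphabetical order so input order cannot affect the result.
#'
#' @param m character matrix from [snp_matrix()].
#' @param nboot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return list: `tree` (ape `phylo` with `node.label` = bootstrap
#'   percentages), `dist`, `matrix` (columns used), `nboot`.
#' @export
build_phylogeny <- function(m, nboot = 100L, seed = 1L) {
  if (nrow(m) < 3L) stop("at least 3 accessions required")
  keep <- colMeans(is.na(m)) <= 0.5
  m <- m[, keep, drop = FALSE]
  keep2 <- colSums(is.na(m)) == 0L
  m <- m[, keep2, drop = FALSE]
  m <- m[order(rownames(m)), , drop = FALSE]
  dnab <- ape::as.DNAbin(apply(tolower(m), c(1, 2), identity))
  dfun <- function(x) {
    d <- ape::dist.dna(x, model = "TN93", pairwise.deletion = FALSE)
    if (!all(is.finite(d))) d <- ape::dist.dna(x, model = "raw")
    d
  }
  d <- dfun(dnab)
  if (all(d == 0)) {
    warning("all accessions identical at retained sites: star tree")
    tree <- ape::stree(nrow(m), type = "star", tip.label = rownames(m))
    tree$edge.length <- rep(0, nrow(tree$edge))
    return(list(tree = tree, dist = d, matrix = m, nboot = 0L))
  }
  tree <- ape::nj(d)
  if (nboot >= 1L) {
    boots <- with_seed(derive_seed(seed, 21L),
                       ape::boot.phylo(tree, dnab,
                                       function(x) ape::nj(dfun(x)),
                                       B = nboot, quiet = TRUE))
    tree$node.label <- round(100 * boots / nboot)
  }
  list(tree = tree, dist = d, matrix = m, nboot = nboot)
}

#' Cut a tree into k groups by removing its longest internal edges
#'
#' Removes the k-1 internal edges with the largest length (ties broken
#' toward the more balanced split, then the lexicographically smallest
#' descendant tip); the connected components of the remaining forest are
#' the groups.
#'
#' @param tree ape `phylo`.
#' @param k number of groups.
#' @return data.table `ecotype`, `group` (groups numbered by smallest
#'   member label).
#' @export
assign_groups <- function(tree, k = 6L) {
  ntip <- length(tree$tip.label)
  if (k > ntip) stop("k exceeds the number of taxa")
  if (k < 1L) stop("k must be >= 1")
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  if (k > 1L) {
    internal <- which(tree$edge[, 2] > ntip)
    if (length(internal) < k - 1L)
      stop("tree has too few internal edges for k = ", k,
           " (star-like topology)")
    desc <- tips_under(tree)
    bal <- vapply(internal, function(e) {
      n <- length(desc[[tree$edge[e, 2]]])
      min(n, ntip - n)
    }, 0)
    first_tip <- vapply(internal, function(e)
      min(desc[[tree$edge[e, 2]]]), "")
    len <- tree$edge.length[internal]
    ord <- order(-len, -bal, first_tip)
    cut <- internal[ord[seq_len(k - 1L)]]
    g <- igraph::delete_edges(g, cut)
  }
  comp <- igraph::components(g)$membership
  tips <- comp[as.character(seq_len(ntip))]
  dt <- data.table(ecotype = tree$tip.label, comp = as.integer(tips))
  relabel <- dt[, .(first = min(ecotype)), by = comp][order(first)]
  relabel[, group := .I]
  merge(dt, relabel[, .(comp, group)], by = "comp")[
    order(ecotype), .(ecotype, group)]
}

#' Structural-variant / phylogeny concordance report
#'
#' For each structural event, the fraction of its carriers falling in a
#' single group; the panel concordance is the fraction of events
#' perfectly nested in one group.
#'
#' @param carriers data.table `event_id`, `ecotype` (one row per
#'   carrier).
#' @param groups data.table `ecotype`, `group`.
#' @return list: `per_event` (`event_id`, `n_carriers`, `modal_group`,
#'   `fraction_in_modal`, `nested`), `panel_concordance`.
#' @export
concordance_report <- function(carriers, groups) {
  x <- merge(data.table::as.data.table(carriers),
             data.table::as.data.table(groups), by = "ecotype")
  per <- x[, {
    tab <- sort(table(group), decreasing = TRUE)
    .(n_carriers = .N, modal_group = as.integer(names(tab)[1]),
      fraction_in_modal = as.numeric(tab[1]) / .N,
      nested = length(tab) == 1L)
  }, by = event_id]
  data.table::setorder(per, event_id)
  list(per_event = per,
       panel_concordance = if (nrow(per)) mean(per$nested) else NA_real_)
}

#' Bootstrap support for a bipartition (tip set vs the rest)
#'
#' Looks the split up either as the clade of `tips` or as the clade of
#' their complement (the same unrooted bipartition; one of the two is
#' always a clade unless the split is absent from the tree).
#'
#' @param tree `phylo` with `node.label` bootstrap percentages
#'   (as from [build_phylogeny()]).
#' @param tips tip labels on one side of the split.
#' @return support percentage, or `NA` when the split is not in the
#'   tree.
#' @export
clade_support <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  desc <- tips_under(tree)
  comp <- setdiff(tree$tip.label, tips)
  for (n in (ntip + 1L):(ntip + tree$Nnode)) {
    if (setequal(desc[[n]], tips) || setequal(desc[[n]], comp)) {
      lab <- tree$node.label[n - ntip]
      return(suppressWarnings(as.numeric(lab)))
    }
  }
  NA_real_
}

#' Export the concatenated-SNP alignment
#'
#' Writes the matrix used for the phylogeny as FASTA or sequential
#' PHYLIP, e.g. to feed an external maximum-likelihood tool.
#'
#' @param m character matrix from [snp_matrix()] (or
#'   `build_phylogeny()$matrix`).
#' @param path output file.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_snp_alignment <- function(m, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- apply(m, 1, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    writeLines(paste0(">", names(seqs), "\n", seqs), con)
  } else {
    writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
    writeLines(sprintf("%-10s %s", names(seqs), seqs), con)
  }
  invisible(path)
}
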