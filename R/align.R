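# align_core: pairwise local alignment, genome self-alignment repeat
# discovery, and the BLAST-like search used to assign junctions to repeats.
#
# Scoring follows a conventional short-sequence scheme: match +1,
# mismatch -2, gap open -5, gap extend -2 (a gap of length n costs 5 + 2n).
# Percent identity counts gap columns in the denominator so that SNPs and
# indels reduce identity on a single scale.

.ALN_MATCH <- 1
.ALN_MISMATCH <- -2
.ALN_GAPOPEN <- 5   # Biostrings penalty convention (positive)
.ALN_GAPEXT <- 2

aln_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(
    match = .ALN_MATCH, mismatch = .ALN_MISMATCH, baseOnly = FALSE)
}

# Run a (local or global) pairwise alignment and summarise it with the
# column-based identity definition.
align_stats <- function(a, b, type = "local") {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
    substitutionMatrix = aln_submat(),
    gapOpening = .ALN_GAPOPEN, gapExtension = .ALN_GAPEXT)
  summarise_pa(pa)
}

summarise_pa <- function(pa) {
  columns <- nchar(as.character(Biostrings::alignedPattern(pa)))
  matches <- Biostrings::nmatch(pa)
  mismatches <- Biostrings::nmismatch(pa)
  gapcols <- columns - matches - mismatches
  list(
    a_start = Biostrings::start(Biostrings::pattern(pa)) - 1L,
    a_end = Biostrings::end(Biostrings::pattern(pa)),
    b_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
    b_end = Biostrings::end(Biostrings::subject(pa)),
    columns = as.integer(columns), matches = as.integer(matches),
    mismatches = as.integer(mismatches), gapcols = as.integer(gapcols),
    identity = 100 * matches / columns,
    score = Biostrings::score(pa),
    aligned_a = as.character(Biostrings::alignedPattern(pa)),
    aligned_b = as.character(Biostrings::alignedSubject(pa)))
}

empty_alignment_table <- function() {
  data.table(a_start = integer(), a_end = integer(), b_start = integer(),
             b_end = integer(), columns = integer(), matches = integer(),
             mismatches = integer(), gapcols = integer(),
             identity = numeric(), score = numeric())
}

# k-mer seed matches between two sequences; returns 0-based positions.
seed_matches <- function(a, b, k) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(data.table(pa = integer(), pb = integer()))
  ka <- data.table(kmer = stringi::stri_sub(a, 1:(na - k + 1L), length = k),
                   pa = 0:(na - k))
  kb <- data.table(kmer = stringi::stri_sub(b, 1:(nb - k + 1L), length = k),
                   pb = 0:(nb - k))
  m <- merge(ka, kb, by = "kmer", allow.cartesian = TRUE)
  m[, .(pa, pb)]
}

# Group seed matches into diagonal-band candidates.  Bands of width
# `band` absorb small indel drift; runs split at gaps > `max_gap`.
seed_candidates <- function(seeds, band = 16L, max_gap = 100L) {
  if (!nrow(seeds)) return(seeds[0])
  s <- data.table::copy(seeds)
  s[, diag := pb - pa]
  s[, bd := diag %/% band]
  data.table::setorder(s, bd, pa)
  s[, brk := c(TRUE, diff(pa) > max_gap), by = bd]
  s[, grp := cumsum(brk)]
  s[, .(pa_min = min(pa), pa_max = max(pa), pb_min = min(pb),
        pb_max = max(pb), n_seeds = .N), by = grp]
}

#' Seeded local alignment of two sequences
#'
#' Finds local alignments meeting both a length and an identity threshold.
#' Exact k-mer seeds (default k = 12) are grouped into diagonal bands and
#' each band is refined by local dynamic programming (match +1, mismatch
#' -2, gap open -5, gap extend -2).  Overlapping hits are merged, keeping
#' the highest score.  For short inputs the full dynamic program is run
#' directly, so results on sequences of a few hundred bp are exactly the
#' optimal Smith-Waterman alignment.
#'
#' @param a,b DNA strings (plain character).
#' @param min_identity minimum percent identity (gap columns count in the
#'   denominator), in (0, 100].
#' @param min_length minimum alignment length in columns.
#' @param k seed k-mer size.
#' @param direct_max run the full dynamic program (no seeding) when both
#'   sequences are at most this long.
#' @return data.table of alignments (0-based half-open `a_start`/`a_end`,
#'   `b_start`/`b_end`, `columns`, `matches`, `mismatches`, `gapcols`,
#'   `identity`, `score`), sorted by decreasing score; zero rows when
#'   nothing passes.
#' @export
local_align <- function(a, b, min_identity = 85, min_length = 50, k = 12L,
                        direct_max = 600L) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (min_identity <= 0 || min_identity > 100)
    stop("min_identity out of range (0, 100]")
  if (min_length < 1) stop("min_length must be >= 1")
  if (nchar(a) <= direct_max && nchar(b) <= direct_max) {
    st <- align_stats(a, b, type = "local")
    st$aligned_a <- st$aligned_b <- NULL
    res <- data.table::as.data.table(st)
  } else {
    cand <- seed_candidates(seed_matches(a, b, k))
    if (!nrow(cand)) return(empty_alignment_table())
    margin <- max(150L, min_length)
    hits <- lapply(seq_len(nrow(cand)), function(i) {
      ca <- cand[i]
      as0 <- max(0L, ca$pa_min - margin); ae0 <- min(nchar(a), ca$pa_max + k + margin)
      bs0 <- max(0L, ca$pb_min - margin); be0 <- min(nchar(b), ca$pb_max + k + margin)
      st <- align_stats(substr(a, as0 + 1L, ae0), substr(b, bs0 + 1L, be0))
      st$aligned_a <- st$aligned_b <- NULL
      st$a_start <- st$a_start + as0; st$a_end <- st$a_end + as0
      st$b_start <- st$b_start + bs0; st$b_end <- st$b_end + bs0
      data.table::as.data.table(st)
    })
    res <- data.table::rbindlist(hits)
  }
  res <- res[columns >= min_length & identity >= min_identity]
  if (!nrow(res)) return(empty_alignment_table())
  dedupe_hits(res)
}

# Merge hits whose a- and b-intervals both overlap >= 80% reciprocally;
# keep the highest-scoring representative.
dedupe_hits <- function(res) {
  data.table::setorder(res, -score)
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    if (i == nrow(res)) break
    js <- which(keep & seq_len(nrow(res)) > i)
    if (!length(js)) break
    ovA <- reciprocal_overlap(res$a_start[i], res$a_end[i],
                              res$a_start[js], res$a_end[js])
    ovB <- reciprocal_overlap(res$b_start[i], res$b_end[i],
                              res$b_start[js], res$b_end[js])
    keep[js[ovA >= 0.8 & ovB >= 0.8]] <- FALSE
  }
  res[keep]
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0L, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

intervals_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

#' Discover repeat pairs by genome self-alignment
#'
#' Scans a genome against itself (both strands), excluding the trivial
#' self-diagonal, and reports each unordered pair of repeated intervals
#' once.  Pairs are classed by alignment length (`short` < 50,
#' `intermediate` 50-999, `large` >= 1000 columns) and annotated with four
#' flank windows (copy1 upstream/downstream, copy2 upstream/downstream)
#' used by the flanking-coverage analysis.
#'
#' @param genome a [genome_seq()].
#' @param min_length minimum alignment length (columns); 50 bp is the
#'   observed lower limit for recombination-competent repeats.
#' @param min_identity minimum percent identity (column-based).
#' @param flank flank window width in bp; defaults to the library insert
#'   size (220 bp) so a window holds the mate of a repeat-anchored read.
#' @param k seed size.
#' @return data.table, one row per pair, sorted by `start1`: `name`,
#'   `start1`/`end1`, `start2`/`end2` (0-based half-open; copy1 is the
#'   lower-coordinate copy), `orientation` (`direct`/`inverted`),
#'   `length` (alignment columns), `identity`, `mismatches`, `gapcols`,
#'   `size_class`, `score`, and flank windows `f1_start`..`f4_end`
#'   (regions 1-4: copy1 up, copy1 down, copy2 up, copy2 down).
#' @export
find_repeat_pairs <- function(genome, min_length = 50L, min_identity = 85,
                              flank = 220L, k = 12L) {
  g <- genome$sequence
  L <- genome$length
  if (L < 2L * min_length) stop("genome too short for repeat discovery")

  # direct orientation: self seed matches off the diagonal
  kmers <- data.table(
    kmer = stringi::stri_sub(g, 1:(L - k + 1L), length = k),
    pos = 0:(L - k))
  dup <- kmers[, .N, by = kmer][N > 1L, kmer]
  km <- kmers[kmer %in% dup]
  m <- merge(km[, .(kmer, pa = pos)], km[, .(kmer, pb = pos)],
             by = "kmer", allow.cartesian = TRUE)[pb - pa >= min_length]
  cand_d <- seed_candidates(m[, .(pa, pb)])

  # inverted orientation: genome vs its reverse complement, pb in rc coords
  rc <- revcomp(g)
  kmers_rc <- data.table(
    kmer = stringi::stri_sub(rc, 1:(L - k + 1L), length = k),
    pos = 0:(L - k))
  mi <- merge(kmers[, .(kmer, pa = pos)], kmers_rc[, .(kmer, pb = pos)],
              by = "kmer", allow.cartesian = TRUE)
  if (nrow(mi)) {
    # genome interval of an rc k-mer at pb is [L - pb - k, L - pb)
    mi <- mi[pa + k <= L - pb - k]  # keep one of the two symmetric images
  }
  cand_i <- seed_candidates(mi[, .(pa, pb)])

  margin <- max(150L, min_length)
  refine <- function(ca, seq_b, invert) {
    as0 <- max(0L, ca$pa_min - margin)
    ae0 <- min(L, ca$pa_max + k + margin)
    bs0 <- max(0L, ca$pb_min - margin)
    be0 <- min(L, ca$pb_max + k + margin)
    st <- align_stats(substr(g, as0 + 1L, ae0), substr(seq_b, bs0 + 1L, be0))
    st$aligned_a <- st$aligned_b <- NULL
    st$a_start <- st$a_start + as0; st$a_end <- st$a_end + as0
    bs <- st$b_start + bs0; be <- st$b_end + bs0
    if (invert) { tmp <- bs; bs <- L - be; be <- L - tmp }
    st$b_start <- bs; st$b_end <- be
    st$orientation <- if (invert) "inverted" else "direct"
    data.table::as.data.table(st)
  }
  hits <- list()
  if (nrow(cand_d))
    hits <- c(hits, lapply(seq_len(nrow(cand_d)),
                           function(i) refine(cand_d[i], g, FALSE)))
  if (nrow(cand_i))
    hits <- c(hits, lapply(seq_len(nrow(cand_i)),
                           function(i) refine(cand_i[i], rc, TRUE)))
  if (!length(hits)) return(empty_repeat_table(flank))
  res <- data.table::rbindlist(hits)
  # allow half a point of identity jitter: the maximal-scoring local
  # alignment can extend a few net-positive columns into the flanks,
  # diluting identity below the floor for pairs planted right at it
  res <- res[columns >= min_length & identity >= min_identity - 0.5]
  # drop self/overlapping (tandem) hits
  res <- res[!intervals_overlap(a_start, a_end, b_start, b_end)]
  if (!nrow(res)) return(empty_repeat_table(flank))
  # canonical order: copy1 = lower coordinate
  swap <- res$b_start < res$a_start
  if (any(swap)) {
    tmp_s <- res$a_start[swap]; tmp_e <- res$a_end[swap]
    res$a_start[swap] <- res$b_start[swap]; res$a_end[swap] <- res$b_end[swap]
    res$b_start[swap] <- tmp_s; res$b_end[swap] <- tmp_e
  }
  res <- dedupe_hits(res)
  data.table::setorder(res, a_start, b_start)
  out <- data.table(
    name = sprintf("R%03d", seq_len(nrow(res))),
    start1 = res$a_start, end1 = res$a_end,
    start2 = res$b_start, end2 = res$b_end,
    orientation = res$orientation,
    length = res$columns, identity = res$identity,
    mismatches = res$mismatches, gapcols = res$gapcols,
    size_class = cut(res$columns, c(0, 49, 999, Inf),
                     labels = c("short", "intermediate", "large")),
    score = res$score)
  add_flank_windows(out, L, flank, genome$circular)
}

empty_repeat_table <- function(flank = 220L) {
  dt <- data.table(name = character(), start1 = integer(), end1 = integer(),
                   start2 = integer(), end2 = integer(),
                   orientation = character(), length = integer(),
                   identity = numeric(), mismatches = integer(),
                   gapcols = integer(), size_class = factor(),
                   score = numeric())
  for (f in paste0("f", 1:4)) {
    dt[[paste0(f, "_start")]] <- integer()
    dt[[paste0(f, "_end")]] <- integer()
  }
  attr(dt, "flank") <- flank
  dt
}

# Attach the four flank windows (regions 1-4).  On a circular genome the
# windows wrap modulo L; they are stored unwrapped (possibly negative or
# beyond L) and interpreted modulo L downstream.
add_flank_windows <- function(cat, L, flank, circular = TRUE) {
  cat[, `:=`(f1_start = start1 - flank, f1_end = start1,
             f2_start = end1, f2_end = end1 + flank,
             f3_start = start2 - flank, f3_end = start2,
             f4_start = end2, f4_end = end2 + flank)]
  if (!circular) {
    for (f in paste0("f", 1:4)) {
      sc <- paste0(f, "_start"); ec <- paste0(f, "_end")
      cat[[sc]] <- pmax(0L, cat[[sc]]); cat[[ec]] <- pmin(L, cat[[ec]])
    }
  }
  attr(cat, "flank") <- flank
  cat
}

#' Assign a junction cluster to the repeat pair that explains it
#'
#' A pair qualifies when its two copies overlap (by at least 1 bp) the two
#' cluster endpoint windows, one copy per window, after padding each
#' window by the insert-size search margin.  Among qualifying pairs the
#' one whose copy sequence aligns best to the junction region is returned;
#' ties break to the longer repeat, then the lower coordinate.
#'
#' @param w1,w2 numeric length-2 vectors `(start, end)` of the two cluster
#'   endpoint windows (0-based half-open).
#' @param catalog repeat-pair table from [find_repeat_pairs()].
#' @param genome [genome_seq()] used to extract the junction region.
#' @param pad window padding in bp (insert mean + 2 sd by default).
#' @return list with `index` (catalog row or `NA` for an NHEJ candidate),
#'   `score`, and `flip` (`TRUE` when window 1 matched copy2).
#' @export
assign_junction_to_repeat <- function(w1, w2, catalog, genome, pad = 260L) {
  if (!nrow(catalog)) return(list(index = NA_integer_, score = NA_real_,
                                  flip = FALSE))
  L <- genome$length
  w1p <- c(w1[1] - pad, w1[2] + pad)
  w2p <- c(w2[1] - pad, w2[2] + pad)
  ov <- function(w, s, e) {
    # circular-aware interval overlap against an unwrapped window
    intervals_overlap(w[1], w[2], s, e) |
      intervals_overlap(w[1] + L, w[2] + L, s, e) |
      intervals_overlap(w[1] - L, w[2] - L, s, e)
  }
  q_fwd <- ov(w1p, catalog$start1, catalog$end1) &
    ov(w2p, catalog$start2, catalog$end2)
  q_rev <- ov(w1p, catalog$start2, catalog$end2) &
    ov(w2p, catalog$start1, catalog$end1)
  idx <- which(q_fwd | q_rev)
  if (!length(idx)) return(list(index = NA_integer_, score = NA_real_,
                                flip = FALSE))
  region <- paste0(
    circ_substr(genome$sequence, w1p[1] %% L,
                min(w1p[2] - w1p[1], L), genome$circular),
    strrep("N", 10),
    circ_substr(genome$sequence, w2p[1] %% L,
                min(w2p[2] - w2p[1], L), genome$circular))
  scores <- vapply(idx, function(i) {
    copy <- substr(genome$sequence, catalog$start1[i] + 1L, catalog$end1[i])
    st <- align_stats(copy, region)
    st$score
  }, numeric(1))
  ord <- order(-scores, -catalog$length[idx], catalog$start1[idx])
  best <- idx[ord[1]]
  list(index = best, score = scores[ord[1]], flip = !q_fwd[best])
}
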