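# mapper: place 36-bp paired-end reads on the circular reference and
# classify pairs as concordant or discordant.
#
# Strategy: exact k-mer seeding with k = read_len/2 (any placement with
# <= 3 mismatches has at least one exact half-read seed, pigeonhole over
# the two halves would need k = read_len/4 for 3 errors; in practice with
# error-free defaults and the 0.1% error model the two half-seeds recover
# essentially every placement, and a read whose both halves are hit is
# found regardless).  Candidates are verified by raw-byte comparison.
# A read with several equally good placements (repeat-internal) is
# ambiguous on its own but rescued when its mate is unique: the placement
# minimising the circular fragment span is chosen.

genome_seed_index <- function(genome, k) {
  L <- genome$length
  ext <- if (genome$circular)
    paste0(genome$sequence, substr(genome$sequence, 1L, k - 1L))
  else genome$sequence
  npos <- if (genome$circular) L else L - k + 1L
  gk <- data.table(kmer = stringi::stri_sub(ext, 1:npos, length = k),
                   gpos = 0:(npos - 1L))
  data.table::setkey(gk, kmer)
  gk
}

# Mismatch counts between reads (fixed width) and genome positions.
# read_raw: raw matrix [read_len x n_reads]; gext_raw: raw vector of the
# wrap-extended genome; pos 0-based; rid indexes read columns.
count_mismatches <- function(read_raw, gext_raw, pos, rid, read_len) {
  m <- length(pos)
  mm <- integer(m)
  for (j in seq_len(read_len)) {
    mm <- mm + (gext_raw[pos + j] != read_raw[j, rid])
  }
  mm
}

#' Map paired-end reads to a circular reference
#'
#' @param pairs data.table with `qname`, `seq1`, `seq2` (fixed-length
#'   reads), e.g. from [simulate_library()] or [read_fastq_pairs()].
#' @param genome a [genome_seq()].
#' @param read_len read length (all reads must share it).
#' @param max_mm maximum mismatches tolerated per end.
#' @param insert_mean,insert_sd library geometry used for concordance
#'   limits (`insert_mean` +/- 4 sd) and rescue.
#' @param chunk candidate-verification chunk size (memory bound).
#' @return data.table, one row per input pair: placements (`pos1`,
#'   `strand1`, `mm1`, `nbest1`, likewise for end 2), directional
#'   fragment `span` (leftmost + strand read to its mate's end, modulo
#'   genome length), `circ_span` (= min(d, L - d)), `concordance`
#'   (`concordant` / `discordant` / `ambiguous` / `unmapped`) and
#'   `reason` (`distance` / `orientation` / `NA`).
#' @export
map_reads <- function(pairs, genome, read_len = 36L, max_mm = 3L,
                      insert_mean = 220, insert_sd = 20, chunk = 2000000L) {
  L <- genome$length
  k <- read_len %/% 2L
  if (L < k) stop("genome shorter than seed size")
  gk <- genome_seed_index(genome, k)
  gext <- if (genome$circular)
    paste0(genome$sequence, substr(genome$sequence, 1L, read_len - 1L))
  else genome$sequence
  gext_raw <- charToRaw(gext)

  n <- nrow(pairs)
  seqs <- c(pairs$seq1, pairs$seq2)   # rid 1..n = end1, n+1..2n = end2
  stopifnot(all(nchar(seqs) == read_len))
  n_reads <- length(seqs)
  cand_all <- vector("list", 2L)
  read_raw_by_ori <- vector("list", 2L)
  for (ori in 1:2) {
    q <- if (ori == 1L) seqs else revcomp(seqs)
    read_raw_by_ori[[ori]] <- matrix(charToRaw(paste(q, collapse = "")),
                                     nrow = read_len)
    s1 <- data.table(kmer = substr(q, 1L, k), rid = seq_len(n_reads))
    s2 <- data.table(kmer = substr(q, k + 1L, 2L * k), rid = seq_len(n_reads))
    h1 <- gk[s1, on = "kmer", nomatch = NULL][, .(rid, gpos)]
    h2 <- gk[s2, on = "kmer", nomatch = NULL][, .(rid, gpos = (gpos - k) %% L)]
    cand <- unique(rbind(h1, h2))
    if (!genome$circular) cand <- cand[gpos >= 0L & gpos + read_len <= L]
    cand[, ori := ori]
    cand_all[[ori]] <- cand
  }
  cand <- data.table::rbindlist(cand_all)
  if (!nrow(cand)) return(placements_table(pairs, NULL, L, read_len,
                                           insert_mean, insert_sd))
  # verify in chunks
  mm <- integer(nrow(cand))
  idx <- seq_len(nrow(cand))
  for (lo in seq(1L, nrow(cand), by = chunk)) {
    hi <- min(lo + chunk - 1L, nrow(cand))
    sel <- lo:hi
    o1 <- sel[cand$ori[sel] == 1L]
    o2 <- sel[cand$ori[sel] == 2L]
    if (length(o1))
      mm[o1] <- count_mismatches(read_raw_by_ori[[1L]], gext_raw,
                                 cand$gpos[o1], cand$rid[o1], read_len)
    if (length(o2))
      mm[o2] <- count_mismatches(read_raw_by_ori[[2L]], gext_raw,
                                 cand$gpos[o2], cand$rid[o2], read_len)
  }
  cand[, mm := mm]
  cand <- cand[mm <= max_mm]
  if (!nrow(cand)) return(placements_table(pairs, NULL, L, read_len,
                                           insert_mean, insert_sd))
  cand[, best := min(mm), by = rid]
  cand <- cand[mm == best]
  cand[, nbest := .N, by = rid]
  # cap pathological multi-mappers
  cand <- cand[nbest <= 50L]
  cand[, strand := ifelse(ori == 1L, "+", "-")]
  placements_table(pairs, cand, L, read_len, insert_mean, insert_sd)
}

# Resolve per-pair placements from the candidate table and classify.
placements_table <- function(pairs, cand, L, read_len, insert_mean,
                             insert_sd) {
  n <- nrow(pairs)
  out <- data.table(qname = pairs$qname,
                    pos1 = NA_integer_, strand1 = NA_character_,
                    mm1 = NA_integer_, nbest1 = 0L,
                    pos2 = NA_integer_, strand2 = NA_character_,
                    mm2 = NA_integer_, nbest2 = 0L)
  if (!is.null(cand) && nrow(cand)) {
    c1 <- cand[rid <= n]
    c2 <- cand[rid > n][, rid := rid - n]
    # cap combos per end by mismatch count then position
    data.table::setorder(c1, rid, mm, gpos)
    data.table::setorder(c2, rid, mm, gpos)
    c1 <- c1[, head(.SD, 8L), by = rid]
    c2 <- c2[, head(.SD, 8L), by = rid]
    combos <- merge(c1[, .(rid, p1 = gpos, s1 = strand, mm1 = mm, nb1 = nbest)],
                    c2[, .(rid, p2 = gpos, s2 = strand, mm2 = mm, nb2 = nbest)],
                    by = "rid", allow.cartesian = TRUE)
    if (nrow(combos)) {
      combos[, d := fragment_span(p1, s1, p2, s2, L, read_len)]
      combos[, circ := pmin(d, L - d)]
      data.table::setorder(combos, rid, circ)
      pick <- combos[, head(.SD, 1L), by = rid]
      out[pick$rid, `:=`(pos1 = pick$p1, strand1 = pick$s1, mm1 = pick$mm1,
                         nbest1 = pick$nb1, pos2 = pick$p2,
                         strand2 = pick$s2, mm2 = pick$mm2,
                         nbest2 = pick$nb2)]
    }
    # single-end info for pairs where only one end mapped
    only1 <- setdiff(unique(c1$rid), unique(c2$rid))
    if (length(only1)) {
      b <- c1[rid %in% only1][, head(.SD, 1L), by = rid]
      out[b$rid, `:=`(pos1 = b$gpos, strand1 = b$strand, mm1 = b$mm,
                      nbest1 = b$nbest)]
    }
    only2 <- setdiff(unique(c2$rid), unique(c1$rid))
    if (length(only2)) {
      b <- c2[rid %in% only2][, head(.SD, 1L), by = rid]
      out[b$rid, `:=`(pos2 = b$gpos, strand2 = b$strand, mm2 = b$mm,
                      nbest2 = b$nbest)]
    }
  }
  cls <- classify_pair(out$pos1, out$strand1, out$nbest1,
                       out$pos2, out$strand2, out$nbest2,
                       L, read_len, insert_mean, insert_sd)
  out[, `:=`(span = cls$span, circ_span = cls$circ_span,
             concordance = cls$concordance, reason = cls$reason,
             rescued1 = nbest1 > 1L & nbest2 == 1L &
               cls$concordance %in% c("concordant", "discordant"),
             rescued2 = nbest2 > 1L & nbest1 == 1L &
               cls$concordance %in% c("concordant", "discordant"))]
  out
}

# Directional fragment span: the + strand read is the fragment's left
# end; span runs from its start to the - strand mate's end, modulo L.
fragment_span <- function(p1, s1, p2, s2, L, read_len) {
  d <- ifelse(s1 == "+" & s2 == "-", (p2 + read_len - p1) %% L,
       ifelse(s1 == "-" & s2 == "+", (p1 + read_len - p2) %% L,
              pmin((p2 - p1) %% L, (p1 - p2) %% L)))
  as.numeric(d)
}

#' Classify a read-pair placement as concordant or discordant
#'
#' Concordant: both ends placed, opposite strands pointing inward, and
#' directional fragment span within `insert_mean` +/- 4 sd (circular
#' wrap-around spans count by their short arc).  Discordant-by-distance
#' means circular span above the 1-kb threshold tested downstream; the
#' threshold itself is applied by the junction detector, this function
#' only records spans.
#'
#' @param pos1,strand1,nbest1,pos2,strand2,nbest2 placement vectors
#'   (`nbest` = number of equally good placements; 0 = unmapped).
#' @param L genome length.
#' @param read_len read length.
#' @param insert_mean,insert_sd library geometry.
#' @return list of vectors `span`, `circ_span`, `concordance`, `reason`.
#' @export
classify_pair <- function(pos1, strand1, nbest1, pos2, strand2, nbest2,
                          L, read_len = 36L, insert_mean = 220,
                          insert_sd = 20) {
  span <- fragment_span(pos1, strand1, pos2, strand2, L, read_len)
  circ <- pmin(span, L - span)
  lo <- insert_mean - 4 * insert_sd
  hi <- insert_mean + 4 * insert_sd
  unmapped <- nbest1 == 0L | nbest2 == 0L | is.na(pos1) | is.na(pos2)
  ambiguous <- !unmapped & nbest1 > 1L & nbest2 > 1L
  proper <- !unmapped & !ambiguous & strand1 != strand2
  concordant <- proper & span >= lo & span <= hi
  concordance <- ifelse(unmapped, "unmapped",
                 ifelse(ambiguous, "ambiguous",
                 ifelse(concordant, "concordant", "discordant")))
  reason <- ifelse(concordance == "discordant",
                   ifelse(strand1 == strand2, "orientation", "distance"),
                   NA_character_)
  span[unmapped | ambiguous] <- NA_real_
  circ[unmapped | ambiguous] <- NA_real_
  list(span = span, circ_span = circ, concordance = concordance,
       reason = reason)
}

#' Per-base read coverage track
#'
#' Counts read bases (not fragments) from uniquely placed or mate-rescued
#' ends of non-ambiguous pairs; wraps circularly.
#'
#' @param placements table from [map_reads()].
#' @param genome [genome_seq()].
#' @param read_len read length.
#' @return integer vector of length `genome$length`; element i is depth
#'   at 0-based position i - 1.
#' @export
coverage_track <- function(placements, genome, read_len = 36L) {
  L <- genome$length
  keep <- placements$concordance %in% c("concordant", "discordant")
  use1 <- keep & (placements$nbest1 == 1L | placements$rescued1)
  use2 <- keep & (placements$nbest2 == 1L | placements$rescued2)
  starts <- c(placements$pos1[use1], placements$pos2[use2])
  if (!length(starts)) return(integer(L))
  ends <- starts + read_len
  wrap <- ends > L
  tab_s <- tabulate(starts + 1L, nbins = L)
  tab_e <- tabulate(pmin(ends, L) + 1L, nbins = L + 1L)
  delta <- c(tab_s, 0) - tab_e
  depth <- cumsum(delta)[seq_len(L)]
  if (any(wrap)) {
    we <- ends[wrap] - L
    tw <- tabulate(we, nbins = L)
    depth <- depth + rev(cumsum(rev(tw)))  # adds 1 on [0, we)
  }
  as.integer(depth)
}

#' Convert externally mapped SAM pairs to the internal placement table
#'
#' Runs the same concordance classification as [map_reads()] so SAM input
#' and the internal mapper are interchangeable downstream.
#'
#' @param sam result of [read_alignments()].
#' @param genome [genome_seq()].
#' @param read_len,insert_mean,insert_sd library geometry.
#' @return placement data.table (unique placements assumed: `nbest` = 1).
#' @export
placements_from_sam <- function(sam, genome, read_len = 36L,
                                insert_mean = 220, insert_sd = 20) {
  p <- sam$pairs
  out <- data.table(qname = p$qname,
                    pos1 = p$start1, strand1 = p$strand1, mm1 = 0L,
                    nbest1 = 1L, pos2 = p$start2, strand2 = p$strand2,
                    mm2 = 0L, nbest2 = 1L)
  cls <- classify_pair(out$pos1, out$strand1, out$nbest1, out$pos2,
                       out$strand2, out$nbest2, genome$length, read_len,
                       insert_mean, insert_sd)
  out[, `:=`(span = cls$span, circ_span = cls$circ_span,
             concordance = cls$concordance, reason = cls$reason,
             rescued1 = FALSE, rescued2 = FALSE)]
  out
}
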