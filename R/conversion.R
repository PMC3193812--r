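# conversion: heteroduplex-repair / gene-conversion analysis at
# nonidentical repeats.  Inter-copy polymorphisms are catalogued from a
# global alignment of the two copies; the recombinant consensus at those
# sites is reconstructed from junction-phased read pairs (members of the
# repeat's discordant cluster, which only recombinant molecules can
# produce); each covered site is resolved toward donor or recipient.

#' Catalog polymorphisms between the two copies of a repeat pair
#'
#' Global (end-to-end) alignment of copy1 versus copy2; every
#' non-identical column is emitted, with adjacent gap columns merged into
#' a single indel event.  Columns within `edge_guard` bp of either
#' alignment end are dropped: a discovered repeat boundary can carry a
#' few bp of flank (terminal alignment extension), and sites that close
#' to the junction cannot be separated from the junction itself.
#'
#' @param pair one catalog/truth row with `start1`/`end1`/`start2`/`end2`.
#' @param genome [genome_seq()].
#' @param edge_guard boundary exclusion in alignment columns.
#' @return data.table: `site` (event index), `type`
#'   (`SNP`/`insertion`/`deletion`, relative to copy1: an insertion is
#'   sequence present only in copy2), `column` (first alignment column of
#'   the event), `pos1`/`pos2` (0-based offsets in each copy; for an
#'   indel, the offset of the base preceding the gap), `gpos1`/`gpos2`
#'   (genome coordinates), `allele1`/`allele2` (`-` marks absence).
#'   Zero rows for identical copies.
#' @export
catalog_polymorphisms <- function(pair, genome, edge_guard = 8L) {
  s1 <- substr(genome$sequence, pair$start1 + 1L, pair$end1)
  s2 <- substr(genome$sequence, pair$start2 + 1L, pair$end2)
  st <- align_stats(s1, s2, type = "global")
  a1 <- strsplit(st$aligned_a, "")[[1]]
  a2 <- strsplit(st$aligned_b, "")[[1]]
  n <- length(a1)
  p1 <- cumsum(a1 != "-") - 1L  # copy offset at each column
  p2 <- cumsum(a2 != "-") - 1L
  events <- list()
  i <- 1L
  while (i <= n) {
    if (a1[i] == a2[i]) { i <- i + 1L; next }
    if (a1[i] != "-" && a2[i] != "-") {
      events[[length(events) + 1L]] <- data.table(
        type = "SNP", column = i, pos1 = p1[i], pos2 = p2[i],
        allele1 = a1[i], allele2 = a2[i])
      i <- i + 1L
    } else {
      gap_in_1 <- a1[i] == "-"
      j <- i
      while (j < n && (if (gap_in_1) a1[j + 1L] else a2[j + 1L]) == "-") {
        j <- j + 1L
      }
      events[[length(events) + 1L]] <- data.table(
        type = if (gap_in_1) "insertion" else "deletion", column = i,
        pos1 = if (gap_in_1) p1[i] else p1[i] - 1L,
        pos2 = if (gap_in_1) p2[i] - 1L else p2[i],
        allele1 = if (gap_in_1) "-" else paste(a1[i:j], collapse = ""),
        allele2 = if (gap_in_1) paste(a2[i:j], collapse = "") else "-")
      i <- j + 1L
    }
  }
  if (!length(events))
    return(data.table(site = integer(), type = character(),
                      column = integer(), pos1 = integer(),
                      pos2 = integer(), gpos1 = integer(),
                      gpos2 = integer(), allele1 = character(),
                      allele2 = character()))
  ev <- data.table::rbindlist(events)
  ev <- ev[ev$column > edge_guard & ev$column <= n - edge_guard]
  if (!nrow(ev))
    return(data.table(site = integer(), type = character(),
                      column = integer(), pos1 = integer(),
                      pos2 = integer(), gpos1 = integer(),
                      gpos2 = integer(), allele1 = character(),
                      allele2 = character()))
  ev[, site := .I]
  ev[, `:=`(gpos1 = pair$start1 + pos1, gpos2 = pair$start2 + pos2)]
  data.table::setcolorder(ev, c("site", "type", "column", "pos1", "pos2",
                                "gpos1", "gpos2", "allele1", "allele2"))
  ev[]
}

# Reference-forward sequence of a placed read.
forward_read <- function(seq, strand) {
  out <- seq
  neg <- strand == "-"
  if (any(neg)) out[neg] <- revcomp(seq[neg])
  out
}

#' Reconstruct the recombinant consensus at polymorphic sites
#'
#' Read pairs phased to the recombinant molecule — members of the
#' repeat's selected discordant cluster, a flank combination only the
#' recombinant possesses — are piled over the polymorphism catalog.  At
#' SNP sites each covering read votes for the copy whose allele it
#' carries (wherever the read was placed); at indel sites a read placed
#' gap-free across the indel locus of one copy votes for that copy's
#' form.  Sites with fewer than `min_reads` phased reads are `uncovered`;
#' a site without `min_agree` majority is `mixed`.
#'
#' @param placements placement table of the mutant library.
#' @param reads read-pair table (`qname`, `seq1`, `seq2`) matching the
#'   placements.
#' @param member_qnames query names of the cluster's member pairs.
#' @param polys polymorphism catalog from [catalog_polymorphisms()].
#' @param min_reads,min_agree consensus thresholds.
#' @param read_len read length.
#' @param margin bases required on each side of an indel locus for a
#'   spanning vote.
#' @return data.table: the catalog plus `n_reads`, `votes1`, `votes2`,
#'   `consensus` (`copy1`/`copy2`/`mixed`/`uncovered`).
#' @export
recombinant_consensus <- function(placements, reads, member_qnames, polys,
                                  min_reads = 5L, min_agree = 0.8,
                                  read_len = 36L, margin = 4L) {
  out <- data.table::copy(polys)
  out[, `:=`(n_reads = 0L, votes1 = 0L, votes2 = 0L,
             consensus = "uncovered")]
  if (!nrow(polys)) return(out)
  pl <- data.table::as.data.table(placements)
  pl <- pl[qname %in% member_qnames]
  if (!nrow(pl)) {
    warning("no phased reads for consensus reconstruction")
    return(out)
  }
  pl <- merge(pl, reads, by = "qname")
  ends <- rbind(
    pl[nbest1 == 1L | rescued1,
       .(pos = pos1, fseq = forward_read(seq1, strand1))],
    pl[nbest2 == 1L | rescued2,
       .(pos = pos2, fseq = forward_read(seq2, strand2))])
  if (!nrow(ends)) return(out)
  for (i in seq_len(nrow(polys))) {
    ev <- polys[i]
    v1 <- 0L; v2 <- 0L
    if (ev$type == "SNP") {
      for (g in c("gpos1", "gpos2")) {
        gp <- ev[[g]]
        cov <- ends[pos <= gp & pos + read_len > gp]
        if (!nrow(cov)) next
        base <- substr(cov$fseq, gp - cov$pos + 1L, gp - cov$pos + 1L)
        v1 <- v1 + sum(base == ev$allele1)
        v2 <- v2 + sum(base == ev$allele2)
      }
    } else {
      # gap-free spanning reads vote for the copy they were placed on:
      # an ungapped placement across the indel locus is only possible on
      # the copy whose form the read carries
      need1 <- if (ev$allele1 == "-") 1L else nchar(ev$allele1)
      need2 <- if (ev$allele2 == "-") 1L else nchar(ev$allele2)
      v1 <- nrow(ends[pos + margin <= ev$gpos1 &
                        pos + read_len - margin >= ev$gpos1 + need1])
      v2 <- nrow(ends[pos + margin <= ev$gpos2 &
                        pos + read_len - margin >= ev$gpos2 + need2])
    }
    n <- v1 + v2
    cons <- if (n < min_reads) "uncovered"
    else if (v1 / n >= min_agree) "copy1"
    else if (v2 / n >= min_agree) "copy2"
    else "mixed"
    data.table::set(out, i, c("n_reads", "votes1", "votes2", "consensus"),
                    list(as.integer(n), as.integer(v1), as.integer(v2),
                         cons))
  }
  out[]
}

#' Resolve conversion direction against the strand-invasion polarity
#'
#' @param report consensus table from [recombinant_consensus()].
#' @param donor_copy donor copy (1 or 2) from the polarity call; `NA`
#'   reports resolutions relative to copy1/copy2 only.
#' @return list: `sites` (report plus `resolution` in
#'   `donor`/`recipient`/`mixed`/`uncovered`), `summary` (counts:
#'   covered SNPs, SNPs resolved to donor, indels to donor/recipient),
#'   `verdict` (`donor-biased` when every covered SNP site resolves
#'   donor; `mixed`; `no data`; or `unpolarised`).
#' @export
resolve_direction <- function(report, donor_copy = NA_integer_) {
  sites <- data.table::copy(report)
  if (is.na(donor_copy)) {
    sites[, resolution := consensus]
    return(list(sites = sites, summary = NULL, verdict = "unpolarised"))
  }
  donor_lab <- paste0("copy", donor_copy)
  recip_lab <- paste0("copy", 3L - donor_copy)
  sites[, resolution := data.table::fcase(
    consensus == donor_lab, "donor",
    consensus == recip_lab, "recipient",
    consensus == "mixed", "mixed",
    default = "uncovered")]
  snp <- sites[type == "SNP" & resolution != "uncovered"]
  ind <- sites[type != "SNP" & resolution != "uncovered"]
  summary <- data.table(
    covered_snps = nrow(snp),
    snps_donor = sum(snp$resolution == "donor"),
    snps_recipient = sum(snp$resolution == "recipient"),
    indels_donor = sum(ind$resolution == "donor"),
    indels_recipient = sum(ind$resolution == "recipient"))
  verdict <- if (nrow(snp) == 0L) "no data"
  else if (all(snp$resolution == "donor")) "donor-biased"
  else "mixed"
  list(sites = sites, summary = summary, verdict = verdict)
}

#' Per-repeat conversion summary table
#'
#' One row per analysed repeat, mirroring a homology / corrected-SNPs /
#' indels / direction report.
#'
#' @param results named list (by repeat) of [resolve_direction()] outputs.
#' @param catalog catalog rows for the analysed repeats.
#' @return data.table.
#' @export
conversion_table <- function(results, catalog) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    idx <- which(catalog[["name"]] == nm)
    s <- r$summary
    data.table(repeat_name = nm,
               homology = round(catalog$identity[idx], 1),
               covered_snps = s$covered_snps %||% 0L,
               snps_donor = s$snps_donor %||% 0L,
               indels_donor = s$indels_donor %||% 0L,
               indels_recipient = s$indels_recipient %||% 0L,
               direction = r$verdict)
  })
  data.table::rbindlist(rows)
}
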