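# formats_io: external file formats and the shared coordinate conventions.
#
# Internally every interval is 0-based half-open; BED output keeps that
# convention, TSV/VCF reports are 1-based inclusive.

#' Construct a genome sequence object
#'
#' Light container for a (possibly circular) genome: plant mitochondrial
#' genomes map as circles even though the in-vivo molecules are mostly
#' linear and branched, so circularity is a property of the coordinate
#' system, carried here as a flag (FASTA has no circular tag).
#'
#' @param name sequence label.
#' @param sequence DNA string (A/C/G/T/N); uppercased on construction.
#' @param circular logical; treat coordinates modulo length.
#' @return object of class `genome_seq` with fields `name`, `sequence`,
#'   `circular`, `length`.
#' @export
genome_seq <- function(name, sequence, circular = TRUE) {
  sequence <- toupper(sequence)
  if (stringi::stri_count_regex(sequence, "[^ACGTN]") > 0L)
    stop("genome '", name, "': alphabet restricted to ACGTN")
  structure(
    list(name = as.character(name), sequence = sequence,
         circular = isTRUE(circular), length = nchar(sequence)),
    class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %s bp, %s\n", x$name,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @param circular circularity flag applied to every record (FASTA carries
#'   no such tag; the mitochondrial master circle is the default use case).
#' @return list of [genome_seq()] objects in file order; empty list (with a
#'   warning) for an empty file.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
  lapply(seq_along(set), function(i) {
    nm <- strsplit(names(set)[i], "\\s+")[[1]][1]
    genome_seq(nm, as.character(set[[i]]), circular = circular)
  })
}

#' Write genome sequences to FASTA
#'
#' @param genomes a [genome_seq()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_seq")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(set) <- vapply(genomes, `[[`, "", "name")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# -- SAM ingest ---------------------------------------------------------

#' Read paired-end alignments from a SAM file
#'
#' Minimal SAM reader for externally mapped reads: only QNAME, FLAG,
#' RNAME, POS, MAPQ and SEQ are used.  Mates are joined by query name;
#' records whose mate is missing are dropped and counted.
#'
#' @param path SAM file (text, with header).
#' @param genome optional [genome_seq()]; when given, alignment
#'   coordinates are validated against its length.
#' @return list with `pairs` (data.table: one row per read pair with
#'   0-based intervals `start1`/`end1`/`strand1`, `start2`/... and
#'   `mapq1`/`mapq2`) and `orphans` (dropped single-mate record count).
#' @export
read_alignments <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !any(startsWith(lines, "@")))
    stop("SAM file '", path, "' has no header")
  body <- lines[!startsWith(lines, "@")]
  if (!length(body)) return(list(pairs = empty_pair_table(), orphans = 0L))
  f <- data.table::fread(text = body, header = FALSE, sep = "\t", fill = TRUE,
                         select = 1:10,
                         col.names = c("qname", "flag", "rname", "pos",
                                       "mapq", "cigar", "rnext", "pnext",
                                       "tlen", "seq"))
  f <- f[rname != "*" & pos > 0L]
  f[, flag := as.integer(flag)]
  if (!nrow(f)) return(list(pairs = empty_pair_table(), orphans = 0L))
  if (!is.null(genome)) {
    bad <- f$pos + nchar(f$seq) - 1L > genome$length
    if (any(bad))
      stop("SAM record with coordinate outside reference: ",
           f$qname[which(bad)[1]])
  }
  f[, `:=`(start = pos - 1L, end = pos - 1L + nchar(seq),
           strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
           first = bitwAnd(flag, 64L) > 0L)]
  e1 <- f[first == TRUE]
  e2 <- f[first == FALSE]
  pairs <- merge(
    e1[, .(qname, start1 = start, end1 = end, strand1 = strand,
           mapq1 = mapq, seq1 = seq)],
    e2[, .(qname, start2 = start, end2 = end, strand2 = strand,
           mapq2 = mapq, seq2 = seq)],
    by = "qname")
  orphans <- nrow(e1) + nrow(e2) - 2L * nrow(pairs)
  list(pairs = pairs, orphans = as.integer(orphans))
}

empty_pair_table <- function() {
  data.table(qname = character(), start1 = integer(), end1 = integer(),
             strand1 = character(), mapq1 = integer(), seq1 = character(),
             start2 = integer(), end2 = integer(), strand2 = character(),
             mapq2 = integer(), seq2 = character())
}

# -- report writers -----------------------------------------------------

#' Write a repeat catalog as BED and TSV
#'
#' BED stays 0-based half-open (two records per pair sharing the name);
#' the TSV carries 1-based inclusive positions plus identity, class and
#' orientation.
#'
#' @param catalog repeat-pair table as returned by [find_repeat_pairs()].
#' @param out_prefix path prefix; writes `<prefix>.bed` and `<prefix>.tsv`.
#' @return named character vector of the written paths.
#' @export
write_repeat_catalog <- function(catalog, out_prefix) {
  bed <- rbind(
    data.table(chrom = "chrM", start = catalog$start1, end = catalog$end1,
               name = catalog$name),
    data.table(chrom = "chrM", start = catalog$start2, end = catalog$end2,
               name = catalog$name))
  data.table::setorder(bed, start)
  bed_path <- paste0(out_prefix, ".bed")
  data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  tsv <- data.table::copy(catalog)
  c1 <- coord_to_1based(tsv$start1, tsv$end1)
  c2 <- coord_to_1based(tsv$start2, tsv$end2)
  tsv[, `:=`(copy1_from = c1$pos1, copy1_to = c1$pos2,
             copy2_from = c2$pos1, copy2_to = c2$pos2,
             start1 = NULL, end1 = NULL, start2 = NULL, end2 = NULL)]
  tsv_path <- paste0(out_prefix, ".tsv")
  data.table::fwrite(tsv, tsv_path, sep = "\t")
  c(bed = bed_path, tsv = tsv_path)
}

#' Read a BED file of repeat copies
#'
#' @param path BED3+name file.
#' @return data.table with `chrom`, `start`, `end`, `name` (0-based
#'   half-open, as in the file).
#' @export
read_bed <- function(path) {
  b <- data.table::fread(path, header = FALSE, sep = "\t")
  data.table::setnames(b, seq_len(min(4L, ncol(b))),
                       c("chrom", "start", "end", "name")[seq_len(min(4L, ncol(b)))])
  b
}

#' Write junction clusters as TSV
#'
#' Windows are reported 1-based inclusive; support columns are one per
#' library.  A header-only file is written for an empty cluster set.
#'
#' @param clusters cluster table from [cluster_discordant()] /
#'   [filter_clusters()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  out <- data.table::copy(data.table::as.data.table(clusters))
  if (nrow(out)) {
    w1 <- coord_to_1based(out$w1_start, out$w1_end)
    w2 <- coord_to_1based(out$w2_start, out$w2_end)
    out[, `:=`(window1_from = w1$pos1, window1_to = w1$pos2,
               window2_from = w2$pos1, window2_to = w2$pos2,
               w1_start = NULL, w1_end = NULL,
               w2_start = NULL, w2_end = NULL)]
  } else {
    out <- data.table(cluster_id = integer(), window1_from = integer(),
                      window1_to = integer(), window2_from = integer(),
                      window2_to = integer(), orientation = character(),
                      support = integer())
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write SNP calls as a minimal VCF v4.2
#'
#' Emits CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO with `DP` (read depth) and
#' `AF` (alternate allele fraction) in INFO.  Positions are 1-based per the
#' VCF standard.
#'
#' @param snps data.table with columns `pos` (0-based), `ref`, `alt`,
#'   `depth`, `af`.
#' @param path output path.
#' @param chrom chromosome label.
#' @param genome optional [genome_seq()] for the contig header line.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snps, path, chrom = "chrM", genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(genome))
             sprintf("##contig=<ID=%s,length=%d>", chrom, genome$length),
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##INFO=<ID=AF,Number=1,Type=Float,Description="Allele fraction">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(snps)) {
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f",
                    chrom, snps$pos + 1L, snps$ref, snps$alt,
                    snps$depth, snps$af)
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a minimal VCF written by [write_vcf()]
#'
#' @param path VCF path.
#' @return data.table with `pos` (0-based), `ref`, `alt`, `depth`, `af`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.table(pos = integer(), ref = character(), alt = character(),
                      depth = integer(), af = numeric()))
  f <- data.table::fread(text = body, header = FALSE, sep = "\t")
  info <- f$V8
  data.table(
    pos = f$V2 - 1L, ref = f$V4, alt = f$V5,
    depth = as.integer(sub(".*DP=([0-9]+).*", "\\1", info)),
    af = as.numeric(sub(".*AF=([0-9.]+).*", "\\1", info)))
}

#' Write a coverage track as bedGraph
#'
#' @param depth integer vector of per-base depth (position 1 = genome
#'   coordinate 0).
#' @param path output path.
#' @param chrom chromosome label.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(depth, path, chrom = "chrM") {
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.table::fwrite(
    data.table(chrom = chrom, start = starts, end = ends, value = r$values),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write results tables for a pipeline run
#'
#' One call per pipeline; dispatches on the named elements present in
#' `results`: `catalog`, `clusters`, `snps`, `tree` (an `ape::phylo`),
#' plus any plain data.tables which are written as TSV under their name.
#'
#' @param results named list of result objects.
#' @param out_dir output directory (created if missing).
#' @return named character vector of written paths.
#' @export
write_tables <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  paths <- character()
  for (nm in names(results)) {
    obj <- results[[nm]]
    if (is.null(obj)) next
    if (nm == "catalog") {
      paths <- c(paths, write_repeat_catalog(obj, file.path(out_dir, "repeats")))
    } else if (nm == "clusters") {
      p <- file.path(out_dir, "clusters.tsv")
      write_cluster_table(obj, p)
      paths <- c(paths, clusters = p)
    } else if (nm == "snps") {
      p <- file.path(out_dir, paste0(nm, ".vcf"))
      write_vcf(obj, p)
      paths <- c(paths, snps = p)
    } else if (inherits(obj, "phylo")) {
      p <- file.path(out_dir, paste0(nm, ".nwk"))
      ape::write.tree(obj, p)
      paths <- c(paths, setNames(p, nm))
    } else if (is.data.frame(obj)) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      data.table::fwrite(report_1based(obj), p, sep = "\t")
      paths <- c(paths, setNames(p, nm))
    }
  }
  paths
}

# Convert any *_start/*_end 0-based column pairs of a report table to
# 1-based inclusive *_from/*_to for human-facing TSV.
report_1based <- function(dt) {
  dt <- data.table::as.data.table(data.table::copy(dt))
  scols <- grep("(_|^)start[0-9]*$", names(dt), value = TRUE)
  for (sc in scols) {
    ec <- sub("start", "end", sc)
    if (!ec %in% names(dt)) next
    conv <- coord_to_1based(dt[[sc]], dt[[ec]])
    data.table::set(dt, j = sub("start", "from", sc), value = conv$pos1)
    data.table::set(dt, j = sub("end", "to", ec), value = conv$pos2)
    data.table::set(dt, j = c(sc, ec), value = NULL)
  }
  dt
}
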