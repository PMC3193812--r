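# synthetic_data: paired-end read library simulation.
#
# Fragments are drawn from a weighted mixture of the parental circular
# genome and per-repeat recombinant molecules.  A recombinant fraction f
# for a repeat means recombinant fragment depth at the junction locus is
# f times the parental per-base fragment depth.  For class I repeats the
# donor parental environment is additionally thinned by (1 - f), so gain
# of the recombinant mirrors loss of the invading-strand parental form.

#' Specify a sequencing library
#'
#' @param condition `"WT"`, `"msh1_gen1"` or `"msh1_adv"`; selects which
#'   per-repeat recombinant fractions of the catalog apply (WT uses the
#'   `ghost` level).
#' @param coverage fold read coverage (read bases per genome base).  The
#'   study's libraries ran at roughly 600x/200x; the desk-scale default is
#'   50x.
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd fragment-size distribution (normal,
#'   truncated to `[2*read_len, insert_mean + 4*insert_sd]`).
#' @param error_rate per-base substitution error rate (default 0; the
#'   detectors are expected to tolerate 0.001).
#' @param ghost trace recombinant level in wild type (ghost bands);
#'   must be <= 0.001.
#' @return `library_spec` list.
#' @export
library_spec <- function(condition = c("WT", "msh1_gen1", "msh1_adv"),
                         coverage = 50, read_len = 36L, insert_mean = 220,
                         insert_sd = 20, error_rate = 0, ghost = 0) {
  condition <- match.arg(condition)
  stopifnot(coverage > 0, ghost >= 0, ghost <= 0.001,
            error_rate >= 0, error_rate < 0.05)
  structure(list(condition = condition, coverage = coverage,
                 read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, ghost = ghost),
            class = "library_spec")
}

# Per-repeat recombinant fraction for a library condition.
catalog_fractions <- function(truth, condition, ghost = 0) {
  f <- switch(condition,
              WT = rep(ghost, nrow(truth)),
              msh1_gen1 = truth$frac_gen1,
              msh1_adv = truth$frac_adv)
  bad <- f > truth$frac_adv + 1e-9 & condition == "msh1_gen1"
  setNames(f, truth$name)
}

draw_inserts <- function(n, spec) {
  lo <- 2L * spec$read_len
  hi <- spec$insert_mean + 4 * spec$insert_sd
  x <- round(rnorm(n, spec$insert_mean, spec$insert_sd))
  pmin(pmax(x, lo), hi)
}

#' Simulate a paired-end library
#'
#' @param ref reference bundle from [build_reference()].
#' @param recombinants list of molecules from [make_recombinant()]; give
#'   `list()` for a pure parental library.
#' @param spec a [library_spec()].
#' @param seed integer seed; identical seed and spec give byte-identical
#'   output.
#' @param fractions optional named per-repeat recombinant fractions
#'   overriding the catalog defaults for this condition.
#' @return list with `pairs` (data.table `qname`, `seq1`, `seq2`) and
#'   `truth` (per-fragment: molecule, fragment start in molecule
#'   coordinates, insert size, `straddles` = spans a recombinant
#'   junction).
#' @export
simulate_library <- function(ref, recombinants = list(), spec = library_spec(),
                             seed = 1L, fractions = NULL) {
  stopifnot(inherits(spec, "library_spec"))
  L <- ref$genome$length
  rl <- spec$read_len
  fr <- fractions %||% catalog_fractions(ref$truth, spec$condition, spec$ghost)
  for (m in recombinants) {
    if (!m$name %in% names(fr))
      stop("recombinant fraction requested for repeat '", m$name,
           "' absent from truth")
  }
  with_seed(derive_seed(seed, 2L + match(spec$condition,
                                         c("WT", "msh1_gen1", "msh1_adv"))), {
    n_par <- round(spec$coverage * L / (2 * rl))
    par_start <- sample.int(L, n_par, replace = TRUE) - 1L
    par_ins <- draw_inserts(n_par, spec)
    keep <- rep(TRUE, n_par)
    # class I: thin the donor parental environment by (1 - f)
    for (m in recombinants) {
      row <- ref$truth[ref$truth$name == m$name]
      f <- fr[[m$name]]
      if (is.na(row$fate_class) || row$fate_class != "I" || f <= 0) next
      ds <- if (m$donor == 1L) row$start1 else row$start2
      de <- if (m$donor == 1L) row$end1 else row$end2
      w_lo <- ds - spec$insert_mean
      frag_end <- par_start + par_ins
      hit <- (par_start < de & frag_end > w_lo) |
        (par_start - L < de & frag_end - L > w_lo) |
        (par_start + L < de & frag_end + L > w_lo)
      thin <- hit & runif(n_par) < f
      keep <- keep & !thin
    }
    frag <- data.table(molecule = "parental", mol_idx = 0L,
                       start = par_start[keep], insert = par_ins[keep])
    lambda <- n_par / L  # parental fragment starts per bp
    for (k in seq_along(recombinants)) {
      m <- recombinants[[k]]
      f <- fr[[m$name]]
      if (f <= 0) next
      mol_len <- nchar(m$sequence)
      usable <- mol_len - spec$insert_mean
      n_rec <- rpois(1L, f * lambda * usable)
      if (n_rec == 0L) next
      ins <- draw_inserts(n_rec, spec)
      st <- floor(runif(n_rec) * pmax(1L, mol_len - ins))
      frag <- rbind(frag, data.table(molecule = m$name, mol_idx = k,
                                     start = as.integer(st), insert = ins))
    }
    mol_seqs <- c(list(ref$genome$sequence),
                  lapply(recombinants, `[[`, "sequence"))
    n <- nrow(frag)
    seq1 <- character(n); seq2 <- character(n)
    for (k in unique(frag$mol_idx)) {
      idx <- which(frag$mol_idx == k)
      s <- mol_seqs[[k + 1L]]
      circ <- k == 0L && ref$genome$circular
      seq1[idx] <- circ_substr(s, frag$start[idx], rl, circ)
      seq2[idx] <- revcomp(circ_substr(s, frag$start[idx] + frag$insert[idx] - rl,
                                       rl, circ))
    }
    if (spec$error_rate > 0) {
      seq1 <- add_errors(seq1, spec$error_rate)
      seq2 <- add_errors(seq2, spec$error_rate)
    }
    # junction-straddling truth: both reads clear of every junction but the
    # fragment spans one (recombinant molecules only)
    straddles <- rep(FALSE, n)
    for (k in seq_along(recombinants)) {
      m <- recombinants[[k]]
      idx <- which(frag$mol_idx == k)
      if (!length(idx)) next
      j1 <- m$repeat_start; j2 <- m$repeat_start + m$repeat_len
      fs <- frag$start[idx]; fe <- fs + frag$insert[idx]
      straddles[idx] <- fs + rl <= j1 & fe - rl >= j2
    }
    frag[, straddles := straddles]
    # random mate order so /1 is not always the leftmost read
    flip <- runif(n) < 0.5
    tmp <- seq1[flip]; seq1[flip] <- seq2[flip]; seq2[flip] <- tmp
    qname <- sprintf("sim_%s_%07d", spec$condition, seq_len(n))
    frag[, `:=`(qname = qname, flipped = flip)]
    list(pairs = data.table(qname = qname, seq1 = seq1, seq2 = seq2),
         truth = frag, spec = spec)
  })
}

add_errors <- function(seqs, rate) {
  n_bases <- sum(nchar(seqs))
  n_err <- rpois(1L, rate * n_bases)
  if (n_err == 0L) return(seqs)
  rl <- nchar(seqs[1])
  at_read <- sample.int(length(seqs), n_err, replace = TRUE)
  at_pos <- sample.int(rl, n_err, replace = TRUE)
  for (i in seq_len(n_err)) {
    old <- substr(seqs[at_read[i]], at_pos[i], at_pos[i])
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    stringi::stri_sub(seqs[at_read[i]], at_pos[i], at_pos[i]) <- new
  }
  seqs
}

#' Write a simulated library as a FASTQ pair
#'
#' @param lib result of [simulate_library()].
#' @param prefix output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` with constant quality `I`.
#' @return character vector of the two paths.
#' @export
write_fastq <- function(lib, prefix) {
  p1 <- paste0(prefix, "_1.fastq"); p2 <- paste0(prefix, "_2.fastq")
  q <- strrep("I", nchar(lib$pairs$seq1[1] %||% ""))
  writeLines(paste0("@", lib$pairs$qname, "/1\n", lib$pairs$seq1, "\n+\n",
                    strrep("I", nchar(lib$pairs$seq1))), p1)
  writeLines(paste0("@", lib$pairs$qname, "/2\n", lib$pairs$seq2, "\n+\n",
                    strrep("I", nchar(lib$pairs$seq2))), p2)
  c(p1, p2)
}

#' Read a FASTQ pair back into the in-memory pair table
#'
#' @param path1,path2 FASTQ files for mates 1 and 2.
#' @return data.table `qname`, `seq1`, `seq2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  l1 <- readLines(path1); l2 <- readLines(path2)
  q1 <- sub("/[12]$", "", sub("^@", "", l1[seq(1, length(l1), 4)]))
  q2 <- sub("/[12]$", "", sub("^@", "", l2[seq(1, length(l2), 4)]))
  s1 <- l1[seq(2, length(l1), 4)]
  s2 <- l2[seq(2, length(l2), 4)]
  dt <- merge(data.table(qname = q1, seq1 = s1),
              data.table(qname = q2, seq2 = s2), by = "qname")
  dt
}
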