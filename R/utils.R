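#' @import data.table
#' @importFrom stats median rnorm runif rpois setNames quantile cor
#' @importFrom utils head tail write.table read.table
NULL

# Internal coordinate convention: 0-based half-open [start, end).
# All user-facing tables are converted to 1-based inclusive on output.

#' Convert 0-based half-open coordinates to 1-based inclusive
#'
#' @param start,end integer vectors, 0-based half-open.
#' @return data.table with columns `pos1` (first base, 1-based) and `pos2`
#'   (last base, 1-based inclusive).
#' @export
coord_to_1based <- function(start, end) {
  stopifnot(all(end > start))
  data.table(pos1 = as.integer(start + 1L), pos2 = as.integer(end))
}

#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' Inverse of [coord_to_1based()].
#'
#' @param pos1,pos2 integer vectors, 1-based inclusive.
#' @return data.table with columns `start` and `end` (0-based half-open).
#' @export
coord_to_0based <- function(pos1, pos2) {
  stopifnot(all(pos2 >= pos1))
  data.table(start = as.integer(pos1 - 1L), end = as.integer(pos2))
}

#' Circular distance between two positions
#'
#' Shortest distance between positions on a circle of length `L`:
#' `min(d, L - d)`.
#'
#' @param a,b positions (any shared base).
#' @param L genome length in bp.
#' @param circular if `FALSE`, plain `abs(a - b)`.
#' @return numeric vector of distances.
#' @export
circular_distance <- function(a, b, L, circular = TRUE) {
  d <- abs(a - b)
  if (!circular) return(d)
  pmin(d, L - d)
}

# Derive a reproducible sub-seed from a master seed.  Offsets are fixed per
# generator so that independent components draw from independent streams.
# Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1000003) %% 2147483587L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

# Reverse complement of a plain character vector of DNA strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Vectorised substring extraction on a circular sequence.  `start` is
# 0-based; `width` fixed.  The caller must ensure width <= nchar(seq).
circ_substr <- function(seq, start, width, circular = TRUE) {
  L <- nchar(seq)
  if (circular) {
    ext <- paste0(seq, substr(seq, 1L, min(L, max(width))))
    start <- start %% L
    stringi::stri_sub(ext, from = start + 1L, length = width)
  } else {
    stringi::stri_sub(seq, from = start + 1L, length = width)
  }
}

# Simple stage logger to stderr.
log_stage <- function(stage, ...) {
  msg <- paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", stage, ": ",
                paste0(..., collapse = ""))
  message(msg)
  invisible(msg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
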