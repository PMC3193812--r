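# synthetic_data: the packaged repeat catalog.
#
# The default catalog emulates the documented structure of the Arabidopsis
# mitochondrial intermediate-repeat complement: 33 previously known pairs
# of 108-556 bp, 14 newly found pairs of 50-250 bp at 85-98 percent
# identity (smaller repeats more identical), a large (> 1 kb) identical
# pair that recombines reciprocally and is therefore never given an
# asymmetric recombinant, and sub-50-bp decoy pairs that must never be
# called active.
#
# Detectability constraint baked into the catalog: with 36-bp reads and
# 220 +/- 20 bp inserts, a junction at an identical repeat is witnessed
# only by read pairs anchored across both repeat edges, which exist only
# for repeats shorter than about insert - 2*read_len.  Identical pairs
# are therefore planted only at the short end of the known range; longer
# pairs are nonidentical, with polymorphic sites placed where the library
# geometry can see them (see mutate_copy).

#' Specify one repeat pair for the generator
#'
#' @param name repeat label.
#' @param length copy1 length in bp.
#' @param identity target percent identity between the copies (column
#'   based, gaps in the denominator).  The realised identity uses the
#'   nearest whole substitution count.
#' @param n_indels number of single-nucleotide insertions carried by
#'   copy2 relative to copy1.
#' @param fate_class `"I"`, `"II"` or `NA` (no recombinant planted).
#' @param donor which copy donates the invading strand (1 or 2).
#' @param novel logical, marks the newly identified subset.
#' @param frac_gen1,frac_adv recombinant fraction of locus depth in the
#'   first- and advanced-generation mutant libraries.
#' @param orientation `"direct"` or `"inverted"`.
#' @return one-row data.table.
#' @export
repeat_spec <- function(name, length, identity = 100, n_indels = 0L,
                        fate_class = NA_character_, donor = 1L,
                        novel = FALSE, frac_gen1 = 0, frac_adv = 0,
                        orientation = "direct") {
  stopifnot(length >= 10, identity > 0, identity <= 100, donor %in% 1:2)
  n_sub <- n_substitutions(length, identity, n_indels)
  realised <- 100 * (length - n_sub) / (length + n_indels)
  data.table(name = name, length = as.integer(length),
             identity = realised, target_identity = identity,
             n_sub = n_sub, n_indels = as.integer(n_indels),
             fate_class = fate_class, donor = as.integer(donor),
             novel = novel, frac_gen1 = frac_gen1, frac_adv = frac_adv,
             orientation = orientation)
}

# Substitution count that realises `identity`: columns = length + n_indels,
# matches = length - n_sub, so n_sub is the nearest whole count.
n_substitutions <- function(length, identity, n_indels = 0L) {
  cols <- length + n_indels
  n <- round(cols * (1 - identity / 100)) - n_indels
  as.integer(max(0L, n))
}

#' The packaged intermediate-repeat catalog
#'
#' 47 recombination-competent intermediate pairs (33 known, 108-556 bp;
#' 14 novel, 50-250 bp at 85-98 percent identity with the smallest pairs
#' the most identical), one 2-kb identical large pair, and six 40-bp
#' identical decoy pairs below the recombination size floor.  Pair `CC`
#' carries the worked-example polymorphism set (three SNPs and one
#' single-nucleotide insertion).  Eight known pairs are class II, the
#' rest class I; donors alternate between copies.  Recombinant fractions
#' are fixed per pair: class I pairs accumulate the recombinant to high
#' level in the advanced generation (~0.6-0.7 of locus depth) while losing
#' the donor parental form; class II pairs accumulate it moderately
#' (~0.4-0.5) and retain both parentals.
#'
#' @return data.table of repeat specifications (see [repeat_spec()]).
#' @export
default_repeat_catalog <- function() {
  known_names <- c(LETTERS, paste0(LETTERS[1:7], LETTERS[1:7]))  # A..Z,AA..GG
  n_known <- 33L
  known_len <- round(seq(108, 556, length.out = n_known))
  known_len[n_known] <- 556L
  # identical pairs only below the junction-anchoring limit; the rest
  # nonidentical with targets cycling a plausible range
  ident_cycle <- c(98, 96, 94, 92)
  known_ident <- ident_cycle[(seq_len(n_known) - 1L) %% 4L + 1L]
  known_ident[1:2] <- 100
  classII_idx <- c(2L, 6L, 10L, 14L, 18L, 22L, 26L, 30L)
  rows <- lapply(seq_len(n_known), function(i) {
    nm <- known_names[i]
    cls <- if (i %in% classII_idx) "II" else "I"
    jit <- ((i %% 3L) - 1L) * 0.02
    if (cls == "I") { fg <- 0.32 + jit; fa <- 0.65 + jit }
    else            { fg <- 0.30 + jit; fa <- 0.45 + jit }
    repeat_spec(nm, known_len[i], known_ident[i],
                n_indels = if (known_ident[i] < 100 && i %% 6L == 0L) 1L else 0L,
                fate_class = cls, donor = if (i %% 2L) 1L else 2L,
                novel = FALSE, frac_gen1 = fg, frac_adv = fa)
  })
  # worked-example pair CC: 3 SNPs + 1 single-nucleotide insertion, 200 bp
  cc <- which(known_names[seq_len(n_known)] == "CC")
  rows[[cc]] <- repeat_spec("CC", 200L, 100 * 197 / 201, n_indels = 1L,
                            fate_class = "I", donor = 1L, novel = FALSE,
                            frac_gen1 = 0.32, frac_adv = 0.65)
  novel_len <- round(seq(50, 250, length.out = 14))
  # 50 bp -> 98%, 250 bp -> 85.2%; realised identities stay >= 85 after
  # rounding the substitution count, keeping the whole subset reportable
  # at the 85% discovery floor.
  novel_ident <- 98 - (novel_len - 50) * 12.8 / 200
  nrows <- lapply(1:14, function(i) {
    cls <- if (i %% 5L == 0L) "II" else "I"
    jit <- ((i %% 3L) - 1L) * 0.02
    if (cls == "I") { fg <- 0.34 + jit; fa <- 0.68 + jit }
    else            { fg <- 0.30 + jit; fa <- 0.42 + jit }
    repeat_spec(sprintf("N%02d", i), novel_len[i], novel_ident[i],
                fate_class = cls, donor = if (i %% 2L) 2L else 1L,
                novel = TRUE, frac_gen1 = fg, frac_adv = fa)
  })
  large <- repeat_spec("LR1", 2000L, 100)
  decoys <- lapply(1:6, function(i)
    repeat_spec(sprintf("D%02d", i), 40L, 100))
  data.table::rbindlist(c(rows, nrows, list(large), decoys))
}
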