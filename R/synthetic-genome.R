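# synthetic_data: reference genome construction and recombinant molecules.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mutate copy1 into copy2: n_sub substitutions plus n_indels single-base
# insertions.  Placement rules reflect what the 36-bp / 220-bp library
# geometry can observe: sites stay >= `edge` bp from either end (so
# junction assignment is not confounded); for repeats long enough that
# edge-anchored read pairs cannot witness the junction (>= 160 bp), three
# substitutions are guaranteed inside the upstream-proximal zone
# (offsets ~15/60/105) so allele-anchored reads map uniquely to the donor
# copy; insertions stay within ~160 bp of the upstream edge so phased
# reads can span them; and a 14-bp identical block is always left intact
# so both copies share an exact discovery seed regardless of substitution
# density.
mutate_copy <- function(seq1, n_sub, n_indels, edge = 10L, anchor = 14L) {
  len <- nchar(seq1)
  interior <- (edge + 1L):(len - edge)
  if (length(interior) < n_sub + n_indels + anchor)
    stop("repeat too short for requested polymorphism count")
  pick_sites <- function() {
    zone <- integer()
    if (len >= 160L && n_sub >= 3L)
      zone <- pmin(len - edge, pmax(edge + 1L,
        c(15L, 60L, 105L) + sample(-7:7, 3L, replace = TRUE)))
    rest_n <- n_sub - length(zone)
    avail <- setdiff(interior, zone)
    rest <- if (rest_n > 0L) sample(avail, rest_n) else integer()
    ins_zone <- interior[interior <= min(len - edge, 160L)]
    ins <- if (n_indels > 0L)
      sample(setdiff(ins_zone, c(zone, rest)), n_indels) else integer()
    list(sub = sort(c(zone, rest)), ins = sort(ins))
  }
  ok <- FALSE
  for (try in 1:200) {
    st <- pick_sites()
    all_sites <- c(st$sub, st$ins)
    if (anyDuplicated(all_sites)) next
    # require an untouched run of `anchor` bp somewhere in the interior
    occupied <- sort(unique(all_sites))
    gaps <- diff(c(edge, occupied, len - edge + 1L))
    if (max(gaps) > anchor + 1L) { ok <- TRUE; break }
  }
  if (!ok) stop("cannot place polymorphisms while keeping a seed anchor")
  sub_sites <- st$sub
  ins_sites <- st$ins
  chars <- strsplit(seq1, "")[[1]]
  alleles1 <- character(); alleles2 <- character()
  for (s in sub_sites) {
    old <- chars[s]
    chars[s] <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    alleles1 <- c(alleles1, old); alleles2 <- c(alleles2, chars[s])
  }
  out <- character(0)
  prev <- 1L
  poly <- data.table(type = character(), pos1 = integer(), offset2 = integer(),
                     allele1 = character(), allele2 = character())
  if (length(sub_sites))
    poly <- rbind(poly, data.table(type = "SNP", pos1 = sub_sites - 1L,
                                   offset2 = NA_integer_,
                                   allele1 = alleles1, allele2 = alleles2))
  # insertions: inserted base goes after position s in copy1 coordinates
  shift <- 0L
  seq2 <- chars
  for (s in sort(ins_sites)) {
    base <- sample(c("A", "C", "G", "T"), 1L)
    seq2 <- append(seq2, base, after = s + shift)
    poly <- rbind(poly, data.table(type = "insertion", pos1 = s - 1L,
                                   offset2 = shift, allele1 = "-",
                                   allele2 = base))
    shift <- shift + 1L
  }
  list(seq2 = paste(seq2, collapse = ""), poly = poly)
}

#' Build a reference genome with a planted repeat catalog
#'
#' Generates a random background genome and embeds every catalog pair:
#' copy1 is fresh random sequence, copy2 is copy1 mutated to the target
#' identity (substitutions plus single-base insertions).  Placement keeps
#' 450 bp between any two repeat intervals (so flank windows stay clean
#' and a recombinant molecule's 400-bp flank can never reach into a
#' neighbouring copy) and at least 2.5 kb between the two copies of a
#' pair (so recombinant junctions exceed the 1-kb discordance span with
#' margin).
#'
#' @param genome_length genome size in bp (default 100 kb: desk-scale
#'   stand-in for the ~360-kb mitochondrial genome).
#' @param catalog repeat specification table ([default_repeat_catalog()]).
#' @param seed integer seed; the build is fully deterministic given it.
#' @param name genome label.
#' @param circular circularity flag for the product.
#' @return list with `genome` ([genome_seq()]), `truth` (catalog with
#'   realised 0-based coordinates and flank windows), and `polymorphisms`
#'   (per-site truth for nonidentical pairs: alignment site positions and
#'   both alleles).
#' @export
build_reference <- function(genome_length = 100000L,
                            catalog = default_repeat_catalog(),
                            seed = 1L, name = "chrM", circular = TRUE) {
  with_seed(derive_seed(seed, 1L), {
    cat <- data.table::copy(data.table::as.data.table(catalog))
    copy_len2 <- cat$length + cat$n_indels
    total <- sum(cat$length + copy_len2)
    gap <- 450L
    n_slots <- 2L * nrow(cat)
    margin <- 600L
    if (total + (n_slots + 1L) * gap + 2L * margin > genome_length)
      stop("catalog does not fit in ", genome_length, " bp: needs at least ",
           total + (n_slots + 1L) * gap + 2L * margin)
    lens <- c(cat$length, copy_len2)  # slot i: copy1 of pair i; n+i: copy2
    ok <- FALSE
    for (try in 1:100) {
      ord <- sample(n_slots)
      slack <- genome_length - 2L * margin - total - (n_slots - 1L) * gap
      cuts <- sort(sample.int(slack + 1L, n_slots, replace = TRUE)) - 1L
      starts_ordered <- margin + cuts + (seq_len(n_slots) - 1L) * gap +
        cumsum(c(0L, lens[ord][-n_slots]))
      starts <- integer(n_slots)
      starts[ord] <- starts_ordered
      s1 <- starts[seq_len(nrow(cat))]
      s2 <- starts[nrow(cat) + seq_len(nrow(cat))]
      d <- circular_distance(s1, s2, genome_length)
      if (all(d >= 2500L | cat$length < 50L)) { ok <- TRUE; break }
    }
    if (!ok) stop("infeasible placement: copies of some pair end up closer ",
                  "than 2.5 kb; conflicting specs: ",
                  paste(cat$name[circular_distance(s1, s2, genome_length) < 2500L],
                        collapse = ", "))
    genome <- random_dna(genome_length)
    polys <- list()
    seq2s <- character(nrow(cat))
    seq1s <- character(nrow(cat))
    for (i in seq_len(nrow(cat))) {
      seq1 <- random_dna(cat$length[i])
      if (cat$n_sub[i] + cat$n_indels[i] > 0L) {
        m <- mutate_copy(seq1, cat$n_sub[i], cat$n_indels[i])
        seq2 <- m$seq2
        if (nrow(m$poly)) {
          p <- m$poly
          p[, name := cat$name[i]]
          polys[[length(polys) + 1L]] <- p
        }
      } else {
        seq2 <- seq1
      }
      if (cat$orientation[i] == "inverted") seq2 <- revcomp(seq2)
      seq1s[i] <- seq1; seq2s[i] <- seq2
    }
    # canonical copy1 = lower coordinate
    flip <- s2 < s1
    start1 <- ifelse(flip, s2, s1)
    start2 <- ifelse(flip, s1, s2)
    len1 <- ifelse(flip, copy_len2, cat$length)
    len2 <- ifelse(flip, cat$length, copy_len2)
    seqA <- ifelse(flip, seq2s, seq1s)
    seqB <- ifelse(flip, seq1s, seq2s)
    for (i in seq_len(nrow(cat))) {
      stringi::stri_sub(genome, start1[i] + 1L, length = len1[i]) <- seqA[i]
      stringi::stri_sub(genome, start2[i] + 1L, length = len2[i]) <- seqB[i]
    }
    truth <- data.table::copy(cat)
    truth[, `:=`(start1 = as.integer(start1), end1 = as.integer(start1 + len1),
                 start2 = as.integer(start2), end2 = as.integer(start2 + len2),
                 copy1_is_spec_copy1 = !flip)]
    truth <- add_flank_windows(truth, genome_length, 220L, circular)
    poly_dt <- if (length(polys)) data.table::rbindlist(polys) else
      data.table(type = character(), pos1 = integer(), offset2 = integer(),
                 allele1 = character(), allele2 = character(),
                 name = character())
    list(genome = genome_seq(name, genome, circular), truth = truth,
         polymorphisms = poly_dt)
  })
}

# Sequence of one planted copy, straight from the reference.
copy_sequence <- function(ref, row, which_copy) {
  s <- if (which_copy == 1L) row$start1 else row$start2
  e <- if (which_copy == 1L) row$end1 else row$end2
  substr(ref$genome$sequence, s + 1L, e)
}

#' Build the asymmetric recombinant molecule for a repeat pair
#'
#' Produces exactly one of the two possible crossover products: the
#' molecule joins the recipient copy's upstream flank to the donor copy's
#' downstream flank through one repeat interval whose polymorphic sites
#' carry donor alleles (heteroduplex mismatch repair biased to the donor
#' strand).  Requesting both reciprocal products is an error: the model
#' is asymmetric by construction.
#'
#' @param ref reference bundle from [build_reference()].
#' @param name repeat name in the catalog.
#' @param flank_len flank length carried on each side of the molecule
#'   (must exceed the library insert size so junction-spanning fragments
#'   fit entirely inside the molecule).
#' @param product `"primary"` (the polarity-dictated product),
#'   `"reciprocal"` (the opposite product, for anomaly testing), or
#'   `"both"` (error).
#' @param indel_origin `"donor"` or `"recipient"`: which copy's allele the
#'   recombinant carries at insertion sites (SNP sites always resolve to
#'   the donor; indel resolution showed no consistent direction).
#' @return list: `name`, `sequence`, `donor`, `recipient`, junction anchor
#'   intervals in reference coordinates (`left_start`/`left_end` = the
#'   recipient-upstream flank, `right_start`/`right_end` = the
#'   donor-downstream flank), `repeat_start` (offset of the repeat within
#'   the molecule), and `site_origin` (per-polymorphism allele origin).
#' @export
make_recombinant <- function(ref, name, flank_len = 400L,
                             product = c("primary", "reciprocal", "both"),
                             indel_origin = c("donor", "recipient")) {
  product <- match.arg(product)
  if (product == "both")
    stop("asymmetric model: only one crossover product exists per repeat; ",
         "request 'primary' or 'reciprocal', not 'both'")
  indel_origin <- match.arg(indel_origin)
  row_i <- which(ref$truth[["name"]] == name)
  row <- ref$truth[row_i]
  if (!nrow(row)) stop("repeat '", name, "' not in catalog truth")
  if (row$length < 50L)
    stop("repeat '", name, "' is below the 50-bp recombination floor")
  if (row$orientation != "direct")
    stop("recombinant construction supports direct-orientation pairs only")
  donor_spec <- row$donor
  if (product == "reciprocal") donor_spec <- 3L - donor_spec
  # spec copy numbering follows the catalog; coordinates may have swapped
  donor <- if (row$copy1_is_spec_copy1) donor_spec else 3L - donor_spec
  recipient <- 3L - donor
  g <- ref$genome$sequence
  L <- ref$genome$length
  r_start <- if (recipient == 1L) row$start1 else row$start2
  d_end <- if (donor == 1L) row$end1 else row$end2
  up <- circ_substr(g, (r_start - flank_len) %% L, flank_len,
                    ref$genome$circular)
  down <- circ_substr(g, d_end %% L, flank_len, ref$genome$circular)
  rep_seq <- copy_sequence(ref, row, donor)
  site_origin <- NULL
  poly_i <- which(ref$polymorphisms[["name"]] == name)
  polys <- ref$polymorphisms[poly_i]
  if (nrow(polys)) {
    site_origin <- data.table::copy(polys)
    site_origin[, origin := "donor"]
    if (indel_origin == "recipient" && any(polys$type != "SNP")) {
      # switch indel sites to the recipient form; the donor copy is the
      # insertion carrier only when donor is the spec's copy2
      rep_chars <- strsplit(rep_seq, "")[[1]]
      ins <- which(polys$type == "insertion")
      donor_is_spec2 <- donor_spec == 2L
      for (j in rev(ins)) {
        at <- polys$pos1[j] + (polys$offset2[j] %||% 0L)
        if (donor_is_spec2) {
          rep_chars <- rep_chars[-(at + 1L + 1L)]  # drop inserted base
        } else {
          rep_chars <- append(rep_chars, polys$allele2[j], after = at + 1L)
        }
        site_origin$origin[j] <- "recipient"
      }
      rep_seq <- paste(rep_chars, collapse = "")
    }
  }
  list(name = name, sequence = paste0(up, rep_seq, down),
       donor = donor, recipient = recipient, donor_spec = donor_spec,
       left_start = (r_start - flank_len) %% L, left_end = r_start,
       right_start = d_end %% L, right_end = (d_end + flank_len) %% L,
       repeat_start = flank_len, repeat_len = nchar(rep_seq),
       flank_len = flank_len, site_origin = site_origin)
}
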