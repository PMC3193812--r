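---
title: "Detecting asymmetric repeat-mediated recombination in plant mitochondrial genomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The biological model

Plant mitochondrial genomes map as circles of a few hundred kilobases.
Double-strand breaks are repaired through several routes that leave
distinct genomic footprints:

* **Reciprocal recombination at large repeats** (> 1 kb) constantly
  interconverts genome isoforms and homogenises the repeat copies, so
  polymorphism inside large repeats is strongly suppressed relative to
  the genome average.
* **Asymmetric recombination at intermediate repeats** (~50–556 bp,
  ≥ 85% identity): a broken end invades the homologous duplex of the
  *other* repeat copy (break-induced replication). Only one of the two
  conceivable crossover products accumulates, and each repeat shows a
  fixed strand-invasion polarity. This pathway is suppressed by MSH1;
  in its absence every competent repeat pair becomes active.
* **Heteroduplex mismatch repair**: when the repeat copies are not
  identical, invasion creates a heteroduplex whose mismatches are
  repaired using the donor strand as template, so the recombinant
  consensus carries donor alleles at SNP sites. Indel repair shows no
  consistent direction.
* **Nonhomologous end-joining and small deletions** produce
  repeat-independent junctions and 2–50-bp losses; together with
  repeat-mediated deletions they account for most structural divergence
  between natural accessions.

The package detects each footprint from 36-bp paired-end reads with
220 ± 20-bp inserts mapped to the circular reference.

# Detection machinery and thresholds

| parameter | default | units | rationale |
|---|---|---|---|
| repeat length floor | 50 | bp | observed lower limit of recombination-competent homology |
| repeat identity floor | 85 | % | lowest identity at which exchange is observed; applied with a 0.5-point epsilon (see below) |
| discordance span | > 1000 | bp, circular | junction definition: ends mapping more than 1 kb apart |
| cluster support | > 10 | read pairs | per required mutant library, strictly, after wild-type subtraction |
| cluster radius | insert + 3 sd = 280 | bp | pairs from one junction cannot spread further |
| flank window | 220 | bp | one insert length: a repeat-anchored read's mate falls within it |
| class I depletion | ≤ −0.5 | relative change | separates the generator's class I fractions (0.55–0.75) with margin |
| class II retention band | > −0.25 | relative change | one-sided; see "Design choices" |
| SNP calling | depth > 5, fraction > 0.8 | strict | the documented operating point, boundary semantics tested exactly |
| mapper mismatch budget | ≤ 3 | per 36-bp end | ~8%, tolerant of the optional 0.1% error model |
| substoichiometric | < 0.05 | junction-support fraction | support relative to expected junction-spanning pairs at median depth |

**Identity definition.** Percent identity is `matches / alignment
columns` with gap columns in the denominator, so substitutions and
single-base indels reduce identity on one scale. A different aligner's
identity may differ by up to ~1 point on gapped pairs.

**Mapping and mate rescue.** Each end is seeded by its two exact
half-read 18-mers and verified by byte comparison. A read with several
equally good placements (repeat-internal) is rescued when its mate is
unique: the placement minimising the circular fragment span wins.
Pairs with neither end unique are dropped from both junction detection
and coverage — conservative, and faithful to flank-anchored analysis.

**What the library geometry can and cannot see.** This is the single
most consequential constraint in the system. With 36-bp reads and
220-bp inserts under span-minimising rescue:

* a junction at an **identical** repeat is witnessed only by read pairs
  anchored across *both* repeat edges, which exist only for repeats
  shorter than roughly `insert − 2×read_len` (~150 bp);
* a junction at a **nonidentical** repeat is witnessed at any length,
  but only through reads that cover a copy-distinguishing site within
  one insert of the repeat's upstream edge;
* conversion evidence reaches only sites within ~180 bp of a repeat
  edge — sites deeper inside long repeats stay "uncovered", mirroring
  the original observation that the library length spanned about half
  of the repeats.

The synthetic catalog respects these facts (below); on real data they
are the reason long identical repeats need longer reads or inserts.

# The synthetic world

`build_reference()` plants the packaged catalog into a random 100-kb
circular genome (a desk-scale stand-in for the ~360-kb genome): 47
intermediate pairs — 33 "known" of 108–556 bp and 14 "novel" of
50–250 bp at 85–98% identity, the smallest the most identical — plus a
2-kb identical large pair and six 40-bp decoys that must never be
called active. Copy2 is copy1 mutated to the target identity. Placement
keeps 450 bp between any two repeat intervals (so flank windows stay
clean and a recombinant molecule's 400-bp flank can never reach a
neighbouring copy — at tighter spacing, a neighbour's recombinant
contaminates the phased conversion pileup) and ≥ 2.5 kb between the
copies of a pair.

Deliberate, load-bearing generator choices:

* **Identical pairs only at short lengths** (108/122 bp). Longer
  identical pairs are undetectable under this read geometry (see
  above), and the stated world requires all 47 pairs recoverable.
* **Edge-proximal polymorphisms.** For nonidentical pairs ≥ 160 bp,
  three substitutions are guaranteed at offsets ~15/60/105 from the
  upstream edge (allele-anchored junction reads need them); insertions
  stay within ~160 bp of that edge (phased reads must span them); all
  sites stay ≥ 10 bp from either end (junction assignment must not be
  confounded); and a 14-bp identical block is always preserved so the
  two copies share an exact discovery seed at any substitution density.
* **Recombinant fractions.** Per-repeat activity is only qualitative in
  the source material, so fractions are free parameters: class I pairs
  run at 0.30–0.36 (first generation) rising to 0.55–0.75 (advanced);
  class II at 0.28–0.32 rising to 0.40–0.50. First-generation fractions
  are set high enough that every junction clears the > 10-support
  filter with Poisson margin at 50×.
* **Class I coupling.** The donor parental environment is thinned by
  `(1 − fraction)`, so gain of recombinant mirrors loss of the
  invading-strand parental form by construction.
* **One product per repeat.** `make_recombinant()` builds exactly one
  crossover product (recipient-upstream flank → donor-allele repeat →
  donor-downstream flank); requesting both reciprocal products is an
  error. The reciprocal product can be built explicitly to test the
  symmetric-exchange anomaly flag.
* **Determinism.** One master seed; every sub-generator derives its own
  stream by fixed offsets. Identical seed and spec give byte-identical
  FASTQ.

The accession panel hangs six coalescent clades from a star root; stem
branches carry 75% of the root-to-tip depth (at less separation,
within-group NJ edges occasionally out-rank a stem edge and the
longest-edge cut splits a clade). SNPs fall on branches proportionally
to length at 5 per 10 kb pairwise, suppressed 66-fold inside large
repeat copies. Structural events are REC (deletion from the end of
copy1 through the end of copy2 of a short pair, leaving one hybrid
copy), NHEJ (a 1.2–8-kb segment lost between junctions ≥ 300 bp from
any repeat copy, with measured microhomology), and DEL (2–50 bp).
Events collide only when some accession would carry both.

**What the generator does not emulate:** base-quality structure, indel
sequencing errors, nuclear contamination, heteroplasmy beyond the
two-form parental/recombinant mixture, transcription, or any
replication-origin structure. A green test therefore establishes that
the *pipeline logic* recovers planted truth under the stated geometry —
not that the thresholds are optimal for a particular real library.

# Numerical choices and degenerate inputs

* **Aligner.** Seeds are exact 12-mers grouped into 16-column diagonal
  bands; each band is refined by affine dynamic programming
  (Biostrings). On inputs of a few hundred bp the full dynamic program
  runs directly, so results equal an independent plain-R
  Smith–Waterman oracle exactly (property-tested). The maximal-scoring
  local alignment may extend a few net-positive columns into random
  flanks; the identity floor is therefore applied with a 0.5-point
  epsilon, and reported identities are the alignment's own.
* **Concordance.** A proper pair has opposite strands and a directional
  fragment span within insert ± 4 sd, computed modulo genome length so
  origin-straddling pairs are handled; discordance-by-distance uses the
  circular distance `min(d, L − d)`.
* **Coverage-gap deletions.** "Near zero" is depth ≤ max(2, 5% of the
  median): reads overhanging a breakpoint by up to the mismatch budget
  bleed a read or two of depth into the first deleted bases, while
  junction-crossing reads are lost up to ~32 bp outside — so
  coverage-based sizes carry a few bp of boundary fuzz (asserted to
  ±10 bp at 20×). Split-read refinement is deliberately out of scope.
  Depth dips *inside* repeat copies are mate-rescue artifacts of a
  rearranged hybrid copy and are never typed as DEL.
* **Conversion edge guard.** Polymorphism-catalog columns within 8 bp
  of the alignment ends are dropped: a discovered boundary can carry a
  few bp of flank, and such columns belong to the junction, not to the
  heteroduplex tract.
* **Phylogeny.** TN93 distances (falling back to raw distance if the
  closed form is undefined), neighbour joining, 100 column-bootstrap
  replicates; taxa are sorted before distance computation so input
  order cannot change the tree. An all-identical matrix yields a star
  tree with a warning; cutting a star into k > 1 groups is an error.
* **Group assignment.** Remove the k − 1 longest internal edges (ties:
  more balanced split, then lexicographically smallest descendant tip);
  connected components are the groups. k defaults to 6 but is a
  parameter — the original division into six groups was chosen by
  inspection.

# Design decisions that were genuinely open

* **One-sided retention band.** The class II criterion is "no region
  depleted below −0.25" rather than a two-sided ±0.25 band. The two
  flanks fused by the junction *gain* coverage by construction (by
  about the recombinant fraction), so a two-sided band would misread
  any class II repeat with fraction above 0.25; only losses
  discriminate the classes. Gains still enter the polarity call as the
  "increased region".
* **Polarity votes.** Coverage (which upstream flank is depleted) and
  junction geometry (which copy's upstream flank is fused in the
  product) vote independently; agreement is required, conflict yields
  `indeterminate` with both votes reported rather than suppression.
* **Fate calling needs depth.** Flank-region read-pair counts at 50×
  carry ~0.12 relative-change noise — against a 0.25 band, perfect
  class recovery is statistically impossible at that scale. The
  polarity/fate recovery guarantee is therefore demonstrated on a
  dedicated 240× fixture, and the fraction-sweep test documents how
  class I calling degrades as the recombinant fraction falls toward
  the threshold.
* **WT background subtraction is arithmetic**: wild-type support in the
  matched windows is subtracted before thresholding, replacing a
  graphical judgement with a reproducible rule.
* **Circularity is configuration**, defaulting to circular: FASTA
  carries no such tag, and the original mapping behaviour is unstated.

# Known limitations

* Junctions at identical repeats longer than ~150 bp are invisible at
  this read geometry (fundamental, not implementational).
* Coverage-based deletion sizes are exact only to a few bp; 2-bp
  deletions can escape detection when junction bleed covers them.
* The mapper is ungapped; reads spanning an indel polymorphism map to
  the copy whose form they carry or not at all, which is exactly what
  the indel-resolution logic exploits, but means indel-dense repeats
  lose some coverage.
* Per-repeat recombinant fractions, and the panel's branch-length
  profile, are free parameters of the generator; recovery statements
  are relative to those stated values.
* E-value statistics, protein alignment, BAM/CRAM writing, and
  maximum-likelihood tree search are out of scope; the group-recovery
  result is what the distance phylogeny is asked to reproduce, and a
  PHYLIP/FASTA export hook can feed external ML tools.
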