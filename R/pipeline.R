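# cli / orchestration: configuration and the two end-to-end pipelines
# (msh1 recombination analysis; ecotype panel analysis).

#' Build a run configuration
#'
#' All thresholds default to the documented operating points: repeats of
#' at least 50 bp and 85% identity; discordance above a 1,000-bp circular
#' span; junction clusters kept above 10 supporting pairs per required
#' library after wild-type subtraction; SNPs above 5x depth and 80%
#' allele fraction; class I depletion at -0.5 and a 0.25 retention band;
#' substoichiometric below 5% support fraction; 36-bp reads with
#' 220 +/- 20 bp inserts.
#'
#' @param overrides named list of values to override.
#' @param path optional JSON config file read before applying
#'   `overrides`.
#' @return `run_config` list.
#' @export
run_config <- function(overrides = list(), path = NULL) {
  cfg <- list(
    seed = 1L, genome_length = 100000L, circular = TRUE,
    min_repeat_length = 50L, min_identity = 85,
    discordance_span = 1000, cluster_support = 10,
    snp_depth = 5L, snp_fraction = 0.8,
    class1_depletion = 0.5, class2_band = 0.25,
    substoichiometric = 0.05, predominant = 0.5,
    read_len = 36L, insert_mean = 220, insert_sd = 20,
    coverage_wt = 50, coverage_gen1 = 50, coverage_adv = 50,
    error_rate = 0,
    panel_ecotypes = 72L, panel_groups = 6L, panel_coverage = 20,
    panel_k = 6L, panel_nboot = 100L,
    recombinant_flank = 400L)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg[names(file_cfg)] <- file_cfg
  }
  cfg[names(overrides)] <- overrides
  num <- c("min_repeat_length", "min_identity", "discordance_span",
           "cluster_support", "snp_depth", "snp_fraction",
           "class1_depletion", "class2_band", "substoichiometric",
           "read_len", "insert_mean", "insert_sd")
  for (f in num) if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
    stop("config field '", f, "' must be a positive number")
  class(cfg) <- "run_config"
  cfg
}

cluster_radius <- function(cfg) cfg$insert_mean + 3 * cfg$insert_sd

#' Simulate the full msh1 fixture set
#'
#' Builds the reference with the packaged catalog, the asymmetric
#' recombinant molecule for every intermediate pair, and the wild-type /
#' first-generation / advanced-generation libraries.  When `out_dir` is
#' given, writes genome FASTA, truth BED/TSV, per-library FASTQ pairs and
#' the serialised config for provenance.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @param catalog repeat catalog specification (defaults to the packaged
#'   one).
#' @return list: `ref`, `recombinants`, `libraries` (named list of
#'   [simulate_library()] results), `config`.
#' @export
cmd_simulate <- function(config = run_config(), out_dir = NULL,
                         catalog = default_repeat_catalog()) {
  log_stage("simulate", "genome ", config$genome_length, " bp, seed ",
            config$seed)
  ref <- build_reference(config$genome_length, catalog, seed = config$seed,
                         circular = config$circular)
  active_specs <- ref$truth[!is.na(ref$truth$fate_class), ][["name"]]
  recs <- lapply(active_specs, function(nm)
    make_recombinant(ref, nm, flank_len = config$recombinant_flank))
  covs <- c(WT = config$coverage_wt, msh1_gen1 = config$coverage_gen1,
            msh1_adv = config$coverage_adv)
  libraries <- lapply(names(covs), function(cond) {
    spec <- library_spec(cond, coverage = covs[[cond]],
                         read_len = config$read_len,
                         insert_mean = config$insert_mean,
                         insert_sd = config$insert_sd,
                         error_rate = config$error_rate)
    simulate_library(ref, recs, spec, seed = config$seed)
  })
  names(libraries) <- names(covs)
  for (cond in names(libraries))
    log_stage("simulate", cond, ": ", nrow(libraries[[cond]]$pairs),
              " read pairs")
  sim <- list(ref = ref, recombinants = recs, libraries = libraries,
              config = config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_fasta(ref$genome, file.path(out_dir, "genome.fasta"))
    write_repeat_catalog(ref$truth, file.path(out_dir, "repeats_truth"))
    data.table::fwrite(ref$polymorphisms,
                       file.path(out_dir, "polymorphisms_truth.tsv"),
                       sep = "\t")
    for (cond in names(libraries))
      write_fastq(libraries[[cond]], file.path(out_dir, cond))
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(sim)
}

map_library <- function(lib, genome, cfg) {
  map_reads(lib$pairs, genome, read_len = cfg$read_len,
            insert_mean = cfg$insert_mean, insert_sd = cfg$insert_sd)
}

#' Run the msh1 recombination analysis pipeline
#'
#' Chains mapping, discordant-pair clustering (pooled across libraries so
#' per-library supports share windows), the support filter with
#' wild-type background subtraction, junction-to-repeat assignment,
#' flanking-coverage polarity and fate classification, the
#' generation-trend report, and gene-conversion analysis for nonidentical
#' active repeats.
#'
#' @param sim simulation bundle from [cmd_simulate()], or a compatible
#'   list with `ref` and `libraries` (each library either a
#'   [simulate_library()] result or a pre-mapped placement table in
#'   `placements`).
#' @param config a [run_config()].
#' @param out_dir optional directory for the report TSVs.
#' @return list of results: `catalog` (discovered), `clusters`,
#'   `selected`, `active`, `assignments`, `polarity`, `fate`, `trend`,
#'   `conversion`, `log`.
#' @export
cmd_recombination <- function(sim, config = run_config(), out_dir = NULL) {
  ref <- sim$ref
  libs <- sim$libraries
  need <- c("WT", "msh1_gen1", "msh1_adv")
  if (!"WT" %in% names(libs))
    stop("wild-type library required for background subtraction")
  if (!any(c("msh1_gen1", "msh1_adv") %in% names(libs)))
    stop("at least one mutant library required")
  log_stage("map", "mapping ", length(libs), " libraries")
  placements <- lapply(names(libs), function(cond) {
    lb <- libs[[cond]]
    p <- if (!is.null(lb$placements)) data.table::as.data.table(lb$placements)
    else map_library(lb, ref$genome, config)
    p[, library := cond]
    p
  })
  names(placements) <- names(libs)
  log_stage("discover", "genome self-alignment repeat scan")
  catalog <- find_repeat_pairs(ref$genome,
                               min_length = config$min_repeat_length,
                               min_identity = config$min_identity,
                               flank = config$insert_mean)
  pooled <- data.table::rbindlist(placements)
  cl <- cluster_discordant(pooled, ref$genome$length,
                           min_span = config$discordance_span,
                           radius = cluster_radius(config),
                           read_len = config$read_len)
  log_stage("cluster", nrow(cl$clusters), " discordant clusters")
  required <- intersect(c("msh1_gen1", "msh1_adv"), names(libs))
  selected <- filter_clusters(cl$clusters,
                              min_support = config$cluster_support,
                              require_libraries = required,
                              wt_library = "WT")
  log_stage("filter", nrow(selected), " clusters pass >",
            config$cluster_support, " in ", paste(required, collapse = "+"),
            " after WT subtraction")
  act <- call_active_repeats(selected, catalog, ref$genome,
                             pad = config$insert_mean +
                               2 * config$insert_sd)
  log_stage("active", nrow(act$active), " active repeat pairs, ",
            sum(act$assignments$call == "NHEJ-candidate"),
            " NHEJ candidates, ", length(act$anomalies),
            " symmetric-exchange anomalies")
  medians <- vapply(placements, function(p)
    stats::median(coverage_track(p, ref$genome, config$read_len)),
    numeric(1))
  mutants <- intersect(c("msh1_gen1", "msh1_adv"), names(libs))
  polarity <- list(); fate <- list(); fate_tables <- list()
  supports <- list()
  for (i in seq_len(nrow(act$active))) {
    pair <- act$active[i]
    jrow <- act$assignments[act$assignments$call == "repeat-mediated" &
                              act$assignments$repeat_name == pair$name][1]
    tab <- flank_change_table(placements, medians, pair, catalog,
                              ref$genome$length,
                              window = config$insert_mean,
                              read_len = config$read_len)
    fate_tables[[pair$name]] <- tab
    polarity[[pair$name]] <- call_polarity(
      tab, jrow, generation = utils::tail(mutants, 1L),
      depletion_threshold = -config$class2_band)
    s1 <- jrow[[paste0("net_support_", "msh1_gen1")]] %||% NA_integer_
    s2 <- jrow[[paste0("net_support_", "msh1_adv")]] %||% NA_integer_
    supports[[pair$name]] <- data.table(repeat_name = pair$name,
                                        support_msh1_gen1 = s1,
                                        support_msh1_adv = s2)
    fate[[pair$name]] <- if (length(mutants) == 2L)
      classify_fate(tab, s1, s2,
                    class1_threshold = -config$class1_depletion,
                    retention_band = config$class2_band)
    else list(class = "indeterminate", depleted_region = NA_integer_,
              change_gen1 = NA_real_, change_adv = NA_real_)
  }
  supports <- data.table::rbindlist(supports)
  trend <- if (nrow(act$active) && length(mutants) == 2L)
    generation_trend(fate_tables, supports, as.list(medians),
                     insert_mean = config$insert_mean,
                     read_len = config$read_len)
  else NULL
  # conversion at nonidentical active repeats, phased from the advanced
  # (or only) mutant library
  conv_lib <- utils::tail(mutants, 1L)
  conv <- list()
  for (i in seq_len(nrow(act$active))) {
    pair <- act$active[i]
    if (pair$identity >= 100) next
    polys <- catalog_polymorphisms(pair, ref$genome)
    cl_ids <- act$assignments[act$assignments$repeat_name == pair$name &
                                act$assignments$call == "repeat-mediated",
                              ][["cluster_id"]]
    members <- cl$members[cl$members$cluster_id %in% cl_ids &
                            cl$members$library == conv_lib, ][["qname"]]
    cons <- recombinant_consensus(placements[[conv_lib]],
                                  libs[[conv_lib]]$pairs, members, polys,
                                  min_reads = config$snp_depth,
                                  min_agree = config$snp_fraction,
                                  read_len = config$read_len)
    conv[[pair$name]] <- resolve_direction(cons,
                                           polarity[[pair$name]]$donor)
  }
  polarity_tab <- data.table::rbindlist(lapply(names(polarity), function(nm) {
    p <- polarity[[nm]]
    f <- fate[[nm]]
    data.table(repeat_name = nm, donor_copy = p$donor,
               recipient_copy = p$recipient,
               depleted_region = p$depleted_region,
               increased_region = p$increased_region,
               polarity_method = p$method, fate_class = f$class,
               change_gen1 = f$change_gen1, change_adv = f$change_adv)
  }))
  results <- list(catalog = catalog, clusters = cl$clusters,
                  selected = selected, active = act$active,
                  assignments = act$assignments,
                  anomalies = act$anomalies,
                  polarity = polarity_tab, fate_tables = fate_tables,
                  trend = trend,
                  conversion = if (length(conv))
                    conversion_table(conv, act$active) else NULL,
                  conversion_details = conv,
                  members = cl$members, medians = medians)
  if (!is.null(out_dir)) {
    tabs <- list(catalog = catalog, clusters = selected,
                 active = act$active, polarity = polarity_tab,
                 conversion = results$conversion,
                 circle = cluster_circle_table(cl$clusters))
    if (!is.null(trend)) tabs$trend <- trend$per_repeat
    write_tables(tabs, out_dir)
  }
  results
}

#' Run the ecotype panel analysis pipeline
#'
#' Simulates (or accepts) a panel, then per accession: reads, mapping,
#' threshold SNP calling and structural-variant typing against the
#' reference; then the concatenated-SNP distance phylogeny with
#' bootstrap, group assignment, and the SV/phylogeny concordance report.
#'
#' @param ref reference bundle from [build_reference()] (or
#'   [cmd_simulate()]`$ref`).
#' @param config a [run_config()].
#' @param panel optional pre-built panel from [make_ecotype_panel()].
#' @param out_dir optional output directory (per-accession VCFs, SV
#'   table, Newick tree, groups, concordance).
#' @return list: `panel`, `snp_sets`, `sv_calls`, `matrix`, `phylogeny`,
#'   `groups`, `concordance`.
#' @export
cmd_panel <- function(ref, config = run_config(), panel = NULL,
                      out_dir = NULL) {
  if (config$panel_ecotypes < 3L) stop("at least 3 ecotypes required")
  spec <- ecotype_panel_spec(n_ecotypes = config$panel_ecotypes,
                             n_groups = config$panel_groups,
                             coverage = config$panel_coverage,
                             read_len = config$read_len,
                             insert_mean = config$insert_mean,
                             insert_sd = config$insert_sd)
  if (is.null(panel)) panel <- make_ecotype_panel(ref, spec,
                                                  seed = config$seed)
  mask <- ambiguity_mask(ref$truth, ref$genome$length,
                         insert_mean = config$insert_mean,
                         insert_sd = config$insert_sd,
                         read_len = config$read_len)
  catalog <- find_repeat_pairs(ref$genome,
                               min_length = config$min_repeat_length,
                               min_identity = config$min_identity,
                               flank = config$insert_mean)
  snp_sets <- list(); depth_sets <- list(); sv_calls <- list()
  for (i in seq_along(panel$genomes)) {
    eco <- names(panel$genomes)[i]
    lib <- simulate_panel_library(panel$genomes[[eco]], spec,
                                  seed = derive_seed(config$seed, 100L + i))
    pl <- map_reads(lib$pairs, ref$genome, read_len = config$read_len,
                    insert_mean = config$insert_mean,
                    insert_sd = config$insert_sd)
    depth <- coverage_track(pl, ref$genome, config$read_len)
    snp_sets[[eco]] <- call_snps(pl, lib$pairs, ref$genome,
                                 min_depth = config$snp_depth,
                                 min_fraction = config$snp_fraction,
                                 mask = mask, read_len = config$read_len)
    cd <- cluster_discordant(pl, ref$genome$length,
                             min_span = config$discordance_span,
                             radius = cluster_radius(config),
                             read_len = config$read_len)
    sel <- filter_clusters(cd$clusters,
                           min_support = config$cluster_support,
                           require_libraries = "all", wt_library = NA)
    sv <- classify_svs(sel, depth, catalog, ref$genome, mask = mask,
                       median_depth = max(1, stats::median(depth)),
                       insert_mean = config$insert_mean,
                       read_len = config$read_len)
    sv[, ecotype := eco]
    sv_calls[[eco]] <- sv
    depth_sets[[eco]] <- depth
    log_stage("panel", eco, ": ", nrow(snp_sets[[eco]]), " SNPs, ",
              nrow(sv), " SVs")
  }
  m <- snp_matrix(snp_sets, depth_sets, ref$genome,
                  min_depth = config$snp_depth,
                  min_fraction = config$snp_fraction)
  ph <- build_phylogeny(m, nboot = config$panel_nboot, seed = config$seed)
  groups <- assign_groups(ph$tree, k = config$panel_k)
  svs <- data.table::rbindlist(sv_calls)
  # concordance over matched SV calls (same type and locus across
  # accessions)
  svs_real <- svs[svs$type %in% c("REC", "NHEJ", "DEL")]
  if (nrow(svs_real)) {
    svs_real[, event_id := .GRP,
             by = .(type, round(start / 50), round(end / 50))]
    conc <- concordance_report(svs_real[, .(event_id, ecotype)], groups)
  } else conc <- list(per_event = NULL, panel_concordance = NA_real_)
  res <- list(panel = panel, snp_sets = snp_sets, sv_calls = svs,
              matrix = m, phylogeny = ph, groups = groups,
              concordance = conc)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (eco in names(snp_sets))
      write_vcf(snp_sets[[eco]], file.path(out_dir, paste0(eco, ".vcf")),
                genome = ref$genome)
    write_tables(list(svs = svs, groups = groups, tree = ph$tree),
                 out_dir)
    if (!is.null(conc$per_event))
      data.table::fwrite(conc$per_event,
                         file.path(out_dir, "concordance.tsv"), sep = "\t")
  }
  res
}
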