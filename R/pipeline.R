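#' Assemble a pipeline configuration
#'
#' Either point at the three input tables (`genotypes`, `phenotypes`,
#' `associations`) or supply `simulate` (a [simulation_config()] or a preset
#' name, `"additive"` or `"reciprocal-heavy"`) to generate them. All stage
#' options are explicit here so a run is fully described by its config.
#'
#' @param out_dir run directory (created).
#' @param genotypes,phenotypes,associations input TSV paths (ignored when
#'   simulating).
#' @param simulate `NULL`, a [simulation_config()], or a preset name.
#' @param tree optional Newick path for phylogenetic correlations.
#' @param grid `-log10` cutoff grid for the sweep.
#' @param maf optional minor-allele-frequency filter threshold.
#' @param ld_r2 optional LD pruning r-squared threshold.
#' @param null_reps randomization replicates (0 disables the null stage).
#' @param direction accessibility direction(s): `"max"`, `"min"` or
#'   `"both"`.
#' @param delta `"auto"` (estimate from the network) or a fixed numeric.
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            genotypes = NULL, phenotypes = NULL,
                            associations = NULL, simulate = NULL,
                            tree = NULL, grid = seq(4, 9, by = 0.5),
                            maf = NULL, ld_r2 = NULL, null_reps = 1000L,
                            direction = "both", delta = "auto", seed = 1L) {
  if (is.character(simulate)) simulate <- simulation_preset(simulate, seed)
  if (is.null(simulate) && (is.null(genotypes) || is.null(phenotypes) ||
                            is.null(associations))) {
    stop("supply the three input tables or a `simulate` specification")
  }
  stopifnot(direction %in% c("max", "min", "both"))
  structure(list(out_dir = out_dir, genotypes = genotypes,
                 phenotypes = phenotypes, associations = associations,
                 simulate = simulate, tree = tree, grid = grid, maf = maf,
                 ld_r2 = ld_r2, null_reps = as.integer(null_reps),
                 direction = direction, delta = delta,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Built-in simulation presets
#'
#' `"additive"`: four causal loci with distinct positive effects, no
#' interactions, no noise — every square is additive and every shortest path
#' to the (unique) maximum is accessible. `"reciprocal-heavy"`: four causal
#' loci arranged as two reciprocal-sign pairs (negative additive effects
#' rescued by strong positive interactions) plus mild noise — reciprocal
#' sign epistasis is planted and some paths are blocked.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return a [simulation_config()].
#' @export
simulation_preset <- function(name, seed = 1L) {
  switch(
    name,
    "additive" = simulation_config(
      n_accessions = 400L, n_causal_loci = 4L, n_neutral_loci = 40L,
      minor_allele_freq = 0.45, additive_effects = c(1, 1, 1, 1),
      noise_sd = 0, baseline = 10, seed = seed),
    "reciprocal-heavy" = simulation_config(
      n_accessions = 1000L, n_causal_loci = 4L, n_neutral_loci = 40L,
      minor_allele_freq = 0.49, additive_effects = c(-1, -1, -1, -1),
      interaction_terms = list(list(1L, 2L, 4), list(3L, 4L, 4)),
      noise_sd = 0.05, baseline = 10, seed = seed),
    stop("unknown preset '", name, "'")
  )
}

#' Run the full genotype-network analysis
#'
#' Orchestrates simulate/read -> optional MAF filter and LD pruning -> cutoff
#' sweep -> network build -> delta estimation -> identical-neighbor fraction
#' -> square classification -> accessibility (max/min) -> randomization null
#' -> structure (betweenness, modules, module phenotype contrast, optional
#' phylogenetic correlation), writing one TSV per stage, the network export,
#' a single summary row, and a reproducibility manifest. Every skipped
#' analysis is recorded with its reason; identical seeds reproduce all
#' outputs byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the key in-memory results (`panel`,
#'   `sweep`, `network`, `delta`, `epistasis`, `accessibility`, `null`,
#'   `structure`, `summary`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  skips <- list()
  note_skip <- function(stage, reason) skips[[stage]] <<- reason

  ## inputs
  if (!is.null(config$simulate)) {
    panel <- simulate_panel(config$simulate)
    assoc <- compute_association_pvalues(panel)
    write_simulated_panel(panel, file.path(out, "input"), assoc = assoc)
  } else {
    inp <- read_panel(config$genotypes, config$phenotypes, config$associations)
    panel <- inp$panel
    assoc <- inp$assoc
  }
  if (!is.null(config$maf)) panel <- maf_filter(panel, config$maf)
  if (!is.null(config$ld_r2)) {
    panel <- ld_prune(panel, assoc[assoc$locus %in% panel$loci, ], config$ld_r2)
    assoc <- assoc[assoc$locus %in% panel$loci, ]
  }

  ## sweep + network
  sweep <- sweep_cutoffs(panel, assoc, grid = config$grid)
  write_tsv(sweep$table, file.path(out, "sweep.tsv"))
  net <- sweep$network
  if (is.null(net) || igraph::vcount(net$graph) == 0L) {
    note_skip("network", "no cutoff yielded a non-degenerate network")
    manifest <- build_manifest(config, sweep, skips, summary = NULL)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(list(panel = panel, sweep = sweep, network = NULL,
                          manifest = manifest)))
  }
  write_network(net, file.path(out, "network"), seed = derive_seed(config$seed, 12L))
  write_tsv(net$vertices, file.path(out, "vertices.tsv"))

  ## delta
  delta_est <- estimate_delta(net)
  delta <- if (identical(config$delta, "auto")) delta_est else {
    de <- delta_est
    de$delta <- as.numeric(config$delta)
    de$available <- TRUE
    de
  }
  if (!delta$available) note_skip("delta", "no vertex with >= 3 members")

  ## epistasis
  epi <- summarize_epistasis(net, delta)
  if (epi$status == "ok") {
    write_tsv(epi$calls, file.path(out, "epistasis_squares.tsv"))
  } else {
    note_skip("epistasis", epi$status)
  }
  fid <- if (delta$available && igraph::ecount(net$graph) > 0L) {
    fraction_identical_neighbors(net, delta$delta)
  } else NA_real_

  ## accessibility
  dirs <- if (config$direction == "both") c("max", "min") else config$direction
  access <- list()
  for (dd in dirs) {
    rep_dd <- accessibility_summary(net, delta = if (delta$available) delta$delta else 0,
                                    direction = dd)
    access[[dd]] <- rep_dd
    if (rep_dd$status == "ok") {
      write_tsv(rep_dd$per_source, file.path(out, sprintf("accessibility_%s.tsv", dd)))
      write_tsv(rep_dd$bins, file.path(out, sprintf("accessibility_%s_bins.tsv", dd)))
    } else {
      note_skip(paste0("accessibility_", dd), rep_dd$status)
    }
  }

  ## null model
  null <- NULL
  if (config$null_reps > 0L) {
    null <- null_distribution(net$accession_haplotypes,
                              n_reps = config$null_reps,
                              seed = derive_seed(config$seed, 11L))
    null_rows <- do.call(rbind, lapply(names(null$observed), function(stat) {
      eq <- empirical_quantile(null$observed[[stat]], null, statistic = stat)
      data.frame(statistic = stat, observed = null$observed[[stat]],
                 null_mean = mean(null$stats[[stat]]),
                 quantile = eq$quantile, p_two_sided = eq$p_two_sided)
    }))
    write_tsv(null_rows, file.path(out, "null_summary.tsv"))
  }

  ## structure
  btw <- vertex_betweenness(net)
  mods <- detect_modules(net, seed = derive_seed(config$seed, 12L))
  mtest <- module_phenotype_test(mods)
  sv <- data.frame(haplotype = names(btw), betweenness = unname(btw),
                   module = unname(mods$membership[names(btw)]),
                   stringsAsFactors = FALSE)
  write_tsv(sv, file.path(out, "structure_vertices.tsv"))
  phylo <- NULL
  if (!is.null(config$tree)) {
    tree <- read_newick(config$tree)
    dm <- phylo_distances(tree, panel)
    phylo <- list(
      internal_nodes = path_vs_phylo_correlation(net, dm$internal_nodes),
      nucleotide_diffs = path_vs_phylo_correlation(net, dm$nucleotide_diffs)
    )
  }

  ## summary row
  summary_row <- data.frame(
    phenotype = if (!is.null(net$provenance$phenotype)) net$provenance$phenotype else "phenotype",
    selected_neglog10 = sweep$selected_neglog10,
    n_loci = length(net$provenance$loci),
    n_unique_genotypes = nrow(net$vertices),
    n_vertices = igraph::vcount(net$graph),
    n_edges = igraph::ecount(net$graph),
    n_components = net$n_components,
    largest_component = net$largest_component,
    n_squares = epi$n_classified + epi$n_skipped_tied_max,
    delta = if (delta$available) delta$delta else NA_real_,
    fraction_identical_neighbors = fid,
    epistatic_fraction = epi$epistatic_fraction,
    frac_magnitude = if (epi$status == "ok") epi$fractions[["magnitude"]] else NA_real_,
    frac_simple_sign = if (epi$status == "ok") epi$fractions[["simple_sign"]] else NA_real_,
    frac_reciprocal_sign = if (epi$status == "ok") epi$fractions[["reciprocal_sign"]] else NA_real_,
    all_epistatic = isTRUE(epi$all_epistatic),
    mean_path_length_max = if (!is.null(access$max) && access$max$status == "ok")
      access$max$mean_path_length else NA_real_,
    accessible_fraction_max = if (!is.null(access$max) && access$max$status == "ok")
      access$max$fraction_accessible else NA_real_,
    accessible_fraction_min = if (!is.null(access$min) && access$min$status == "ok")
      access$min$fraction_accessible else NA_real_,
    modularity = mods$modularity,
    module_test_p = mtest$p_value,
    stringsAsFactors = FALSE
  )
  write_tsv(summary_row, file.path(out, "summary.tsv"))

  manifest <- build_manifest(config, sweep, skips, summary_row)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(panel = panel, assoc = assoc, sweep = sweep, network = net,
                 delta = delta, epistasis = epi, accessibility = access,
                 null = null,
                 structure = list(betweenness = btw, modules = mods,
                                  module_test = mtest, phylo = phylo),
                 summary = summary_row, manifest = manifest))
}

# internal: reproducibility manifest (no timestamps: outputs must be
# byte-identical across reruns with the same seed)
build_manifest <- function(config, sweep, skips, summary) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # implied by the manifest's own location
  cfg$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
  list(
    package = "epinet",
    version = as.character(utils::packageVersion("epinet")),
    config = cfg,
    seed = config$seed,
    stage_seeds = list(genotypes = derive_seed(config$seed, 0L),
                       noise = derive_seed(config$seed, 500009L),
                       null = derive_seed(config$seed, 11L),
                       modules = derive_seed(config$seed, 12L)),
    selected_neglog10 = sweep$selected_neglog10,
    sensitivity_neglog10 = as.list(sweep$sensitivity),
    skips = if (length(skips)) skips else NULL,
    summary = if (!is.null(summary)) as.list(summary[1L, ])
  )
}
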