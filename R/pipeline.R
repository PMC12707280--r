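#' Default run configuration
#'
#' Returns the full configuration list for [run_pipeline()], which can be
#' edited or partially overridden. The same structure can be read from a
#' YAML file (see `germnet run --config`).
#'
#' @param outdir output directory.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @return named list of stage settings.
#' @export
default_config <- function(outdir = tempfile("germnet_run_"), seed = 1L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    simulate = list(enabled = TRUE,
                    design = list(n_genotypes = 3, n_soils = 2,
                                  n_temperatures = 2, n_reps = 4),
                    params = list()),
    preprocess = list(plant_filter = c(75, 4),
                      microbe_filter = c(250, 3),
                      clr_pseudocount = 0.5),
    community = list(enabled = TRUE, n_perm_permanova = 999,
                     n_perm_mantel = 5000,
                     terms = c("genotype", "soil", "temperature")),
    diffcorr = list(enabled = TRUE, fdr = 0.05, min_dz = 1.0,
                    edge_rho = 0.7),
    traits = list(enabled = TRUE,
                  traits = c("heat_score", "shoot_biomass", "root_volume"),
                  rho_min = 0.05, alpha = 0.5, folds = 10,
                  n_trees = 2000, top_k = 25, min_methods = 2)
  )
}

validate_config <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$outdir)) stop("config requires an output directory")
  fdr <- config$diffcorr$fdr
  if (!is.null(fdr) && (fdr <= 0 || fdr > 1))
    stop("diffcorr fdr must lie in (0, 1]")
  if (!is.null(config$diffcorr$min_dz) && config$diffcorr$min_dz < 0)
    stop("min_dz must be non-negative")
  al <- config$traits$alpha
  if (!is.null(al) && (al < 0 || al > 1))
    stop("elastic-net alpha must lie in [0, 1]")
  if (!isTRUE(config$simulate$enabled) &&
      is.null(config$input))
    stop("either a simulation spec or input paths must be given")
  invisible(config)
}

# Merge user settings over defaults, recursively.
merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      merge_config(base[[k]], user[[k]]) else user[[k]]
  }
  base
}

#' Read a run configuration from YAML
#'
#' Settings in the file override [default_config()] values key by key.
#'
#' @param path YAML file.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  cfg
}

write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (or load inputs), preprocess (filters,
#' pathway collapse, CLR on microbial tables, median-of-ratios on plant
#' counts), community statistics (Euclidean distances, Mantel between the
#' plant and microbial distance matrices, PERMANOVA per table), differential
#' correlation between the two temperature conditions, trait models
#' (prefilter, elastic net, random forest per trait), and the three-method
#' consensus. All tabular outputs are written as TSV with a commented header
#' carrying the stage's settings and seed; a JSON manifest with per-file
#' checksums is written last. Identical config + seed reproduce identical
#' checksums.
#'
#' @param config list from [default_config()] / [read_config()].
#' @return the run manifest (invisibly also written to
#'   `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  logf <- function(...) message(sprintf("[germnet] %s", sprintf(...)))
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  files <- character(0)
  stage_seeds <- list()

  ## -- stage 1: simulate or load ------------------------------------------
  if (isTRUE(config$simulate$enabled)) {
    logf("simulate: factorial design, seed %d", seed)
    ds <- do.call(design_spec, c(config$simulate$design, list(seed = seed)))
    design <- generate_design(ds)
    params <- do.call(generator_params, config$simulate$params)
    sim <- generate_counts(design, params)
    meta <- generate_phenotypes(design, sim$plant, sim$microbe, sim$truth,
                                params)
    plant_counts <- sim$plant
    microbe_counts <- sim$microbe
    annotation <- sim$annotation
    files["plant_counts"] <- write_matrix(
      plant_counts, file.path(outdir, "plant_counts.tsv"),
      header = c("kind: plant_gene", paste("seed:", seed)))
    files["microbe_counts"] <- write_matrix(
      microbe_counts, file.path(outdir, "microbe_counts.tsv"),
      header = c("kind: microbial_gene", paste("seed:", seed)))
    utils::write.csv(meta, file.path(outdir, "metadata.csv"),
                     row.names = FALSE)
    files["metadata"] <- file.path(outdir, "metadata.csv")
    files["annotation"] <- write_tsv(annotation,
                                     file.path(outdir, "annotation.tsv"))
    files["truth_pairs"] <- write_tsv(
      sim$truth$planted_pairs, file.path(outdir, "truth_planted_pairs.tsv"))
    files["truth_de"] <- write_tsv(sim$truth$de_genes,
                                   file.path(outdir, "truth_de_genes.tsv"))
    files["truth_traits"] <- write_tsv(
      sim$truth$trait_features, file.path(outdir, "truth_trait_features.tsv"))
    stage_seeds$simulate <- seed
  } else {
    logf("load: reading input tables")
    plant_counts <- read_matrix(config$input$plant, "plant_gene")
    microbe_counts <- read_matrix(config$input$microbe, "microbial_gene")
    meta <- utils::read.csv(config$input$metadata,
                            stringsAsFactors = FALSE)
    annotation <- utils::read.table(config$input$annotation, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)
    attr(meta, "temperature_levels") <- unique(meta$temperature)
  }
  temp_levels <- attr(meta, "temperature_levels") %||%
    unique(meta$temperature)

  ## -- stage 2: preprocess ------------------------------------------------
  pf <- config$preprocess$plant_filter
  mf <- config$preprocess$microbe_filter
  logf("preprocess: filters (%g,%g) plant / (%g,%g) microbe",
       pf[1], pf[2], mf[1], mf[2])
  plant_f <- filter_low_expression(plant_counts, pf[1], pf[2])
  microbe_f <- filter_low_expression(microbe_counts, mf[1], mf[2])
  pathways <- collapse_pathways(microbe_f, annotation)
  plant_norm <- median_ratio_normalize(plant_f)$matrix
  microbe_clr <- clr_transform(microbe_f,
                               config$preprocess$clr_pseudocount)
  pathway_clr <- clr_transform(pathways, config$preprocess$clr_pseudocount)
  files["pathway_counts"] <- write_matrix(
    pathways, file.path(outdir, "pathway_counts.tsv"),
    header = "kind: pathway")
  files["plant_norm"] <- write_matrix(
    plant_norm, file.path(outdir, "plant_median_ratio.tsv"),
    header = "transform: median_ratio")
  files["pathway_clr"] <- write_matrix(
    pathway_clr, file.path(outdir, "pathway_clr.tsv"),
    header = "transform: clr")

  ## -- stage 3: community statistics --------------------------------------
  if (isTRUE(config$community$enabled)) {
    logf("community: Mantel + PERMANOVA")
    d_plant <- euclidean_distance(clr_transform(plant_f,
                                                config$preprocess$clr_pseudocount))
    d_microbe <- euclidean_distance(microbe_clr)
    mt <- mantel(d_plant, d_microbe,
                 n_perm = config$community$n_perm_mantel,
                 seed = seed + 11L)
    terms <- intersect(config$community$terms, colnames(meta))
    pv_plant <- permanova(d_plant, meta, terms,
                          n_perm = config$community$n_perm_permanova,
                          seed = seed + 12L)
    pv_microbe <- permanova(d_microbe, meta, terms,
                            n_perm = config$community$n_perm_permanova,
                            seed = seed + 13L)
    files["mantel"] <- write_tsv(
      data.frame(statistic = mt$statistic, p = mt$p, n_perm = mt$n_perm,
                 seed = mt$seed),
      file.path(outdir, "mantel.tsv"),
      header = "mantel: plant (CLR) vs microbe (CLR) Euclidean distances")
    files["permanova_plant"] <- write_tsv(
      pv_plant, file.path(outdir, "permanova_plant.tsv"))
    files["permanova_microbe"] <- write_tsv(
      pv_microbe, file.path(outdir, "permanova_microbe.tsv"))
    stage_seeds$community <- seed + c(11L, 12L, 13L)
  }

  ## -- stage 4: differential correlation ----------------------------------
  diffcorr_sets <- NULL
  if (isTRUE(config$diffcorr$enabled)) {
    logf("diffcorr: %s vs %s", temp_levels[1], temp_levels[2])
    samples_A <- meta$sample_id[meta$temperature == temp_levels[1]]
    samples_B <- meta$sample_id[meta$temperature == temp_levels[2]]
    dc <- differential_correlation(plant_norm, pathway_clr,
                                   samples_A, samples_B,
                                   q_threshold = config$diffcorr$fdr,
                                   dz_threshold = config$diffcorr$min_dz)
    files["diffcorr"] <- write_tsv(
      dc, file.path(outdir, "diffcorr.tsv"),
      header = sprintf("fdr: %g | min_dz: %g | A: %s | B: %s",
                       config$diffcorr$fdr, config$diffcorr$min_dz,
                       temp_levels[1], temp_levels[2]))
    corr_B <- pairwise_spearman(plant_norm, pathway_clr, samples_B)
    net <- bipartite_network(corr_B,
                             rho_threshold = config$diffcorr$edge_rho,
                             condition = temp_levels[2])
    files["network"] <- write_tsv(
      net$edges, file.path(outdir, "network_edges.tsv"),
      header = sprintf("edge rule: rho > %g", config$diffcorr$edge_rho))
    sig <- dc[dc$significant, , drop = FALSE]
    diffcorr_sets <- unique(c(sig$plant_feature, sig$microbial_feature))
  }

  ## -- stage 5 + 6: trait models and consensus ----------------------------
  if (isTRUE(config$traits$enabled)) {
    tcfg <- config$traits
    feats <- rbind(unclass(plant_norm), unclass(pathway_clr))
    ftype <- stats::setNames(
      c(rep("plant_gene", nrow(plant_norm)),
        rep("pathway", nrow(pathway_clr))),
      c(rownames(plant_norm), rownames(pathway_clr)))
    sets_by_trait <- list()
    coef_rows <- list()
    imp_rows <- list()
    for (tr in tcfg$traits) {
      logf("traits: %s", tr)
      y <- meta[[tr]]
      keep <- univariate_prefilter(feats, y, tcfg$rho_min)
      X <- t(feats[keep, , drop = FALSE])
      en <- elastic_net_associate(X, y, alpha_mix = tcfg$alpha,
                                  folds = tcfg$folds, seed = seed + 21L)
      rf <- random_forest_associate(X, y, n_trees = tcfg$n_trees,
                                    top_k = tcfg$top_k,
                                    feature_type = ftype[keep],
                                    seed = seed + 22L)
      sets_by_trait[[tr]] <- list(
        diffcorr = diffcorr_sets %||% character(0),
        elastic_net = en$feature,
        random_forest = rf$feature)
      if (nrow(en)) coef_rows[[tr]] <- data.frame(trait = tr, en)
      imp_rows[[tr]] <- data.frame(trait = tr, rf)
    }
    cons <- consensus_features(sets_by_trait,
                               min_methods = tcfg$min_methods,
                               feature_types = ftype)
    files["coefficients"] <- write_tsv(
      do.call(rbind, coef_rows) %||% data.frame(),
      file.path(outdir, "elastic_net_coefficients.tsv"))
    files["importance"] <- write_tsv(
      do.call(rbind, imp_rows), file.path(outdir, "rf_importance.tsv"))
    files["consensus"] <- write_tsv(
      cons$table, file.path(outdir, "consensus.tsv"),
      header = sprintf("min_methods: %d", tcfg$min_methods))
    files["tally"] <- write_tsv(cons$tally,
                                file.path(outdir, "consensus_tally.tsv"))
    stage_seeds$traits <- seed + c(21L, 22L)
  }

  ## -- manifest ------------------------------------------------------------
  manifest <- list(
    package = "germnet",
    version = as.character(utils::packageVersion("germnet")),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    stage_seeds = stage_seeds,
    config = config,
    checksums = as.list(tools::md5sum(unname(files[!is.na(files)])))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("done: %s", outdir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
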