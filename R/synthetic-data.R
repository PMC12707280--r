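#' Factorial design specification
#'
#' Describes the growth-chamber experiment the generator emulates: fully
#' crossed genotype x soil x temperature with replication (defaults: 3
#' genotypes, 2 soils, 2 temperatures, 4 replicates = 48 samples).
#'
#' @param n_genotypes,n_soils,n_temperatures,n_reps factor sizes, all >= 1.
#' @param temperature_levels labels for the temperature levels; the first is
#'   treated as the optimal condition (A), the second as heat (B).
#' @param seed master seed; per-stream substreams are derived from it
#'   (`seed + 1` plant counts, `seed + 2` microbial counts, `seed + 3`
#'   phenotypes).
#' @return object of class `design_spec`.
#' @export
design_spec <- function(n_genotypes = 3L, n_soils = 2L, n_temperatures = 2L,
                        n_reps = 4L,
                        temperature_levels = c("28C", "38C"),
                        seed = 1L) {
  counts <- c(n_genotypes, n_soils, n_temperatures, n_reps)
  if (any(counts < 1)) stop("all design counts must be >= 1")
  if (length(temperature_levels) < n_temperatures)
    stop("need a label per temperature level")
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_soils = as.integer(n_soils),
                 n_temperatures = as.integer(n_temperatures),
                 n_reps = as.integer(n_reps),
                 temperature_levels = temperature_levels[seq_len(n_temperatures)],
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Generator parameters
#'
#' Tunable knobs of the synthetic world: feature counts, sequencing depths,
#' negative-binomial dispersion for plant counts, the fraction and size of
#' planted differential-expression effects, the cross-kingdom planted
#' correlation pairs (Spearman targets per temperature condition), and the
#' planted trait-feature structure feeding the phenotypes.
#'
#' @param n_plant_genes,n_microbial_genes,n_pathways feature counts.
#' @param library_size_plant,library_size_microbe integer depth intervals
#'   per kingdom.
#' @param nb_dispersion NB dispersion for plant counts (size = 1/dispersion).
#' @param frac_de_temperature fraction of features (per kingdom) with a
#'   planted temperature effect; `frac_de_soil` and `frac_de_genotype`
#'   default to half of it.
#' @param effect_size_logfc planted log2 fold change.
#' @param n_diffcorr_pairs number of planted cross-kingdom correlated pairs.
#' @param rho_condition_A,rho_condition_B target Spearman correlation of
#'   planted pairs in the optimal and heat condition (`|rho| < 1`).
#' @param n_trait_features_plant,n_trait_features_microbe number of plant
#'   genes / microbial pathways planted as phenotype drivers.
#' @param trait_noise_sd Gaussian noise sd added to the phenotypes.
#' @param frac_de_soil,frac_de_genotype planted effect fractions for the
#'   other factors.
#' @return object of class `generator_params`.
#' @export
generator_params <- function(n_plant_genes = 400L, n_microbial_genes = 300L,
                             n_pathways = 40L,
                             library_size_plant = c(50000L, 100000L),
                             library_size_microbe = c(50000L, 100000L),
                             nb_dispersion = 0.2,
                             frac_de_temperature = 0.1,
                             effect_size_logfc = 1.0,
                             n_diffcorr_pairs = 10L,
                             rho_condition_A = 0.8,
                             rho_condition_B = -0.8,
                             n_trait_features_plant = 5L,
                             n_trait_features_microbe = 3L,
                             trait_noise_sd = 0.5,
                             frac_de_soil = frac_de_temperature / 2,
                             frac_de_genotype = frac_de_temperature / 2) {
  p <- list(n_plant_genes = as.integer(n_plant_genes),
            n_microbial_genes = as.integer(n_microbial_genes),
            n_pathways = as.integer(n_pathways),
            library_size_plant = as.integer(library_size_plant),
            library_size_microbe = as.integer(library_size_microbe),
            nb_dispersion = nb_dispersion,
            frac_de_temperature = frac_de_temperature,
            effect_size_logfc = effect_size_logfc,
            n_diffcorr_pairs = as.integer(n_diffcorr_pairs),
            rho_condition_A = rho_condition_A,
            rho_condition_B = rho_condition_B,
            n_trait_features_plant = as.integer(n_trait_features_plant),
            n_trait_features_microbe = as.integer(n_trait_features_microbe),
            trait_noise_sd = trait_noise_sd,
            frac_de_soil = frac_de_soil,
            frac_de_genotype = frac_de_genotype)
  fr <- c(p$frac_de_temperature, p$frac_de_soil, p$frac_de_genotype)
  if (any(fr < 0) || any(fr > 1)) stop("DE fractions must lie in [0, 1]")
  if (abs(p$rho_condition_A) >= 1 || abs(p$rho_condition_B) >= 1)
    stop("planted correlations must satisfy |rho| < 1")
  if (p$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (p$trait_noise_sd < 0) stop("trait_noise_sd must be non-negative")
  if (p$n_diffcorr_pairs > min(p$n_plant_genes, p$n_microbial_genes))
    stop("more planted pairs than available features")
  if (p$n_trait_features_plant > p$n_plant_genes ||
      p$n_trait_features_microbe > p$n_pathways)
    stop("more trait features than available features")
  structure(p, class = "generator_params")
}

#' Generate the factorial sample table
#'
#' One row per sample; factor levels fully crossed; sample ids unique. The
#' first temperature level is the optimal condition, the second the heat
#' condition.
#'
#' @param spec a [design_spec()].
#' @return data frame with `sample_id`, `genotype`, `soil`, `temperature`,
#'   `replicate`; the master seed travels along as attribute `"seed"`.
#' @export
#' @examples
#' nrow(generate_design(design_spec()))   # 48
generate_design <- function(spec) {
  if (!inherits(spec, "design_spec")) stop("invalid design spec")
  soils <- c("field", "autoclaved", paste0("soil", seq_len(spec$n_soils)))
  design <- expand.grid(
    replicate = seq_len(spec$n_reps),
    temperature = spec$temperature_levels,
    soil = soils[seq_len(spec$n_soils)],
    genotype = paste0("G", seq_len(spec$n_genotypes)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("genotype", "soil", "temperature", "replicate")]
  design <- data.frame(
    sample_id = sprintf("S%03d", seq_len(nrow(design))), design,
    stringsAsFactors = FALSE
  )
  attr(design, "seed") <- spec$seed
  attr(design, "temperature_levels") <- spec$temperature_levels
  design
}

# Pearson latent correlation that yields a target Spearman under a Gaussian
# copula: rho_S = (6/pi) asin(rho_P / 2)  =>  rho_P = 2 sin(pi rho_S / 6).
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate plant and microbial count matrices with a truth registry
#'
#' Plant counts follow a negative-binomial model (gene-specific log-normal
#' baselines x sample library factors), with designated genes carrying
#' genotype, soil, or temperature log-fold effects. Microbial counts are
#' compositional: log-normal per-sample proportions drawn into a multinomial
#' of the sample's library depth, so column sums equal the drawn depths
#' exactly. Planted cross-kingdom pairs share a Gaussian latent factor whose
#' correlation is `rho_condition_A` in the optimal-temperature samples and
#' `rho_condition_B` in the heat samples (targets on the Spearman scale; the
#' latent Pearson correlation is back-transformed through the Gaussian
#' copula). Planted trait features (plant genes and microbial pathways) load
#' on a per-sample trait latent that [generate_phenotypes()] later turns
#' into phenotypes. Everything planted is recorded in the truth registry.
#'
#' @param design output of [generate_design()].
#' @param params a [generator_params()].
#' @param seed overrides the seed carried by `design`.
#' @return list with `plant` (`count_matrix`), `microbe` (`count_matrix`),
#'   `annotation` (gene_id / pathway_id data frame), `truth` (registry:
#'   `de_genes`, `planted_pairs`, `trait_features`, plus internal latents
#'   used by the phenotype stage).
#' @export
generate_counts <- function(design, params = generator_params(),
                            seed = attr(design, "seed")) {
  if (is.null(seed)) seed <- 1L
  n <- nrow(design)
  if (n < 1) stop("empty design")
  if (n < 2 && params$n_diffcorr_pairs > 0)
    stop("planted correlations are undefined on a single sample")
  temp_levels <- attr(design, "temperature_levels")
  if (is.null(temp_levels)) temp_levels <- unique(design$temperature)
  hot <- design$temperature != temp_levels[1]
  autocl <- design$soil != design$soil[1]
  geno1 <- design$genotype == design$genotype[1]

  plant_ids <- sprintf("PG%04d", seq_len(params$n_plant_genes))
  microbe_ids <- sprintf("MG%04d", seq_len(params$n_microbial_genes))
  pathway_ids <- sprintf("EC%03d", seq_len(params$n_pathways))

  ## ---- feature role assignment (deterministic under the master seed) ----
  set.seed(seed)
  n_de_t <- round(params$frac_de_temperature * params$n_plant_genes)
  n_de_s <- round(params$frac_de_soil * params$n_plant_genes)
  n_de_g <- round(params$frac_de_genotype * params$n_plant_genes)
  roles_p <- sample(plant_ids)   # shuffled, then carved into disjoint blocks
  de_t_p <- roles_p[seq_len(n_de_t)]
  de_s_p <- roles_p[n_de_t + seq_len(n_de_s)]
  de_g_p <- roles_p[n_de_t + n_de_s + seq_len(n_de_g)]
  n_de_all <- n_de_t + n_de_s + n_de_g
  rest_p <- if (n_de_all > 0) roles_p[-seq_len(n_de_all)] else roles_p
  if (length(rest_p) < params$n_diffcorr_pairs + params$n_trait_features_plant)
    stop("feature budget exceeded: reduce DE fractions or planted features")
  pair_p <- rest_p[seq_len(params$n_diffcorr_pairs)]
  trait_p <- rest_p[params$n_diffcorr_pairs +
                      seq_len(params$n_trait_features_plant)]

  n_de_t_m <- round(params$frac_de_temperature * params$n_microbial_genes)
  n_de_s_m <- round(params$frac_de_soil * params$n_microbial_genes)
  roles_m <- sample(microbe_ids)
  de_t_m <- roles_m[seq_len(n_de_t_m)]
  de_s_m <- roles_m[n_de_t_m + seq_len(n_de_s_m)]
  pair_m <- roles_m[n_de_t_m + n_de_s_m + seq_len(params$n_diffcorr_pairs)]

  # gene -> pathway annotation: ~5% of genes unassigned, ~2% in two pathways
  pw <- sample(pathway_ids, params$n_microbial_genes, replace = TRUE)
  unassigned <- sample(microbe_ids,
                       max(round(0.05 * params$n_microbial_genes), 0))
  annotation <- data.frame(gene_id = microbe_ids, pathway_id = pw,
                           stringsAsFactors = FALSE)
  annotation <- annotation[!(annotation$gene_id %in% unassigned), ]
  multi <- sample(annotation$gene_id,
                  max(round(0.02 * params$n_microbial_genes), 0))
  if (length(multi))
    annotation <- rbind(annotation, data.frame(
      gene_id = multi,
      pathway_id = sample(pathway_ids, length(multi), replace = TRUE),
      stringsAsFactors = FALSE))
  rownames(annotation) <- NULL
  trait_pw <- sample(pathway_ids, params$n_trait_features_microbe)

  direction_t <- sample(c(1, -1), n_de_t, replace = TRUE)
  direction_s <- sample(c(1, -1), n_de_s, replace = TRUE)
  direction_g <- sample(c(1, -1), n_de_g, replace = TRUE)
  direction_tm <- sample(c(1, -1), n_de_t_m, replace = TRUE)
  direction_sm <- sample(c(1, -1), n_de_s_m, replace = TRUE)

  # shared latents: trait latent u (temperature-independent) and the
  # per-condition bivariate pair latents. Each trait feature mixes the
  # shared latent with its own component (0.6 u + 0.8 e_f, unit variance)
  # so planted features are correlated but individually identifiable.
  u <- stats::rnorm(n)
  e_trait_p <- matrix(stats::rnorm(n * params$n_trait_features_plant),
                      params$n_trait_features_plant, n)
  e_trait_m <- matrix(stats::rnorm(n * params$n_trait_features_microbe),
                      params$n_trait_features_microbe, n)
  lat_trait_p <- 0.6 * rep(u, each = nrow(e_trait_p)) + 0.8 * e_trait_p
  lat_trait_m <- 0.6 * rep(u, each = nrow(e_trait_m)) + 0.8 * e_trait_m
  rho_p_A <- spearman_to_pearson(params$rho_condition_A)
  rho_p_B <- spearman_to_pearson(params$rho_condition_B)
  z_plant <- matrix(stats::rnorm(n * params$n_diffcorr_pairs),
                    params$n_diffcorr_pairs, n)
  z_eps <- matrix(stats::rnorm(n * params$n_diffcorr_pairs),
                  params$n_diffcorr_pairs, n)
  rho_vec <- ifelse(hot, rho_p_B, rho_p_A)
  z_microbe <- sweep(z_plant, 2, rho_vec, "*") +
    sweep(z_eps, 2, sqrt(1 - rho_vec^2), "*")

  ## ---- plant counts: NB(mean = baseline * library * effects) ----
  set.seed(seed + 1L)
  log_mu <- stats::rnorm(params$n_plant_genes, 4, 1.5)
  names(log_mu) <- plant_ids
  log_mu[pair_p] <- 5.5        # planted pairs ride high so count noise is
  log_mu[trait_p] <- 5.5       # small relative to the latent signal
  lib_p <- stats::runif(n, params$library_size_plant[1],
                        params$library_size_plant[2])
  lib_factor <- lib_p / mean(lib_p)
  lfc <- params$effect_size_logfc * log(2)
  eff <- matrix(0, params$n_plant_genes, n, dimnames = list(plant_ids, NULL))
  if (n_de_t) eff[de_t_p, hot] <- eff[de_t_p, hot] + direction_t * lfc
  if (n_de_s) eff[de_s_p, autocl] <- eff[de_s_p, autocl] + direction_s * lfc
  if (n_de_g) eff[de_g_p, geno1] <- eff[de_g_p, geno1] + direction_g * lfc
  if (params$n_diffcorr_pairs) eff[pair_p, ] <- eff[pair_p, ] + z_plant
  if (params$n_trait_features_plant)
    eff[trait_p, ] <- eff[trait_p, ] + lat_trait_p
  mu <- outer(exp(log_mu), lib_factor) * exp(eff)
  size <- rep(1 / params$nb_dispersion, params$n_plant_genes)
  names(size) <- plant_ids
  size[c(pair_p, trait_p)] <- 50   # low dispersion on planted features
  plant <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = rep(size, times = n)),
                  nrow = params$n_plant_genes,
                  dimnames = list(plant_ids, design$sample_id))

  ## ---- microbial counts: log-normal proportions x multinomial depth ----
  set.seed(seed + 2L)
  alpha <- stats::rnorm(params$n_microbial_genes, 0, 1.2)
  names(alpha) <- microbe_ids
  alpha[pair_m] <- 2           # abundant, so multinomial noise is small
  eta <- matrix(stats::rnorm(params$n_microbial_genes * n, 0, 0.3),
                params$n_microbial_genes, n,
                dimnames = list(microbe_ids, NULL))
  if (n_de_t_m) eta[de_t_m, hot] <- eta[de_t_m, hot] + direction_tm * lfc
  if (n_de_s_m) eta[de_s_m, autocl] <- eta[de_s_m, autocl] + direction_sm * lfc
  if (params$n_diffcorr_pairs) eta[pair_m, ] <- eta[pair_m, ] + z_microbe
  for (k in seq_along(trait_pw)) {
    genes_k <- unique(annotation$gene_id[annotation$pathway_id == trait_pw[k]])
    if (length(genes_k))
      eta[genes_k, ] <- eta[genes_k, , drop = FALSE] +
        rep(0.8 * lat_trait_m[k, ], each = length(genes_k))
  }
  logp <- alpha + eta
  depths <- sample(seq(params$library_size_microbe[1],
                       params$library_size_microbe[2]), n, replace = TRUE)
  microbe <- matrix(0L, params$n_microbial_genes, n,
                    dimnames = list(microbe_ids, design$sample_id))
  for (j in seq_len(n)) {
    pj <- exp(logp[, j] - max(logp[, j]))
    microbe[, j] <- stats::rmultinom(1, depths[j], pj)[, 1]
  }

  ## ---- truth registry ----
  de_block <- function(ids, kingdom, factor, direction) {
    if (length(ids) == 0) return(NULL)
    data.frame(feature_id = ids, kingdom = kingdom, factor = factor,
               direction = direction, stringsAsFactors = FALSE)
  }
  de_genes <- rbind(
    de_block(de_t_p, "plant", "temperature", direction_t),
    de_block(de_s_p, "plant", "soil", direction_s),
    de_block(de_g_p, "plant", "genotype", direction_g),
    de_block(de_t_m, "microbe", "temperature", direction_tm),
    de_block(de_s_m, "microbe", "soil", direction_sm)
  )
  if (is.null(de_genes))
    de_genes <- data.frame(feature_id = character(), kingdom = character(),
                           factor = character(), direction = numeric(),
                           stringsAsFactors = FALSE)
  planted_pairs <- data.frame(
    plant_feature = pair_p, microbial_feature = pair_m,
    rho_A = rep(params$rho_condition_A, params$n_diffcorr_pairs),
    rho_B = rep(params$rho_condition_B, params$n_diffcorr_pairs),
    stringsAsFactors = FALSE
  )
  trait_features <- if (length(trait_p) + length(trait_pw) == 0) {
    data.frame(feature_id = character(), feature_type = character(),
               trait = character(), coefficient = numeric(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(
      c("shoot_biomass", "root_volume", "heat_score"),
      function(tr) data.frame(
        feature_id = c(trait_p, trait_pw),
        feature_type = c(rep("plant_gene", length(trait_p)),
                         rep("pathway", length(trait_pw))),
        trait = tr,
        coefficient = if (tr == "heat_score") -0.5 else
          if (tr == "shoot_biomass") 1.0 else 0.6,
        stringsAsFactors = FALSE)))
  }
  trait_pathway_members <- lapply(stats::setNames(trait_pw, trait_pw),
                                  function(p)
                                    unique(annotation$gene_id[
                                      annotation$pathway_id == p]))
  truth <- list(de_genes = de_genes, planted_pairs = planted_pairs,
                trait_features = trait_features,
                trait_latent = stats::setNames(u, design$sample_id),
                trait_plant_genes = trait_p, trait_pathways = trait_pw,
                trait_pathway_members = trait_pathway_members,
                seed = seed)
  list(plant = count_matrix(plant, "plant_gene"),
       microbe = count_matrix(microbe, "microbial_gene"),
       annotation = annotation, truth = truth)
}

#' Generate phenotypes linked to planted features
#'
#' Shoot biomass is a linear combination of the planted trait features'
#' standardized log abundances plus Gaussian noise
#' (`biomass = 10 + sum_f c_f A_f + N(0, sd)` with the biomass coefficients
#' from the truth registry). Root volume tracks the same signal at a
#' smaller gain. The ordinal heat score is a continuous latent stress
#' variable — a temperature shift minus a loading on the planted signal —
#' thresholded into 5 bins (0 = unstressed, 4 = withered), which makes the
#' heat score negatively correlated with biomass by construction.
#' Root:shoot ratio decreases under heat independently of the planted
#' signal.
#'
#' @param design output of [generate_design()].
#' @param plant,microbe count matrices from [generate_counts()].
#' @param truth the truth registry from [generate_counts()].
#' @param params the [generator_params()] used for generation.
#' @param seed overrides the design's master seed.
#' @return `design` with columns `heat_score` (integer 0-4),
#'   `shoot_biomass`, `root_volume`, `root_shoot_ratio` appended.
#' @export
generate_phenotypes <- function(design, plant, microbe, truth,
                                params = generator_params(),
                                seed = attr(design, "seed")) {
  if (is.null(seed)) seed <- truth$seed
  n <- nrow(design)
  tf <- unique(truth$trait_features[
    truth$trait_features$trait == "shoot_biomass",
    c("feature_id", "feature_type", "coefficient")])
  if (nrow(tf) > 0 && !all(
    tf$feature_id[tf$feature_type == "plant_gene"] %in% rownames(plant)))
    stop("truth registry lists plant trait features absent from the matrix")

  # standardized log abundance per planted feature; pathway features use
  # their member genes' aggregated counts (membership recorded in truth)
  signal <- rep(0, n)
  if (nrow(tf) > 0) {
    mat <- vapply(seq_len(nrow(tf)), function(i) {
      if (tf$feature_type[i] == "plant_gene") {
        v <- log1p(as.numeric(plant[tf$feature_id[i], ]))
      } else {
        genes <- truth$trait_pathway_members[[tf$feature_id[i]]]
        v <- log1p(as.numeric(colSums(microbe[genes, , drop = FALSE])))
      }
      if (stats::sd(v) == 0) rep(0, n) else as.numeric(scale(v))
    }, numeric(n))
    signal <- as.numeric(mat %*% tf$coefficient)
  }

  set.seed(seed + 3L)
  temp_levels <- attr(design, "temperature_levels")
  if (is.null(temp_levels)) temp_levels <- unique(design$temperature)
  hot <- as.numeric(design$temperature != temp_levels[1])

  shoot_biomass <- 10 + signal + stats::rnorm(n, 0, params$trait_noise_sd)
  root_volume <- 3 + 0.6 * signal + stats::rnorm(n, 0, params$trait_noise_sd)
  # latent stress: temperature shift plus the registered (negative)
  # per-feature heat coefficients, binned into quintile-style cutpoints of
  # its standardized distribution -> ordinal 0-4 score
  stress <- 1.3 * hot - 0.5 * signal + stats::rnorm(n, 0, 0.35)
  stress_z <- if (stats::sd(stress) == 0) stress else
    as.numeric(scale(stress))
  heat_score <- as.integer(cut(stress_z,
                               c(-Inf, -0.84, -0.25, 0.25, 0.84, Inf),
                               labels = FALSE)) - 1L
  root_shoot_ratio <- pmax(
    0.8 - 0.25 * hot + stats::rnorm(n, 0, max(params$trait_noise_sd / 5,
                                              0.01)),
    0.05)

  out <- design
  out$heat_score <- heat_score
  out$shoot_biomass <- shoot_biomass
  out$root_volume <- root_volume
  out$root_shoot_ratio <- root_shoot_ratio
  out
}
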