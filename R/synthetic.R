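#' Configuration for the synthetic community generator
#'
#' Defines a seeded generative model for genus-level compositional count
#' data with planted correlation modules and a module-driven N2O response.
#' Taxa in module m share a latent per-sample factor f[m,j]; taxon i's
#' latent log-abundance is mu[i] + lambda * f[m(i),j] + eps[ij] with
#' lambda = sqrt(latent_corr) and sd(eps) = sqrt(1 - latent_corr), so the
#' within-module latent correlation equals `latent_corr` exactly. Module-0
#' (background) taxa are mutually independent. Counts are multinomial draws
#' of `library_size` reads from the softmax composition, and
#' N2O[j] = baseline + sum_m effect[m] * f[m,j] + noise.
#'
#' @param n_treatments,reps_per_treatment study design; samples are
#'   `n_treatments * reps_per_treatment` columns.
#' @param n_taxa taxa in this kingdom.
#' @param n_modules number of planted modules; `module_sizes` must have this
#'   length and sum to at most `n_taxa` (remaining taxa form independent
#'   background, module 0).
#' @param module_sizes integer vector of taxa per module.
#' @param latent_corr target within-module latent correlation in [0, 1).
#' @param treatment_shift `n_treatments x n_modules` matrix of per-treatment
#'   mean shifts of the module factors (log scale).
#' @param library_size sequencing reads per sample (multinomial total).
#' @param n2o_effects signed per-module coefficients on the N2O rate
#'   (nmol N g-1 h-1 per factor unit).
#' @param n2o_noise_sd,baseline_n2o Gaussian noise sd and intercept of the
#'   N2O response (nmol N g-1 h-1).
#' @param mu_log optional per-taxon baseline log-abundances; drawn
#'   N(0, mu_log_sd) when `NULL`.
#' @param mu_log_sd sd of baseline log-abundances (controls how uneven the
#'   community is, hence how many observed zeros appear).
#' @param n_env number of pure-noise environmental covariates to emit.
#' @param treatment_names optional treatment labels.
#' @param kingdom taxon kingdom tag.
#' @param seed integer RNG seed; identical configs give bit-identical data.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_treatments = 3, reps_per_treatment = 3,
                             n_taxa = 60, n_modules = 3,
                             module_sizes = rep(10, n_modules),
                             latent_corr = 0.85,
                             treatment_shift = matrix(0, n_treatments, n_modules),
                             library_size = 20000,
                             n2o_effects = rep(0, n_modules),
                             n2o_noise_sd = 0.02, baseline_n2o = 0.0005,
                             mu_log = NULL, mu_log_sd = 2, n_env = 5,
                             treatment_names = paste0("T", seq_len(n_treatments)),
                             kingdom = "bacteria", seed = 1L) {
  if (length(module_sizes) != n_modules)
    stop_n2onet("module_sizes must have length n_modules", "n2onet_config_error")
  if (sum(module_sizes) > n_taxa)
    stop_n2onet("module_sizes exceed n_taxa", "n2onet_config_error")
  if (latent_corr < 0 || latent_corr >= 1)
    stop_n2onet("latent_corr must lie in [0, 1)", "n2onet_config_error")
  if (library_size < 1)
    stop_n2onet("library_size must be positive", "n2onet_config_error")
  treatment_shift <- as.matrix(treatment_shift)
  if (!all(dim(treatment_shift) == c(n_treatments, n_modules)))
    stop_n2onet("treatment_shift must be n_treatments x n_modules", "n2onet_config_error")
  if (length(n2o_effects) != n_modules)
    stop_n2onet("n2o_effects must have length n_modules", "n2onet_config_error")
  if (!is.null(mu_log) && length(mu_log) != n_taxa)
    stop_n2onet("mu_log must have length n_taxa", "n2onet_config_error")
  if (n2o_noise_sd <= 0)
    stop_n2onet("n2o_noise_sd must be positive", "n2onet_config_error")
  structure(list(n_treatments = n_treatments,
                 reps_per_treatment = reps_per_treatment, n_taxa = n_taxa,
                 n_modules = n_modules, module_sizes = module_sizes,
                 latent_corr = latent_corr, treatment_shift = treatment_shift,
                 library_size = library_size, n2o_effects = n2o_effects,
                 n2o_noise_sd = n2o_noise_sd, baseline_n2o = baseline_n2o,
                 mu_log = mu_log, mu_log_sd = mu_log_sd, n_env = n_env,
                 treatment_names = treatment_names, kingdom = kingdom,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic community with planted modules and N2O response
#'
#' @param config a [synthetic_config()].
#' @return A list with elements
#'   \describe{
#'     \item{table}{[count_table] of multinomial counts (column sums equal
#'       `library_size` exactly).}
#'     \item{n2o}{data.frame `sample_id`, `rate` (nmol N g-1 h-1).}
#'     \item{env}{data.frame of `n_env` independent standard-normal soil
#'       covariates per sample.}
#'     \item{truth}{ground truth: `true_partition` (taxon -> module, 0 =
#'       background), `true_effect_signs` (per module, in \{-1, 0, 1\}),
#'       `factors` (module x sample latent factors), `generator_seed`.}
#'   }
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_s <- config$n_treatments * config$reps_per_treatment
  treat_idx <- rep(seq_len(config$n_treatments), each = config$reps_per_treatment)
  treatment <- config$treatment_names[treat_idx]
  prefix <- substr(config$kingdom, 1L, 1L)
  samples <- sprintf("%s_s%02d", prefix, seq_len(n_s))
  taxa <- sprintf("%s_g%03d", prefix, seq_len(config$n_taxa))

  assignment <- integer(config$n_taxa)
  pos <- 1L
  for (m in seq_len(config$n_modules)) {
    if (config$module_sizes[m] > 0) {
      assignment[pos:(pos + config$module_sizes[m] - 1L)] <- m
      pos <- pos + config$module_sizes[m]
    }
  }
  names(assignment) <- taxa

  mu <- config$mu_log %||% rnorm(config$n_taxa, 0, config$mu_log_sd)
  lambda <- sqrt(config$latent_corr)
  sd_eps <- sqrt(1 - config$latent_corr)

  # latent module factors: unit variance around per-treatment means
  f <- matrix(rnorm(config$n_modules * n_s), config$n_modules, n_s)
  if (config$n_modules > 0)
    f <- f + t(config$treatment_shift[treat_idx, , drop = FALSE])

  x <- matrix(mu, config$n_taxa, n_s)
  in_mod <- assignment > 0L
  if (any(in_mod))
    x[in_mod, ] <- x[in_mod, , drop = FALSE] +
      lambda * f[assignment[in_mod], , drop = FALSE] +
      matrix(rnorm(sum(in_mod) * n_s, 0, sd_eps), sum(in_mod), n_s)
  if (any(!in_mod))
    x[!in_mod, ] <- x[!in_mod, , drop = FALSE] +
      matrix(rnorm(sum(!in_mod) * n_s), sum(!in_mod), n_s)

  p <- apply(x, 2, function(col) { e <- exp(col - max(col)); e / sum(e) })
  counts <- vapply(seq_len(n_s),
                   function(j) rmultinom(1L, config$library_size, p[, j])[, 1L],
                   integer(config$n_taxa))
  dimnames(counts) <- list(taxa, samples)

  rate <- config$baseline_n2o + as.numeric(crossprod(f, config$n2o_effects)) +
    rnorm(n_s, 0, config$n2o_noise_sd)

  env <- matrix(rnorm(n_s * config$n_env), n_s, config$n_env,
                dimnames = list(samples, paste0("soil_v", seq_len(config$n_env))))

  meta <- data.frame(sample_id = samples, treatment = treatment,
                     replicate = rep(seq_len(config$reps_per_treatment),
                                     config$n_treatments),
                     stringsAsFactors = FALSE)
  list(table = count_table(counts, kingdom = config$kingdom, metadata = meta),
       n2o = data.frame(sample_id = samples, rate = rate,
                        stringsAsFactors = FALSE),
       env = as.data.frame(env),
       truth = list(true_partition = assignment,
                    true_effect_signs = sign(config$n2o_effects),
                    factors = f, generator_seed = config$seed))
}

#' Random phylogeny over a taxon set
#'
#' Seeded random rooted binary tree with positive branch lengths, one leaf
#' per taxon; supports Faith's PD in [alpha_diversity()].
#'
#' @param taxa character vector of unique taxon names (length >= 2).
#' @param seed integer seed.
#' @return A newick string.
#' @export
generate_tree <- function(taxa, seed = 1L) {
  if (anyDuplicated(taxa))
    stop_n2onet("duplicate taxon names", "n2onet_input_error")
  if (length(taxa) < 2L)
    stop_n2onet("need at least 2 taxa", "n2onet_input_error")
  set.seed(as.integer(seed))
  tr <- ape::rtree(length(taxa), rooted = TRUE)
  tr$tip.label <- taxa
  ape::write.tree(tr)
}

#' Generator presets
#'
#' `preset_paper_mimic()` emulates the study design this pipeline targets:
#' 3 treatments (RF, VE4, VE7) x 3 replicates, 60 genera per kingdom,
#' modules whose factors shift with treatment, and an N2O response whose
#' treatment means sit near (0.0005, 0.43, 0.008) nmol N g-1 h-1 with
#' module 1 acting negatively and module 2 positively. `preset_power()` is
#' the high-replication variant (3 x 10 samples, latent_corr 0.9, effects
#' -0.5/+0.5) used for recovery assertions, where n = 9 would be hopeless.
#'
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @param seed integer seed.
#' @return A [synthetic_config()].
#' @export
preset_paper_mimic <- function(kingdom = "bacteria", seed = 1L) {
  if (kingdom == "bacteria") {
    synthetic_config(
      n_treatments = 3, reps_per_treatment = 3, n_taxa = 60, n_modules = 3,
      module_sizes = c(10, 10, 10), latent_corr = 0.85,
      treatment_shift = rbind(c(0, 0, 0), c(-2.5, 2.5, 0), c(0.5, 0.28, 0)),
      library_size = 20000, n2o_effects = c(-0.052, 0.12, 0),
      n2o_noise_sd = 0.02, baseline_n2o = 0.0005,
      treatment_names = c("RF", "VE4", "VE7"), kingdom = "bacteria",
      seed = seed)
  } else {
    synthetic_config(
      n_treatments = 3, reps_per_treatment = 3, n_taxa = 60, n_modules = 4,
      module_sizes = c(8, 8, 8, 8), latent_corr = 0.85,
      treatment_shift = rbind(c(0, 0, 0, 0), c(1.5, -1.5, 0.5, 0),
                              c(-0.5, 1, -1, 0.3)),
      library_size = 20000, n2o_effects = c(0, 0, 0, 0),
      n2o_noise_sd = 0.02, baseline_n2o = 0.0005,
      treatment_names = c("RF", "VE4", "VE7"), kingdom = "fungi",
      seed = seed)
  }
}

#' @rdname preset_paper_mimic
#' @export
preset_power <- function(kingdom = "bacteria", seed = 1L) {
  synthetic_config(
    n_treatments = 3, reps_per_treatment = 10, n_taxa = 60, n_modules = 3,
    module_sizes = c(12, 12, 12), latent_corr = 0.9,
    # module-1 and module-2 shift vectors are orthogonal across treatments so
    # the treatment design induces no cross-module correlation
    treatment_shift = rbind(c(0, 0.9, 0), c(0.8, -0.45, 0), c(-0.8, -0.45, 0)),
    library_size = 50000, n2o_effects = c(-0.5, 0.5, 0),
    n2o_noise_sd = 0.2, baseline_n2o = 1,
    treatment_names = c("RF", "VE4", "VE7"), kingdom = kingdom, seed = seed)
}

#' Simulate a paired bacteria + fungi dataset
#'
#' Runs [generate_community()] once per kingdom (independent seeds derived
#' from `seed`). The N2O vector comes from the bacterial generator (the
#' fungal config's effects are ignored), mirroring a system whose
#' denitrification response is driven by bacterial modules.
#'
#' @param preset `"paper_mimic"` or `"power"`.
#' @param seed integer global seed.
#' @return list with `bacteria`, `fungi` (each as [generate_community()]
#'   output), shared `n2o`, `env` (bacterial draw), `metadata`, and `tree`
#'   (newick over bacterial taxa).
#' @export
simulate_dataset <- function(preset = c("paper_mimic", "power"), seed = 1L) {
  preset <- match.arg(preset)
  mk <- if (preset == "paper_mimic") preset_paper_mimic else preset_power
  bac <- generate_community(mk("bacteria", seed = derive_seed(seed, 1L)))
  fun <- generate_community(mk("fungi", seed = derive_seed(seed, 2L)))
  # fungal samples are the same physical soils: reuse the bacterial metadata ids
  colnames(fun$table$counts) <- colnames(bac$table$counts)
  fun$table$metadata <- bac$table$metadata
  fun$n2o <- NULL
  list(bacteria = bac, fungi = fun, n2o = bac$n2o, env = bac$env,
       metadata = bac$table$metadata,
       tree = generate_tree(rownames(bac$table$counts),
                            seed = derive_seed(seed, 3L)))
}

#' Write a simulated dataset to plain-text files
#'
#' Emits counts (TSV per kingdom), metadata TSV, N2O TSV, environmental
#' covariates TSV, the bacterial taxon tree (newick) and the ground truth
#' (JSON) into `dir`.
#'
#' @param ds output of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(ds$bacteria$table, file.path(dir, "counts_bacteria.tsv"))
  write_count_table(ds$fungi$table, file.path(dir, "counts_fungi.tsv"))
  utils::write.table(ds$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$n2o, file.path(dir, "n2o.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(ds$env), ds$env),
                     file.path(dir, "env.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(ds$tree, file.path(dir, "tree.nwk"))
  truth <- list(
    bacteria = list(true_partition = as.list(ds$bacteria$truth$true_partition),
                    true_effect_signs = ds$bacteria$truth$true_effect_signs,
                    generator_seed = ds$bacteria$truth$generator_seed),
    fungi = list(true_partition = as.list(ds$fungi$truth$true_partition),
                 true_effect_signs = ds$fungi$truth$true_effect_signs,
                 generator_seed = ds$fungi$truth$generator_seed))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
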