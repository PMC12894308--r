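#' Build a validated pipeline configuration
#'
#' Collects every tunable of the analysis chain in one object. Either a
#' simulation `preset` ("paper_mimic" or "power") or a set of input
#' `paths` must be supplied. Unknown arguments are rejected.
#'
#' @param preset simulation preset name, or `NULL` when reading files.
#' @param paths named list of input files (`counts_bacteria`,
#'   `counts_fungi`, `metadata`, `n2o`, optionally `env`, `tree`); ignored
#'   when `preset` is set.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param out output directory for tables, networks and `report.json`
#'   (`NULL` = return the report only).
#' @param min_rel_abund,min_prevalence low-abundance filter settings.
#' @param rho_min,p_max edge-calling thresholds.
#' @param fdr apply BH correction to correlation p-values before
#'   thresholding.
#' @param zi_threshold keystone Zi cutoff.
#' @param robustness_fractions,robustness_reps robustness curve settings.
#' @param cohesion_null_iters taxa-shuffle null iterations for cohesion.
#' @param anosim_n_perm ANOSIM permutations.
#' @param rf_n_trees,rf_n_perm forest size and permutation count for the
#'   driver analysis.
#' @param min_module_size smallest module carried into the
#'   module-abundance regressions and driver predictors.
#' @param ... unknown keys; any use is an error.
#' @return List of class `run_config`.
#' @export
run_config <- function(preset = "paper_mimic", paths = NULL, seed = 1L,
                       out = NULL, min_rel_abund = 1e-4, min_prevalence = 2,
                       rho_min = 0.7, p_max = 0.05, fdr = FALSE,
                       zi_threshold = 2.5,
                       robustness_fractions = seq(0.1, 0.9, by = 0.1),
                       robustness_reps = 100, cohesion_null_iters = 0,
                       anosim_n_perm = 999, rf_n_trees = 500,
                       rf_n_perm = 199, min_module_size = 3, ...) {
  extra <- list(...)
  if (length(extra))
    stop_n2onet(paste0("unknown configuration keys: ",
                       paste(names(extra), collapse = ", ")),
                "n2onet_config_error")
  if (is.null(preset) && is.null(paths))
    stop_n2onet("either a preset or input paths are required", "n2onet_config_error")
  if (!is.null(preset) && !preset %in% c("paper_mimic", "power"))
    stop_n2onet("preset must be 'paper_mimic' or 'power'", "n2onet_config_error")
  if (!is.numeric(rho_min) || rho_min <= 0 || rho_min >= 1)
    stop_n2onet("rho_min must lie in (0, 1)", "n2onet_config_error")
  if (!is.numeric(p_max) || p_max <= 0 || p_max > 1)
    stop_n2onet("p_max must lie in (0, 1]", "n2onet_config_error")
  if (any(robustness_fractions <= 0 | robustness_fractions >= 1))
    stop_n2onet("robustness_fractions must lie strictly in (0, 1)",
                "n2onet_config_error")
  for (nm in c("min_prevalence", "robustness_reps", "anosim_n_perm",
               "rf_n_trees", "rf_n_perm", "min_module_size")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1)
      stop_n2onet(paste0(nm, " must be a positive count"),
                  "n2onet_config_error")
  }
  structure(list(preset = preset, paths = paths, seed = as.integer(seed),
                 out = out, min_rel_abund = min_rel_abund,
                 min_prevalence = min_prevalence, rho_min = rho_min,
                 p_max = p_max, fdr = fdr, zi_threshold = zi_threshold,
                 robustness_fractions = robustness_fractions,
                 robustness_reps = robustness_reps,
                 cohesion_null_iters = cohesion_null_iters,
                 anosim_n_perm = anosim_n_perm, rf_n_trees = rf_n_trees,
                 rf_n_perm = rf_n_perm, min_module_size = min_module_size),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

load_inputs <- function(config) {
  if (!is.null(config$preset))
    return(simulate_dataset(config$preset, seed = derive_seed(config$seed, 0L)))
  p <- config$paths
  for (key in c("counts_bacteria", "counts_fungi", "metadata", "n2o")) {
    if (is.null(p[[key]]) || !file.exists(p[[key]]))
      stop_n2onet(paste0("missing input file for '", key, "': ",
                         p[[key]] %||% "<unset>"), "n2onet_io_error")
  }
  bac <- read_count_table(p$counts_bacteria, p$metadata, kingdom = "bacteria")
  fun <- read_count_table(p$counts_fungi, p$metadata, kingdom = "fungi")
  n2o <- utils::read.delim(p$n2o, stringsAsFactors = FALSE)
  env <- NULL
  if (!is.null(p$env)) {
    env <- utils::read.delim(p$env, stringsAsFactors = FALSE, row.names = 1)
  }
  tree <- if (!is.null(p$tree)) paste(readLines(p$tree), collapse = "") else NULL
  list(bacteria = list(table = bac), fungi = list(table = fun),
       n2o = n2o, env = env, metadata = bac$metadata, tree = tree)
}

check_sample_consistency <- function(ds) {
  ids <- colnames(ds$bacteria$table$counts)
  probes <- list(fungal_counts = colnames(ds$fungi$table$counts),
                 n2o = ds$n2o$sample_id,
                 metadata = ds$metadata$sample_id)
  if (!is.null(ds$env)) probes$env <- rownames(ds$env)
  for (nm in names(probes)) {
    miss <- setdiff(ids, probes[[nm]])
    if (length(miss))
      stop_n2onet(paste0("samples missing from ", nm, ": ",
                         paste(miss, collapse = ", ")),
                  "n2onet_consistency_error")
  }
  invisible(TRUE)
}

analyse_kingdom <- function(table, n2o, config, kseed) {
  out <- list()
  filt <- filter_low_abundance(table, config$min_rel_abund,
                               config$min_prevalence)
  norm <- normalize_counts(filt)
  z <- suppressWarnings(zscore_rows(norm$norm_abund))
  out$preprocess <- list(
    n_taxa_in = nrow(table$counts), n_taxa_kept = nrow(filt$counts),
    tmm_factor = as.list(round(norm$tmm_factor, 10)))

  corr <- spearman_matrix(norm)
  net <- threshold_network(corr, rho_min = config$rho_min,
                           p_max = config$p_max, kingdom = filt$kingdom,
                           fdr = config$fdr)
  out$network <- list(rho_min = config$rho_min, p_max = config$p_max,
                      fdr = config$fdr,
                      n_candidate_taxa = nrow(corr$rho),
                      n_edges = igraph::ecount(net))

  treatments <- unique(filt$metadata$treatment)
  tnets <- lapply(treatments, function(tr) treatment_subnetwork(net, filt, tr))
  names(tnets) <- treatments
  snets <- lapply(colnames(filt$counts),
                  function(s) sample_subnetwork(net, filt, s))
  names(snets) <- colnames(filt$counts)

  topo_global <- topology_summary(net)
  topo_treat <- do.call(rbind, lapply(tnets, topology_summary))
  topo_treat <- cbind(treatment = treatments, topo_treat)
  topo_sample <- do.call(rbind, lapply(snets, topology_summary))
  topo_sample <- cbind(sample_id = names(snets), topo_sample)
  out$topology <- list(global = topo_global, by_treatment = topo_treat,
                       by_sample = topo_sample)

  part <- NULL
  keystones <- NULL
  if (igraph::ecount(net) > 0) {
    part <- detect_modules(net, seed = derive_seed(kseed, 4L))
    keystones <- within_module_degree_z(net, part, config$zi_threshold)
    out$modules <- list(
      modularity_Q = part$modularity_Q,
      n_modules = length(unique(part$assignment)),
      n_major_modules = sum(table(part$assignment) >= config$min_module_size),
      keystones = keystones$node[keystones$keystone])
  } else {
    out$modules <- list(error = "edgeless network: no module partition")
  }

  rob <- lapply(seq_along(tnets), function(i)
    robustness_curve(tnets[[i]], fractions = config$robustness_fractions,
                     reps = config$robustness_reps,
                     seed = derive_seed(kseed, 10L + i)))
  names(rob) <- treatments
  rob_tests <- list()
  if (length(treatments) >= 2) {
    cmb <- utils::combn(treatments, 2)
    for (k in seq_len(ncol(cmb))) {
      cr <- compare_robustness(rob[[cmb[1, k]]], rob[[cmb[2, k]]])
      rob_tests[[paste(cmb[1, k], cmb[2, k], sep = "_vs_")]] <-
        list(t = cr$t, p = cr$p, degenerate = cr$degenerate)
    }
  }
  coh <- cohesion(norm, corr, null_iters = config$cohesion_null_iters,
                  seed = derive_seed(kseed, 20L))
  out$stability <- list(
    robustness_mean_at_half = vapply(rob, function(r)
      unname(r$mean[match(0.5, r$fractions)]), numeric(1)),
    robustness_tests = rob_tests,
    pos_cohesion = as.list(coh$pos_cohesion),
    neg_cohesion = as.list(coh$neg_cohesion))

  div <- alpha_diversity(filt)
  nb <- vapply(treatments, function(tr)
    levins_breadth(filt, tr)$community_mean, numeric(1))
  an <- anosim_test(bray_curtis(norm), filt$metadata$treatment,
                    n_perm = config$anosim_n_perm,
                    seed = derive_seed(kseed, 30L))
  out$ecostats <- list(diversity = div,
                       niche_breadth_by_treatment = as.list(nb),
                       anosim = list(R = an$R, p = an$p, n_perm = an$n_perm))

  modreg <- NULL
  if (!is.null(part)) {
    major <- names(which(table(part$assignment) >= config$min_module_size))
    sub <- part
    sub$assignment <- part$assignment[part$assignment %in% as.integer(major)]
    if (length(sub$assignment))
      modreg <- module_abundance_regression(z, sub, n2o)
  }
  out$module_regression <- modreg

  feat <- cbind(topo_sample[, c("n_edges", "n_pos_edges", "n_neg_edges",
                                "n_vertices", "avg_degree", "mean_clustering",
                                "centralization_betweenness", "pos_neg_ratio")],
                pos_cohesion = unname(coh$pos_cohesion),
                neg_cohesion = unname(coh$neg_cohesion))
  rownames(feat) <- topo_sample$sample_id
  out$pearson_screen <- pearson_screen(feat, n2o)

  list(report = out, filtered = filt, norm = norm, z = z, corr = corr,
       net = net, part = part, keystones = keystones, features = feat,
       diversity = div, robustness = rob, cohesion = coh)
}

module_mean_block <- function(z, part, min_size, prefix) {
  if (is.null(part)) return(NULL)
  tab <- table(part$assignment)
  major <- as.integer(names(tab)[tab >= min_size])
  if (!length(major)) return(NULL)
  blk <- vapply(major, function(m) {
    taxa <- intersect(names(part$assignment)[part$assignment == m],
                      rownames(z))
    colMeans(z[taxa, , drop = FALSE])
  }, numeric(ncol(z)))
  colnames(blk) <- paste0(prefix, "_module_", major)
  blk
}

safe_composite <- function(vars, name) {
  tryCatch(suppressWarnings(composite_index(vars, name)),
           n2onet_error = function(e) NULL, error = function(e) NULL)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest -> preprocess -> network inference ->
#' topology/modules/keystones -> stability -> ecological statistics ->
#' random-forest driver attribution for both kingdoms, writes the output
#' tables and a machine-readable `report.json` when `config$out` is set,
#' and returns the report. Identical config + seed gives an identical
#' report.
#'
#' @param config a [run_config()].
#' @return The report (nested list), invisibly when `config$out` is set.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ds <- load_inputs(config)
  check_sample_consistency(ds)
  report <- list(provenance = list(
    package = "n2onet",
    version = as.character(utils::packageVersion("n2onet")),
    seed = config$seed, preset = config$preset,
    rho_min = config$rho_min, p_max = config$p_max, fdr = config$fdr,
    min_rel_abund = config$min_rel_abund,
    min_prevalence = config$min_prevalence,
    zi_threshold = config$zi_threshold,
    robustness_reps = config$robustness_reps,
    anosim_n_perm = config$anosim_n_perm,
    rf_n_trees = config$rf_n_trees, rf_n_perm = config$rf_n_perm))
  report$warnings <- list()

  kingdoms <- list()
  state <- list()
  for (kd in c("bacteria", "fungi")) {
    kseed <- derive_seed(config$seed, if (kd == "bacteria") 100L else 200L)
    res <- tryCatch(
      analyse_kingdom(ds[[kd]]$table, ds$n2o, config, kseed),
      error = function(e) e)
    if (inherits(res, "error")) {
      kingdoms[[kd]] <- list(error = conditionMessage(res))
      report$warnings <- c(report$warnings,
                           paste0(kd, " stage failed: ", conditionMessage(res)))
    } else {
      kingdoms[[kd]] <- res$report
      state[[kd]] <- res
    }
  }
  report$kingdoms <- kingdoms

  report$n2o <- list(
    by_treatment = as.list(tapply(ds$n2o$rate,
                                  ds$metadata$treatment[
                                    match(ds$n2o$sample_id,
                                          ds$metadata$sample_id)], mean)),
    anova_lsd = local({
      al <- anova_lsd(ds$n2o$rate,
                      ds$metadata$treatment[match(ds$n2o$sample_id,
                                                  ds$metadata$sample_id)])
      list(F = al$F, p = al$p, letters = as.list(al$letters))
    }))

  drv <- tryCatch(
    run_driver_stage(ds, state, config),
    error = function(e) list(error = conditionMessage(e)))
  report$drivers <- drv

  if (!is.null(config$out)) {
    write_run_outputs(report, state, ds, config)
    invisible(report)
  } else report
}

run_driver_stage <- function(ds, state, config) {
  preds <- list()
  if (!is.null(ds$env)) {
    ci <- safe_composite(ds$env, "soil")
    if (!is.null(ci)) preds$soil <- ci$scores
  }
  for (kd in names(state)) {
    st <- state[[kd]]
    dv <- st$diversity[, c("shannon", "simpson", "pielou", "coverage", "heip")]
    ci <- safe_composite(dv, paste0(kd, "_diversity"))
    if (!is.null(ci)) preds[[paste0(kd, "_diversity")]] <- ci$scores
    keep <- vapply(st$features, function(x)
      is.numeric(x) && all(is.finite(x)) && sd(x) > 0, logical(1))
    if (sum(keep) >= 2) {
      ci <- safe_composite(st$features[, keep, drop = FALSE],
                           paste0(kd, "_network"))
      if (!is.null(ci)) preds[[paste0(kd, "_network")]] <- ci$scores
    }
    blk <- module_mean_block(st$z, st$part, config$min_module_size,
                             substr(kd, 1, 3))
    if (!is.null(blk)) for (cn in colnames(blk)) preds[[cn]] <- blk[, cn]
  }
  if (!length(preds))
    stop_n2onet("no usable driver predictors", "n2onet_input_error")
  x <- do.call(cbind, preds)
  rate <- ds$n2o$rate[match(ds$metadata$sample_id, ds$n2o$sample_id)]
  sig <- permutation_significance(x, rate, n_trees = config$rf_n_trees,
                                  n_perm = config$rf_n_perm,
                                  seed = derive_seed(config$seed, 300L))
  ord <- order(-sig$observed$importance)
  list(importance = as.list(sig$observed$importance[ord]),
       perm_p = as.list(sig$perm_p[ord]),
       stars = as.list(sig$stars[ord]),
       model_r2 = sig$observed$model_r2, model_p = sig$model_p,
       n_trees = config$rf_n_trees, n_perm = config$rf_n_perm,
       mtry = sig$observed$mtry)
}

write_run_outputs <- function(report, state, ds, config) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  for (kd in names(state)) {
    st <- state[[kd]]
    write_network(st$net,
                  file.path(config$out, paste0("network_", kd, ".tsv")),
                  file.path(config$out, paste0("network_", kd, ".graphml")))
    utils::write.table(st$report$topology$by_sample,
                       file.path(config$out, paste0("topology_", kd, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(st$keystones))
      utils::write.table(st$keystones,
                         file.path(config$out, paste0("zi_", kd, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(st$diversity,
                       file.path(config$out, paste0("diversity_", kd, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    coh <- data.frame(sample_id = st$cohesion$samples,
                      pos_cohesion = unname(st$cohesion$pos_cohesion),
                      neg_cohesion = unname(st$cohesion$neg_cohesion))
    utils::write.table(coh,
                       file.path(config$out, paste0("cohesion_", kd, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$drivers$importance)) {
    imp <- data.frame(predictor = names(report$drivers$importance),
                      importance = unlist(report$drivers$importance),
                      perm_p = unlist(report$drivers$perm_p),
                      stars = unlist(report$drivers$stars))
    utils::write.table(imp, file.path(config$out, "driver_importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report, file.path(config$out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(NULL)
}
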