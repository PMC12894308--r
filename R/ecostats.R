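#' Alpha diversity indices
#'
#' Per-sample Shannon H = -sum p ln p (nats), Gini-Simpson 1 - sum p^2,
#' Pielou evenness H / ln S, Good's coverage 1 - F1/N (F1 = taxa observed
#' exactly once), Heip evenness (e^H - 1)/(S - 1), and optionally Faith's
#' phylogenetic diversity (total branch length of the minimal subtree
#' spanning the observed taxa, including the path to the root, as common
#' amplicon toolchains compute it). Pielou and Heip are 0 (flagged via NA
#' -> 0 convention) for single-taxon samples.
#'
#' @param table a [count_table].
#' @param tree optional newick string or [ape::read.tree] phylo object;
#'   required for the `pd` column. Every taxon observed in any sample must
#'   be a tip of the tree.
#' @return data.frame with one row per sample: `sample_id`, `richness`,
#'   `shannon`, `simpson`, `pielou`, `coverage`, `heip` and, with a tree,
#'   `pd`.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  stopifnot(inherits(table, "count_table"))
  counts <- table$counts
  if (any(colSums(counts) <= 0))
    stop_n2onet("every sample needs at least one read", "n2onet_input_error")
  res <- lapply(colnames(counts), function(s) {
    x <- counts[, s]
    n <- sum(x)
    p <- x[x > 0] / n
    S <- length(p)
    H <- -sum(p * log(p))
    data.frame(sample_id = s, richness = S, shannon = H,
               simpson = 1 - sum(p^2),
               pielou = if (S > 1) H / log(S) else 0,
               coverage = 1 - sum(x == 1) / n,
               heip = if (S > 1) (exp(H) - 1) / (S - 1) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(tree)) {
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    observed <- rownames(counts)[rowSums(counts > 0) > 0]
    missing <- setdiff(observed, tree$tip.label)
    if (length(missing))
      stop_n2onet(paste0("tree lacks observed taxa: ",
                         paste(missing, collapse = ", ")),
                  "n2onet_taxon_mismatch_error")
    comm <- t(counts)
    pdres <- picante::pd(comm, tree, include.root = TRUE)
    out$pd <- pdres$PD[match(out$sample_id, rownames(pdres))]
  }
  out
}

#' N2O emission rate from an incubation time series
#'
#' Converts each headspace concentration to a total slurry concentration
#' with the Bunsen solubility coefficient,
#' total = conc * (v_gas + beta * v_liquid) / v_liquid, and returns the
#' ordinary-least-squares slope of total concentration against time.
#'
#' @param time incubation times (hours).
#' @param conc headspace N2O concentrations at those times.
#' @param beta Bunsen solubility coefficient at the equilibration
#'   temperature (dimensionless; site-specific, so never defaulted).
#' @param v_gas,v_liquid headspace and liquid volumes (same units).
#' @return List with `rate` (slope, concentration units per hour),
#'   `intercept`, `r_squared` and `total` (the converted series).
#' @export
n2o_rate <- function(time, conc, beta, v_gas, v_liquid) {
  if (length(time) != length(conc) || length(time) < 2)
    stop_n2onet("need >= 2 paired time points", "n2onet_input_error")
  if (beta <= 0) stop_n2onet("beta must be positive", "n2onet_parameter_error")
  if (length(unique(time)) < 2)
    stop_n2onet("all timestamps identical: slope is singular",
                "n2onet_singular_fit_error")
  total <- conc * (v_gas + beta * v_liquid) / v_liquid
  fit <- lm(total ~ time)
  list(rate = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, total = total)
}

#' Levins niche breadth within a treatment
#'
#' For taxon i over the samples of one treatment, with q_ij the share of
#' the taxon's group total found in sample j, B_i = 1 / sum_j q_ij^2
#' (1 = specialist confined to one sample, n = uniform generalist). The
#' community value is the unweighted mean over taxa with a non-zero group
#' total; absent taxa are excluded and counted.
#'
#' @param table a [count_table].
#' @param group treatment label (must have >= 2 samples).
#' @return List with `levins_B` (named per-taxon vector), `community_mean`,
#'   `n_samples`, `n_excluded`.
#' @export
levins_breadth <- function(table, group) {
  stopifnot(inherits(table, "count_table"))
  ids <- table$metadata$sample_id[table$metadata$treatment == group]
  if (length(ids) < 2)
    stop_n2onet("group needs at least 2 samples", "n2onet_input_error")
  sub <- table$counts[, ids, drop = FALSE]
  tot <- rowSums(sub)
  present <- tot > 0
  q <- sweep(sub[present, , drop = FALSE], 1, tot[present], "/")
  B <- 1 / rowSums(q^2)
  list(levins_B = B, community_mean = mean(B), n_samples = length(ids),
       n_excluded = sum(!present))
}

#' Analysis of similarities (ANOSIM)
#'
#' R = (mean between-group rank - mean within-group rank) / (M / 2) on the
#' mid-ranked dissimilarities (M = n(n-1)/2), with a seeded label
#' permutation p-value p = (1 + #\{R_perm >= R_obs\}) / (1 + n_perm).
#'
#' @param d dissimilarity: a `dist` object or symmetric matrix with zero
#'   diagonal.
#' @param groups group label per sample; every group needs >= 2 samples.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return List with `R`, `p`, `n_perm`, `perm_R`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1L) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- as.character(groups)
  if (length(groups) != n)
    stop_n2onet("groups must match the dissimilarity dimension",
                "n2onet_input_error")
  if (any(table(groups) < 2) || length(unique(groups)) < 2)
    stop_n2onet("need >= 2 groups with >= 2 samples each", "n2onet_grouping_error")
  up <- upper.tri(m)
  rk <- rank(m[up])  # mid-ranks
  pair_i <- row(m)[up]; pair_j <- col(m)[up]
  denom <- length(rk) / 2
  stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  r_obs <- stat(groups)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(b) stat(sample(groups)), numeric(1))
  list(R = r_obs, p = (1 + sum(perm >= r_obs)) / (1 + n_perm),
       n_perm = n_perm, perm_R = perm)
}

#' Bray-Curtis dissimilarity of TMM-scaled abundances
#'
#' Convenience wrapper: [vegan::vegdist] Bray-Curtis on the transposed
#' `norm_abund` matrix of a `normalized_table`.
#'
#' @param norm a `normalized_table`.
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(norm) {
  stopifnot(inherits(norm, "normalized_table"))
  vegan::vegdist(t(norm$norm_abund), method = "bray")
}

#' One-way ANOVA with Fisher's LSD letters
#'
#' Omnibus one-way ANOVA, then all pairwise Fisher LSD tests using the
#' pooled mean squared error and its degrees of freedom, and a compact
#' letter display in which two groups share a letter iff their pairwise
#' p >= `alpha`.
#'
#' @param values numeric response per sample.
#' @param groups group label per sample (>= 2 groups, each >= 2 values).
#' @param alpha significance level for the letter display.
#' @return List with `F`, `p`, `df`, `mse`, `pairwise` (symmetric p
#'   matrix), `letters` (named per group, ordered by decreasing mean),
#'   `means`, `degenerate` flag.
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop_n2onet("need >= 2 groups with >= 2 values each", "n2onet_grouping_error")
  fit <- aov(values ~ groups)
  an <- anova(fit)
  mse <- an[["Mean Sq"]][2]
  dfe <- an[["Df"]][2]
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  lv <- levels(groups)
  k <- length(lv)
  pmat <- matrix(1, k, k, dimnames = list(lv, lv))
  degenerate <- mse == 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (degenerate) {
      pij <- if (isTRUE(all.equal(means[i], means[j]))) 1 else 0
    } else {
      tij <- (means[i] - means[j]) / sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      pij <- 2 * pt(-abs(tij), dfe)
    }
    pmat[i, j] <- pmat[j, i] <- pij
  }
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1], df = c(an[["Df"]]),
       mse = mse, pairwise = pmat,
       letters = lsd_letters(pmat, means, alpha),
       means = means, degenerate = degenerate)
}

# Compact letter display: letters = maximal cliques of the
# "not significantly different" graph, ordered by best group mean.
lsd_letters <- function(pmat, means, alpha = 0.05) {
  lv <- rownames(pmat)
  adj <- pmat >= alpha
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  cliques <- cliques[order(vapply(cliques, function(cl)
    -max(means[lv[as.integer(cl)]]), numeric(1)))]
  letters_out <- setNames(rep("", length(lv)), lv)
  for (ci in seq_along(cliques)) {
    memb <- lv[as.integer(cliques[[ci]])]
    letters_out[memb] <- paste0(letters_out[memb], letters[ci])
  }
  letters_out[order(-means)]
}

#' Module abundance vs N2O regressions
#'
#' Per module: abundance = per-sample mean z-score over the module's taxa;
#' ordinary least squares of the N2O rate on that abundance. Modules with
#' (numerically) zero abundance variance are flagged and get no p-value.
#'
#' @param z z-scored abundance matrix from [zscore_rows()].
#' @param part a `module_partition`.
#' @param n2o data.frame `sample_id`, `rate` aligned to the columns of `z`.
#' @return data.frame per module: `module`, `n_taxa`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, `degenerate`.
#' @export
module_abundance_regression <- function(z, part, n2o) {
  stopifnot(inherits(part, "module_partition"))
  rate <- n2o$rate[match(colnames(z), n2o$sample_id)]
  if (anyNA(rate))
    stop_n2onet(paste0("samples without N2O rate: ",
                       paste(colnames(z)[is.na(rate)], collapse = ", ")),
                "n2onet_consistency_error")
  mods <- sort(unique(part$assignment))
  res <- lapply(mods, function(m) {
    taxa <- intersect(names(part$assignment)[part$assignment == m],
                      rownames(z))
    ab <- colMeans(z[taxa, , drop = FALSE])
    if (sd(ab) < 1e-12)
      return(data.frame(module = m, n_taxa = length(taxa), slope = NA_real_,
                        intercept = NA_real_, r_squared = NA_real_,
                        p_value = NA_real_, n = length(ab), degenerate = TRUE))
    fit <- lm(rate ~ ab)
    sm <- summary(fit)
    data.frame(module = m, n_taxa = length(taxa),
               slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4], n = length(ab),
               degenerate = FALSE)
  })
  do.call(rbind, res)
}

#' Pearson screening of per-sample features against N2O
#'
#' Pearson r and its two-sided t-test p-value per feature column, with the
#' usual star coding (* p < 0.05, ** p < 0.01, *** p < 0.001).
#' Zero-variance features are flagged and excluded from testing.
#'
#' @param features data.frame / matrix of per-sample metrics (rows =
#'   samples, aligned with `n2o`).
#' @param n2o data.frame `sample_id`, `rate`; rows of `features` are
#'   matched by rowname when present, else by position.
#' @return data.frame: `feature`, `r`, `p`, `stars`, `excluded`.
#' @export
pearson_screen <- function(features, n2o) {
  features <- as.data.frame(features)
  if (!is.null(rownames(features)) &&
      all(rownames(features) %in% n2o$sample_id)) {
    rate <- n2o$rate[match(rownames(features), n2o$sample_id)]
  } else {
    if (nrow(features) != nrow(n2o))
      stop_n2onet("features and n2o have different numbers of samples",
                  "n2onet_consistency_error")
    rate <- n2o$rate
  }
  if (length(rate) < 3)
    stop_n2onet("need >= 3 aligned samples", "n2onet_insufficient_data_error")
  res <- lapply(names(features), function(f) {
    x <- features[[f]]
    if (!is.numeric(x) || sd(x, na.rm = TRUE) == 0 || anyNA(x) ||
        any(!is.finite(x)))
      return(data.frame(feature = f, r = NA_real_, p = NA_real_,
                        stars = "", excluded = TRUE))
    ct <- cor.test(x, rate, method = "pearson")
    data.frame(feature = f, r = unname(ct$estimate), p = ct$p.value,
               stars = stars_for(ct$p.value), excluded = FALSE)
  })
  do.call(rbind, res)
}

stars_for <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
}
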