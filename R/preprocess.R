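#' Filter low-abundance genera
#'
#' Retains taxa whose mean relative abundance (mean over samples of
#' count / library size) is at least `min_rel_abund` AND which are present
#' (count > 0) in at least `min_prevalence` samples. Samples are never
#' dropped. Defaults remove singleton noise while keeping Spearman
#' p-values computable at small n.
#'
#' @param table a [count_table].
#' @param min_rel_abund minimum mean relative abundance in [0, 1).
#' @param min_prevalence minimum number of samples with a non-zero count.
#' @return A filtered [count_table] with attributes `n_removed_abundance`
#'   and `n_removed_prevalence` recording each filter's casualties.
#' @export
filter_low_abundance <- function(table, min_rel_abund = 1e-4,
                                 min_prevalence = 2) {
  stopifnot(inherits(table, "count_table"))
  if (min_rel_abund < 0 || min_rel_abund >= 1)
    stop_n2onet("min_rel_abund must be in [0, 1)", "n2onet_parameter_error")
  if (min_prevalence < 0 || min_prevalence > ncol(table$counts))
    stop_n2onet("min_prevalence must be in [0, n_samples]", "n2onet_parameter_error")
  rel <- sweep(table$counts, 2, colSums(table$counts), "/")
  keep_ab <- rowMeans(rel) >= min_rel_abund
  keep_prev <- rowSums(table$counts > 0) >= min_prevalence
  keep <- keep_ab & keep_prev
  if (!any(keep))
    stop_n2onet(sprintf(
      "all taxa removed (%d failed abundance, %d failed prevalence)",
      sum(!keep_ab), sum(!keep_prev)), "n2onet_empty_result_error")
  out <- count_table(table$counts[keep, , drop = FALSE],
                     kingdom = table$kingdom[keep], metadata = table$metadata)
  attr(out, "n_removed_abundance") <- sum(!keep_ab)
  attr(out, "n_removed_prevalence") <- sum(!keep_prev)
  out
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors (Robinson & Oshlack 2010), as
#' implemented in edgeR: the reference library is the one whose upper
#' quartile of count fractions is closest to the mean of that quantity
#' (ties broken by lowest sample index); each sample's factor is
#' 2^(precision-weighted mean of gene-wise log2 fold changes M after
#' trimming `logratio_trim` from each M tail and `abs_trim` from each
#' A tail), over taxa non-zero in both sample and reference; factors are
#' rescaled to geometric mean 1.
#'
#' @param table a [count_table] (or bare count matrix).
#' @param logratio_trim,abs_trim trim fractions for the M and A tails.
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(table, logratio_trim = 0.30, abs_trim = 0.05) {
  counts <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  libs <- colSums(counts)
  if (any(libs <= 0))
    stop_n2onet("every sample needs a positive library size", "n2onet_input_error")
  fracs <- sweep(counts, 2, libs, "/")
  ref <- which.min(abs(apply(fracs, 2, quantile, p = 0.75) -
                         mean(apply(fracs, 2, quantile, p = 0.75))))
  shared <- colSums(counts > 0 & counts[, ref] > 0)
  if (any(shared == 0))
    stop_n2onet(paste0("sample(s) share no non-zero taxa with the reference: ",
                       paste(colnames(counts)[shared == 0], collapse = ", ")),
                "n2onet_degenerate_overlap_error")
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref,
                              logratioTrim = logratio_trim,
                              sumTrim = abs_trim, doWeighting = TRUE)
  names(f) <- colnames(counts)
  f
}

#' TMM-normalized abundance matrices
#'
#' Couples [tmm_factors()] with the count table: effective library size =
#' library size x factor; `norm_abund` = counts / effective library size
#' (the matrix co-occurrence correlation is computed on); `rel_abund` =
#' per-sample proportions summing to 1 (used as cohesion weights and for
#' diversity).
#'
#' @inheritParams tmm_factors
#' @return Object of class `normalized_table`: list with `rel_abund`,
#'   `norm_abund`, `tmm_factor`, `effective_libsize`, plus the originating
#'   `counts`, `kingdom` and `metadata`.
#' @export
normalize_counts <- function(table, logratio_trim = 0.30, abs_trim = 0.05) {
  stopifnot(inherits(table, "count_table"))
  f <- tmm_factors(table, logratio_trim, abs_trim)
  libs <- colSums(table$counts)
  eff <- libs * f
  norm <- sweep(table$counts, 2, eff, "/")
  rel <- sweep(table$counts, 2, libs, "/")
  structure(list(rel_abund = rel, norm_abund = norm, tmm_factor = f,
                 effective_libsize = eff, counts = table$counts,
                 kingdom = table$kingdom, metadata = table$metadata),
            class = "normalized_table")
}

#' Row-wise z-score standardization
#'
#' Centers and scales each row to mean 0 and sample standard deviation 1.
#' Zero-variance rows become all zeros (flagged in the `"flagged"`
#' attribute) rather than aborting the pipeline: they contribute nothing
#' to module means.
#'
#' @param m numeric matrix (taxa x samples).
#' @return Matrix of the same shape; attribute `flagged` holds the names
#'   (or indices) of zero-variance rows.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L)
    stop_n2onet("z-scores need at least 2 samples", "n2onet_insufficient_data_error")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  flagged <- s == 0
  s[flagged] <- 1
  z <- (m - mu) / s
  z[flagged, ] <- 0
  if (any(flagged))
    warning(sprintf("%d zero-variance row(s) z-scored to 0", sum(flagged)))
  attr(z, "flagged") <- rownames(m)[flagged] %||% which(flagged)
  z
}
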