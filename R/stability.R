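#' Network robustness under random node removal
#'
#' For each removal fraction f and repetition, `floor(f * V)` nodes are
#' deleted uniformly at random and robustness is measured as the
#' proportion of remaining nodes that keep at least one surviving edge.
#' This "non-isolated survivor" statistic is the standard co-occurrence
#' toolkit definition; the whole curve is seeded and reproducible.
#'
#' @param net network graph with at least 2 nodes.
#' @param fractions removal fractions, each in (0, 1).
#' @param reps repetitions per fraction.
#' @param seed RNG seed.
#' @param summary_at fraction whose values feed single-number comparisons.
#' @return List of class `robustness_curve`: `fractions`, `reps`, `values`
#'   (fractions x reps matrix), `mean`, `sd`, `summary_at`, `seed`.
#' @export
robustness_curve <- function(net, fractions = seq(0.1, 0.9, by = 0.1),
                             reps = 100, seed = 1L, summary_at = 0.5) {
  if (igraph::vcount(net) < 2)
    stop_n2onet("robustness needs at least 2 nodes", "n2onet_input_error")
  if (any(fractions <= 0 | fractions >= 1))
    stop_n2onet("removal fractions must lie in (0, 1)", "n2onet_parameter_error")
  v <- igraph::vcount(net)
  set.seed(as.integer(seed))
  values <- matrix(NA_real_, length(fractions), reps,
                   dimnames = list(paste0("f", fractions), NULL))
  for (i in seq_along(fractions)) {
    k <- floor(fractions[i] * v)
    for (r in seq_len(reps)) {
      drop <- sample.int(v, k)
      g <- igraph::delete_vertices(net, drop)
      values[i, r] <- sum(igraph::degree(g) >= 1) / igraph::vcount(g)
    }
  }
  structure(list(fractions = fractions, reps = reps, values = values,
                 mean = rowMeans(values), sd = apply(values, 1, sd),
                 summary_at = summary_at, seed = as.integer(seed)),
            class = "robustness_curve")
}

#' Compare robustness between two networks
#'
#' Welch two-sided t-test on the repetition values of two robustness
#' curves at a common removal fraction.
#'
#' @param a,b `robustness_curve` objects containing fraction `at`.
#' @param at removal fraction at which to compare (defaults to the curves'
#'   `summary_at`).
#' @return List with `t`, `df`, `p`, group means, and `degenerate`
#'   (`TRUE` when both rep vectors had zero variance).
#' @export
compare_robustness <- function(a, b, at = NULL) {
  at <- at %||% a$summary_at
  ia <- match(at, a$fractions); ib <- match(at, b$fractions)
  if (is.na(ia) || is.na(ib))
    stop_n2onet("both curves must contain the comparison fraction",
                "n2onet_parameter_error")
  va <- a$values[ia, ]; vb <- b$values[ib, ]
  if (length(va) < 2 || length(vb) < 2)
    stop_n2onet("need at least 2 repetitions per curve", "n2onet_input_error")
  if (sd(va) == 0 && sd(vb) == 0) {
    equal <- isTRUE(all.equal(mean(va), mean(vb)))
    return(list(t = if (equal) 0 else Inf * sign(mean(va) - mean(vb)),
                df = NA_real_, p = if (equal) 1 else 0,
                mean_a = mean(va), mean_b = mean(vb), degenerate = TRUE))
  }
  tt <- t.test(va, vb, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(va), mean_b = mean(vb),
       degenerate = FALSE)
}

#' Per-sample positive and negative cohesion
#'
#' Connectedness of taxon i is the mean of the positive (respectively
#' negative) off-diagonal correlations in its row of the correlation
#' matrix (0 when there are none). Sample j's positive cohesion is the
#' relative-abundance-weighted sum sum_i p_ij * connectedness_pos_i, and
#' likewise for the negative component, so cohesion_pos >= 0 >=
#' cohesion_neg always. With `null_iters > 0`, connectedness is corrected
#' to observed minus the mean over taxa-shuffle null iterations (each row
#' of the abundance matrix permuted independently across samples, the
#' Spearman matrix recomputed); corrected positive (negative)
#' connectedness is floored (capped) at 0 so the sign constraints still
#' hold.
#'
#' @param norm a `normalized_table` from [normalize_counts()].
#' @param corr matching `correlation_result` from [spearman_matrix()].
#' @param null_iters number of null iterations (0 = uncorrected).
#' @param seed RNG seed for the null model.
#' @return List of class `cohesion_result`: `pos_cohesion`, `neg_cohesion`
#'   (per sample), `connectedness_pos`, `connectedness_neg` (per taxon),
#'   `null_iters`, `seed`.
#' @export
cohesion <- function(norm, corr, null_iters = 0, seed = 1L) {
  stopifnot(inherits(norm, "normalized_table"),
            inherits(corr, "correlation_result"))
  taxa <- rownames(norm$rel_abund)
  if (!identical(taxa, rownames(corr$rho)))
    stop_n2onet("taxa differ between abundance table and correlation matrix",
                "n2onet_consistency_error")
  conn <- connectedness_from_rho(corr$rho)
  if (null_iters > 0) {
    set.seed(as.integer(seed))
    acc_pos <- acc_neg <- matrix(0, length(taxa), null_iters)
    for (b in seq_len(null_iters)) {
      shuf <- t(apply(norm$norm_abund, 1, sample))
      rho_null <- suppressWarnings(cor(t(shuf), method = "spearman"))
      rho_null[is.na(rho_null)] <- 0
      cn <- connectedness_from_rho(rho_null)
      acc_pos[, b] <- cn$pos
      acc_neg[, b] <- cn$neg
    }
    conn$pos <- pmax(conn$pos - rowMeans(acc_pos), 0)
    conn$neg <- pmin(conn$neg - rowMeans(acc_neg), 0)
  }
  structure(list(
    pos_cohesion = setNames(as.numeric(crossprod(norm$rel_abund, conn$pos)),
                            colnames(norm$rel_abund)),
    neg_cohesion = setNames(as.numeric(crossprod(norm$rel_abund, conn$neg)),
                            colnames(norm$rel_abund)),
    connectedness_pos = setNames(conn$pos, taxa),
    connectedness_neg = setNames(conn$neg, taxa),
    samples = colnames(norm$rel_abund),
    null_iters = null_iters, seed = as.integer(seed)),
    class = "cohesion_result")
}

connectedness_from_rho <- function(rho) {
  diag(rho) <- NA
  pos <- apply(rho, 1, function(r) {
    r <- r[!is.na(r) & r > 0]; if (length(r)) mean(r) else 0
  })
  neg <- apply(rho, 1, function(r) {
    r <- r[!is.na(r) & r < 0]; if (length(r)) mean(r) else 0
  })
  list(pos = pos, neg = neg)
}
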