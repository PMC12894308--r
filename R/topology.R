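#' Topological summary of a co-occurrence network
#'
#' The per-network metric vector reported for the global network and every
#' treatment / sample subnetwork: edge counts by sign, number of vertices
#' (nodes with degree >= 1 — isolated taxa carry no interaction
#' information), average degree 2E/V, mean local clustering coefficient
#' (averaged over nodes of degree >= 2 only, so sparse subnetworks are not
#' distorted by 0-imputation), Freeman betweenness centralization
#' sum_i(B_max - B_i) / ((V - 1) * (V - 1) * (V - 2) / 2) on unweighted
#' shortest paths over the non-isolated node set, and the
#' positive/negative edge ratio (`Inf` when there are positive but no
#' negative edges, `NA` when edgeless).
#'
#' @param net network graph from [threshold_network()] (any undirected
#'   igraph works; edge signs default to "+" when absent).
#' @param count_isolated if `TRUE`, `n_vertices` counts all nodes instead
#'   of only connected ones.
#' @return One-row data.frame with columns `n_edges`, `n_pos_edges`,
#'   `n_neg_edges`, `n_vertices`, `avg_degree`, `mean_clustering`,
#'   `centralization_betweenness`, `pos_neg_ratio`.
#' @export
topology_summary <- function(net, count_isolated = FALSE) {
  ne <- igraph::ecount(net)
  signs <- if (ne && "sign" %in% igraph::edge_attr_names(net))
    igraph::E(net)$sign else rep("+", ne)
  n_pos <- sum(signs == "+")
  n_neg <- ne - n_pos
  deg <- igraph::degree(net)
  core <- igraph::induced_subgraph(net, which(deg >= 1))
  nv <- if (count_isolated) igraph::vcount(net) else igraph::vcount(core)
  avg_deg <- if (nv > 0) 2 * ne / nv else 0

  cl <- 0
  if (igraph::vcount(core)) {
    loc <- igraph::transitivity(core, type = "local", isolates = "NaN")
    eligible <- igraph::degree(core) >= 2
    if (any(eligible)) cl <- mean(loc[eligible])
  }

  cb <- 0
  v <- igraph::vcount(core)
  if (v >= 3) {
    btw <- igraph::betweenness(core, directed = FALSE, weights = NA)
    cb <- sum(max(btw) - btw) / ((v - 1) * (v - 1) * (v - 2) / 2)
  }

  ratio <- if (ne == 0) NA_real_ else if (n_neg == 0) Inf else n_pos / n_neg
  data.frame(n_edges = as.integer(ne), n_pos_edges = as.integer(n_pos),
             n_neg_edges = as.integer(n_neg), n_vertices = as.integer(nv),
             avg_degree = avg_deg, mean_clustering = cl,
             centralization_betweenness = cb, pos_neg_ratio = ratio)
}

#' Module (ecological cluster) detection
#'
#' Seeded Louvain maximization of Newman-Girvan modularity on the unsigned,
#' unweighted network skeleton. Modules are relabeled by descending size
#' (ties by first member); singleton components end up as their own
#' modules.
#'
#' @param net network graph with at least one edge.
#' @param seed RNG seed recorded alongside the partition.
#' @return List of class `module_partition`: `assignment` (named integer,
#'   node -> module), `modularity_Q`, `algorithm`, `seed`.
#' @export
detect_modules <- function(net, seed = 1L) {
  if (igraph::ecount(net) == 0)
    stop_n2onet("cannot partition an edgeless network", "n2onet_no_partition_error")
  skel <- net
  if ("weight" %in% igraph::edge_attr_names(skel))
    skel <- igraph::delete_edge_attr(skel, "weight")
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(skel)
  mem <- igraph::membership(comm)
  sizes <- table(mem)
  new_id <- setNames(rank(-as.numeric(sizes), ties.method = "first"),
                     names(sizes))
  assignment <- setNames(as.integer(new_id[as.character(mem)]),
                         igraph::V(net)$name)
  q <- igraph::modularity(skel, mem)
  structure(list(assignment = assignment, modularity_Q = q,
                 algorithm = "louvain", seed = as.integer(seed)),
            class = "module_partition")
}

#' Within-module degree z-score (Zi) and keystone calls
#'
#' For node i in module s, kappa_i counts i's edges to other members of s;
#' Zi = (kappa_i - mean_s kappa) / sd_s kappa with the population standard
#' deviation. Modules whose members all have identical within-module
#' degree (sd = 0) get Zi = 0. Nodes at or above `zi_threshold` (2.5, the
#' canonical within-module hub cutoff) are flagged as keystones.
#'
#' @param net network graph.
#' @param part a `module_partition` covering every node of `net`.
#' @param zi_threshold keystone cutoff on Zi.
#' @return data.frame with `node`, `module`, `kappa`, `zi`, `keystone`;
#'   attribute `zi_threshold`.
#' @export
within_module_degree_z <- function(net, part, zi_threshold = 2.5) {
  stopifnot(inherits(part, "module_partition"))
  nodes <- igraph::V(net)$name
  missing <- setdiff(nodes, names(part$assignment))
  if (length(missing))
    stop_n2onet(paste0("nodes missing from partition: ",
                       paste(missing, collapse = ", ")),
                "n2onet_consistency_error")
  mod <- part$assignment[nodes]
  kappa <- setNames(numeric(length(nodes)), nodes)
  if (igraph::ecount(net)) {
    el <- igraph::as_edgelist(net)
    same <- mod[el[, 1]] == mod[el[, 2]]
    if (any(same)) {
      tab <- table(c(el[same, 1], el[same, 2]))
      kappa[names(tab)] <- as.numeric(tab)
    }
  }
  zi <- numeric(length(nodes))
  for (s in unique(mod)) {
    idx <- mod == s
    k <- kappa[idx]
    sdp <- sqrt(mean((k - mean(k))^2))
    zi[idx] <- if (sdp > 0) (k - mean(k)) / sdp else 0
  }
  out <- data.frame(node = nodes, module = as.integer(mod),
                    kappa = as.numeric(kappa), zi = zi,
                    keystone = zi >= zi_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "zi_threshold") <- zi_threshold
  out
}
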