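# Independent oracles used to validate the implementation. Everything here
# is deliberately naive (enumeration, double loops, BFS path counting) and
# shares no code with the package internals.

# ---- permutations / exact Spearman p ----------------------------------------

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

# Exact two-sided permutation p for Spearman rho: share of rank
# permutations with |rho| at least the observed value.
spearman_exact <- function(x, y) {
  n <- length(x)
  rho_obs <- cor(x, y, method = "spearman")
  rhos <- vapply(all_perms(seq_len(n)),
                 function(p) cor(seq_len(n), p, method = "spearman"),
                 numeric(1))
  list(rho = rho_obs, p = mean(abs(rhos) >= abs(rho_obs) - 1e-9))
}

# ---- graph metric oracles (adjacency-matrix based) --------------------------

# Brandes-style betweenness by BFS path counting, undirected unweighted.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  if (n < 3) return(bc)
  for (s in seq_len(n)) {
    order_visited <- integer(0)
    preds <- vector("list", n)
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in which(adj[v, ] > 0)) {
        if (dist[w] < 0) { queue <- c(queue, w); dist[w] <- dist[v] + 1 }
        if (dist[w] == dist[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2
}

# Local clustering 2T/(k(k-1)) by triangle enumeration.
oracle_local_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(NA_real_)
    tri <- sum(adj[nb, nb, drop = FALSE]) / 2
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# Full topology summary from an adjacency matrix and per-edge signs
# (sign_mat entries +1/-1 on edges).
oracle_topology <- function(adj, sign_mat) {
  deg <- rowSums(adj)
  core <- which(deg >= 1)
  a <- adj[core, core, drop = FALSE]
  ne <- sum(adj) / 2
  npos <- sum(sign_mat[upper.tri(sign_mat)] > 0 & adj[upper.tri(adj)] > 0)
  nneg <- ne - npos
  v <- length(core)
  cl <- 0
  if (v) {
    loc <- oracle_local_clustering(a)
    if (any(!is.na(loc))) cl <- mean(loc, na.rm = TRUE)
    if (all(is.na(loc))) cl <- 0
  }
  cb <- 0
  if (v >= 3) {
    btw <- oracle_betweenness(a)
    cb <- sum(max(btw) - btw) / ((v - 1) * (v - 1) * (v - 2) / 2)
  }
  list(n_edges = ne, n_pos_edges = npos, n_neg_edges = nneg,
       n_vertices = v, avg_degree = if (v) 2 * ne / v else 0,
       mean_clustering = cl, centralization_betweenness = cb,
       pos_neg_ratio = if (ne == 0) NA_real_
                       else if (nneg == 0) Inf else npos / nneg)
}

# Random signed graph for metric comparisons.
random_signed_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  sgn <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) {
      adj[i, j] <- adj[j, i] <- 1
      s <- if (runif(1) < 0.7) 1 else -1
      sgn[i, j] <- sgn[j, i] <- s
    }
  }
  rownames(adj) <- colnames(adj) <- paste0("t", seq_len(n))
  list(adj = adj, sign = sgn)
}

graph_from_adj_signed <- function(adj, sgn) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (igraph::ecount(g)) {
    el <- igraph::as_edgelist(g, names = FALSE)
    s <- sgn[cbind(el[, 1], el[, 2])]
    igraph::E(g)$sign <- ifelse(s > 0, "+", "-")
    igraph::E(g)$rho <- s * 0.9
    igraph::E(g)$weight <- 0.9
  }
  g
}

# ---- TMM step-by-step oracle ------------------------------------------------

# Doubly trimmed, precision-weighted mean of M-values between one sample
# and the reference, written directly from the published formula.
oracle_tmm_pair <- function(obs, ref, logratio_trim = 0.30, abs_trim = 0.05) {
  n_o <- sum(obs); n_r <- sum(ref)
  keep0 <- obs > 0 & ref > 0
  o <- obs[keep0]; r <- ref[keep0]
  M <- log2((o / n_o) / (r / n_r))
  A <- (log2(o / n_o) + log2(r / n_r)) / 2
  v <- (n_o - o) / (n_o * o) + (n_r - r) / (n_r * r)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

oracle_tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  fracs <- sweep(counts, 2, colSums(counts), "/")
  q75 <- apply(fracs, 2, quantile, p = 0.75)
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(counts)), function(j)
    if (j == ref) 1 else oracle_tmm_pair(counts[, j], counts[, ref],
                                         logratio_trim, abs_trim),
    numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# ---- cohesion double-loop oracle --------------------------------------------

oracle_cohesion <- function(rel, rho) {
  nt <- nrow(rel); ns <- ncol(rel)
  cp <- numeric(ns); cn <- numeric(ns)
  for (j in seq_len(ns)) {
    for (i in seq_len(nt)) {
      pos <- c(); neg <- c()
      for (k in seq_len(nt)) {
        if (k == i) next
        if (rho[i, k] > 0) pos <- c(pos, rho[i, k])
        if (rho[i, k] < 0) neg <- c(neg, rho[i, k])
      }
      cpi <- if (length(pos)) mean(pos) else 0
      cni <- if (length(neg)) mean(neg) else 0
      cp[j] <- cp[j] + rel[i, j] * cpi
      cn[j] <- cn[j] + rel[i, j] * cni
    }
  }
  list(pos = cp, neg = cn)
}

# ---- adjusted Rand index ----------------------------------------------------

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)
  (sij - expected) / (maxidx - expected)
}
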