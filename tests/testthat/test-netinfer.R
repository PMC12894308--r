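test_that("Spearman matrix handles monotone, tied and constant rows", {
  m <- rbind(a = c(1, 2, 3, 4, 5),
             b = c(2, 4, 6, 8, 10),
             c = c(5, 4, 3, 2, 1),
             d = c(1, 3, 2, 5, 4),
             e = c(7, 7, 7, 7, 7))
  colnames(m) <- paste0("s", 1:5)
  cr <- spearman_matrix(m)
  expect_equal(cr$rho["a", "b"], 1)
  expect_equal(cr$pval["a", "b"], 0)
  expect_equal(cr$rho["a", "c"], -1)
  expect_equal(cr$pval["a", "c"], 0)
  expect_equal(cr$rho["a", "d"], 0.8)
  expect_equal(cr$flagged, "e")
  expect_equal(unname(cr$rho["e", "a"]), 0)
  expect_equal(unname(cr$pval["e", "a"]), 1)
  expect_equal(cr$rho, t(cr$rho))
  expect_equal(diag(cr$pval), rep(0, 5), ignore_attr = TRUE)
  expect_error(spearman_matrix(m[, 1:3]),
               class = "n2onet_insufficient_data_error")
})

test_that("t-approximation p agrees with exhaustive permutation enumeration", {
  # rho must equal the enumerated value exactly; the two-sided t p-value
  # deviates from the exact permutation p by < 0.09 for n >= 5
  # (< 0.16 at n = 4), the documented bound.
  fixtures <- list(
    list(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3)),
    list(x = c(1, 2, 3, 4, 5), y = c(1, 3, 2, 5, 4)),
    list(x = c(1, 2, 3, 4, 5, 6), y = c(2, 1, 4, 3, 6, 5)),
    list(x = c(1, 2, 3, 4, 5, 6, 7), y = c(3, 1, 2, 5, 4, 7, 6)),
    list(x = c(1, 2, 3, 4, 5, 6, 7), y = c(7, 5, 6, 1, 3, 2, 4)))
  for (fx in fixtures) {
    n <- length(fx$x)
    ex <- spearman_exact(fx$x, fx$y)
    m <- rbind(x = fx$x, y = fx$y)
    colnames(m) <- paste0("s", seq_len(n))
    cr <- spearman_matrix(m)
    expect_equal(cr$rho["x", "y"], ex$rho, tolerance = 1e-12)
    bound <- if (n >= 5) 0.09 else 0.16
    expect_lt(abs(cr$pval["x", "y"] - ex$p), bound)
  }
  # the n = 5, rho = 0.8 case of record
  ex <- spearman_exact(1:5, c(1, 3, 2, 5, 4))
  expect_equal(ex$rho, 0.8)
  expect_equal(ex$p, mean(abs(sapply(all_perms(1:5), function(p)
    cor(1:5, p, method = "spearman"))) >= 0.8 - 1e-9))
})

test_that("edge calling applies both thresholds with signs", {
  rho <- diag(6)
  rownames(rho) <- colnames(rho) <- paste0("g", 1:6)
  pv <- matrix(0.5, 6, 6, dimnames = dimnames(rho)); diag(pv) <- 0
  set_pair <- function(i, j, r, p) {
    rho[i, j] <<- rho[j, i] <<- r
    pv[i, j] <<- pv[j, i] <<- p
  }
  set_pair(1, 2, 0.71, 0.01)    # in
  set_pair(1, 3, 0.69, 0.001)   # fails rho
  set_pair(2, 3, -0.85, 0.02)   # in, negative
  set_pair(4, 5, 0.95, 0.06)    # fails p
  set_pair(5, 6, 0.75, 0.04)    # in
  cr <- structure(list(rho = rho, pval = pv, n = 9, flagged = character(0)),
                  class = "correlation_result")
  net <- threshold_network(cr, rho_min = 0.7, p_max = 0.05)

  # brute-force double loop over the matrix
  want <- c()
  for (i in 1:5) for (j in (i + 1):6)
    if (abs(rho[i, j]) > 0.7 && pv[i, j] < 0.05)
      want <- c(want, paste0("g", i, "|g", j))
  got <- apply(igraph::as_edgelist(net), 1, paste, collapse = "|")
  expect_setequal(got, want)
  expect_equal(igraph::vcount(net), 6)  # isolated nodes retained
  eattr <- igraph::as_data_frame(net, what = "edges")
  expect_equal(eattr$sign[eattr$from == "g2" & eattr$to == "g3"], "-")
  expect_equal(igraph::graph_attr(net, "rho_min"), 0.7)
  expect_error(threshold_network(cr, rho_min = 1.2),
               class = "n2onet_parameter_error")
})

test_that("thresholding is monotone in both thresholds", {
  set.seed(99)
  for (rep in 1:20) {
    k <- 12
    z <- matrix(rnorm(k * 10), k, 10,
                dimnames = list(paste0("g", 1:k), paste0("s", 1:10)))
    cr <- spearman_matrix(z)
    base <- igraph::ecount(threshold_network(cr, 0.5, 0.05))
    expect_lte(igraph::ecount(threshold_network(cr, 0.65, 0.05)), base)
    expect_lte(igraph::ecount(threshold_network(cr, 0.5, 0.01)), base)
  }
})

test_that("subnetworks are induced by presence and nest correctly", {
  counts <- rbind(g1 = c(5, 0, 1, 2), g2 = c(3, 2, 0, 1),
                  g3 = c(0, 1, 4, 2), g4 = c(1, 1, 1, 1))
  colnames(counts) <- paste0("s", 1:4)
  tab <- toy_table(counts, treatments = c("A", "A", "B", "B"))
  rho <- diag(4); rownames(rho) <- colnames(rho) <- rownames(counts)
  pv <- matrix(0, 4, 4, dimnames = dimnames(rho))
  rho[1, 2] <- rho[2, 1] <- 0.9
  rho[3, 4] <- rho[4, 3] <- -0.8
  rho[1, 4] <- rho[4, 1] <- 0.75
  pv[upper.tri(pv)] <- 0.001; pv[lower.tri(pv)] <- 0.001
  cr <- structure(list(rho = rho, pval = pv, n = 4, flagged = character(0)),
                  class = "correlation_result")
  net <- threshold_network(cr)

  # s1 lacks g3: induced subgraph keeps edges g1-g2, g1-g4 only
  s1 <- sample_subnetwork(net, tab, "s1")
  expect_setequal(igraph::V(s1)$name, c("g1", "g2", "g4"))
  expect_setequal(apply(igraph::as_edgelist(s1), 1, paste, collapse = "|"),
                  c("g1|g2", "g1|g4"))
  # s2 lacks g1: only isolated g2, g3, g4 minus edges not fully present
  s2 <- sample_subnetwork(net, tab, "s2")
  expect_setequal(igraph::V(s2)$name, c("g2", "g3", "g4"))
  expect_setequal(apply(igraph::as_edgelist(s2), 1, paste, collapse = "|"),
                  "g3|g4")

  trA <- treatment_subnetwork(net, tab, "A")
  expect_setequal(igraph::V(trA)$name, c("g1", "g2", "g3", "g4"))
  expect_equal(igraph::ecount(trA), igraph::ecount(net))

  # nesting: sample edge sets within treatment within global
  for (s in c("s1", "s2")) {
    es <- apply(igraph::as_edgelist(sample_subnetwork(net, tab, s)), 1,
                paste, collapse = "|")
    et <- apply(igraph::as_edgelist(trA), 1, paste, collapse = "|")
    expect_true(all(es %in% et))
  }
  expect_error(sample_subnetwork(net, tab, "nope"), class = "n2onet_key_error")
  expect_error(treatment_subnetwork(net, tab, "nope"), class = "n2onet_key_error")
})

test_that("background-only communities stay near-edgeless", {
  # module-0 taxa are independent; the false-edge rate at the default
  # thresholds must stay within 5x the nominal p_max
  rate <- vapply(seq_len(30), function(s) {
    cfg <- synthetic_config(n_treatments = 1, reps_per_treatment = 30,
                            n_taxa = 25, n_modules = 1, module_sizes = 0,
                            treatment_shift = matrix(0, 1, 1), n2o_effects = 0,
                            seed = 7000 + s)
    g <- generate_community(cfg)
    rel <- sweep(g$table$counts, 2, colSums(g$table$counts), "/")
    cr <- spearman_matrix(rel)
    igraph::ecount(threshold_network(cr)) / choose(nrow(rel), 2)
  }, numeric(1))
  expect_lte(mean(rate), 5 * 0.05)
})
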