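test_that("alpha diversity has the even-community closed forms", {
  m <- cbind(even = c(25, 25, 25, 25), single = c(10, 0, 0, 0),
             mixed = c(1, 9, 45, 45))
  rownames(m) <- c("A", "B", "C", "D")
  tab <- toy_table(m)
  d <- alpha_diversity(tab)
  even <- d[d$sample_id == "even", ]
  expect_equal(even$shannon, log(4))
  expect_equal(even$pielou, 1)
  expect_equal(even$heip, 1)
  expect_equal(even$simpson, 0.75)
  expect_equal(even$coverage, 1)

  single <- d[d$sample_id == "single", ]
  expect_equal(single$shannon, 0)
  expect_equal(single$simpson, 0)
  expect_equal(single$pielou, 0)
  expect_equal(single$coverage, 1)   # no singleton taxa: 10 reads in one taxon

  mixed <- d[d$sample_id == "mixed", ]
  expect_equal(mixed$coverage, 1 - 1 / 100)  # one taxon with exactly 1 read
})

test_that("Faith PD includes the root path", {
  tree <- "((A:1,B:1):1,(C:1,D:1):1);"
  m <- cbind(s1 = c(5, 3, 0, 0), s2 = c(1, 1, 1, 1))
  rownames(m) <- c("A", "B", "C", "D")
  d <- alpha_diversity(toy_table(m), tree = tree)
  expect_equal(d$pd[d$sample_id == "s1"], 3)  # A:1 + B:1 + stem:1
  expect_equal(d$pd[d$sample_id == "s2"], 6)  # whole tree

  m2 <- rbind(m, E = c(0, 2))
  expect_error(alpha_diversity(toy_table(m2), tree = tree),
               class = "n2onet_taxon_mismatch_error")
})

test_that("N2O rates come from the OLS slope of the converted series", {
  lin <- n2o_rate(time = 0:4, conc = 2 * (0:4), beta = 0.5,
                  v_gas = 0, v_liquid = 1)
  # conversion factor (0 + 0.5*1)/1 = 0.5 halves the slope
  expect_equal(lin$rate, 1)
  expect_equal(n2o_rate(0:4, rep(3, 5), beta = 1, v_gas = 1,
                        v_liquid = 1)$rate, 0)

  t5 <- c(0, 1, 2, 4, 7); c5 <- c(0.2, 1.1, 2.3, 3.9, 7.4)
  beta <- 0.6; vg <- 13.5; vl <- 5
  tot <- c5 * (vg + beta * vl) / vl
  slope <- sum((t5 - mean(t5)) * (tot - mean(tot))) / sum((t5 - mean(t5))^2)
  expect_equal(n2o_rate(t5, c5, beta, vg, vl)$rate, slope, tolerance = 1e-12)

  expect_error(n2o_rate(c(1, 1, 1), c(1, 2, 3), 0.5, 10, 5),
               class = "n2onet_singular_fit_error")
  expect_error(n2o_rate(1, 2, 0.5, 10, 5), class = "n2onet_input_error")
})

test_that("Levins niche breadth hits its closed forms", {
  m <- rbind(uniform = c(10, 10, 10), onesample = c(7, 0, 0),
             skew = c(20, 10, 10))   # q = (0.5, 0.25, 0.25)
  colnames(m) <- paste0("s", 1:3)
  nb <- levins_breadth(toy_table(m), "A")
  expect_equal(unname(nb$levins_B["uniform"]), 3)
  expect_equal(unname(nb$levins_B["onesample"]), 1)
  expect_equal(unname(nb$levins_B["skew"]), 1 / 0.375, tolerance = 1e-9)
  expect_equal(nb$community_mean, mean(c(3, 1, 1 / 0.375)))
  expect_true(all(nb$levins_B >= 1 & nb$levins_B <= 3))

  # rescaling one taxon's counts leaves its breadth unchanged
  m2 <- m; m2["skew", ] <- m["skew", ] * 17
  nb2 <- levins_breadth(toy_table(m2), "A")
  expect_equal(nb2$levins_B["skew"], nb$levins_B["skew"])
})

test_that("ANOSIM reproduces the hand-ranked example and ties give R = 0", {
  # groups {1,2} and {3,4}; within-distances get ranks {1,2}, between {3..6}
  d <- matrix(0, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.2
  d[1, 3] <- d[3, 1] <- 0.5
  d[1, 4] <- d[4, 1] <- 0.6
  d[2, 3] <- d[3, 2] <- 0.7
  d[2, 4] <- d[4, 2] <- 0.8
  res <- anosim_test(d, c("g1", "g1", "g2", "g2"), n_perm = 99, seed = 1)
  expect_equal(res$R, (4.5 - 1.5) / 3)  # = 1

  tied <- matrix(1, 5, 5); diag(tied) <- 0
  res0 <- anosim_test(tied, c("a", "a", "a", "b", "b"), n_perm = 99, seed = 1)
  expect_equal(res0$R, 0)

  expect_error(anosim_test(d, c("g1", "g1", "g2", "g3")),
               class = "n2onet_grouping_error")
})

test_that("ANOSIM agrees with the vegan reference implementation", {
  set.seed(9)
  comm <- matrix(rpois(12 * 20, 20), nrow = 12)
  grp <- rep(c("A", "B", "C"), each = 4)
  d <- vegan::vegdist(comm, method = "bray")
  ours <- anosim_test(d, grp, n_perm = 999, seed = 3)
  ref <- vegan::anosim(d, grouping = grp, permutations = 999)
  expect_equal(ours$R, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.06)  # independent permutation streams
  expect_gte(ours$R, -1); expect_lte(ours$R, 1)
})

test_that("permutation p is reproducible under a fixed seed", {
  set.seed(4)
  comm <- matrix(rpois(10 * 8, 15), nrow = 10)
  d <- vegan::vegdist(comm, "bray")
  grp <- rep(c("x", "y"), each = 5)
  a <- anosim_test(d, grp, n_perm = 499, seed = 77)
  b <- anosim_test(d, grp, n_perm = 499, seed = 77)
  expect_identical(a$p, b$p)
  expect_identical(a$perm_R, b$perm_R)
})

test_that("one-way ANOVA + LSD match direct arithmetic", {
  # (1,2,3) vs (7,8,9): SSB = 54 (df 1), MSE = 1 (df 4) -> F = 54
  res <- anova_lsd(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 54)
  expect_equal(res$p, pf(54, 1, 4, lower.tail = FALSE))
  expect_equal(res$mse, 1)
  # two groups: F is the squared pooled t statistic
  tt <- t.test(c(1, 2, 3), c(7, 8, 9), var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2)
  expect_false(res$letters["a"] == res$letters["b"])

  # identical means with variance: everything shares a letter
  res2 <- anova_lsd(c(1, 3, 2, 1, 3, 2), rep(c("a", "b"), each = 3))
  expect_lt(res2$F, 1e-12)
  expect_equal(unname(res2$letters["a"]), unname(res2$letters["b"]))

  # three-group fixture: pairwise LSD p from the pooled-MSE closed form
  v <- c(5.1, 4.9, 5.3, 7.2, 7.0, 6.8, 5.2, 5.0, 5.4)
  g <- rep(c("g1", "g2", "g3"), each = 3)
  res3 <- anova_lsd(v, g)
  an <- anova(aov(v ~ factor(g)))
  mse <- an[["Mean Sq"]][2]
  for (pair in list(c("g1", "g2"), c("g1", "g3"), c("g2", "g3"))) {
    mi <- mean(v[g == pair[1]]); mj <- mean(v[g == pair[2]])
    tij <- (mi - mj) / sqrt(mse * (1 / 3 + 1 / 3))
    expect_equal(res3$pairwise[pair[1], pair[2]], 2 * pt(-abs(tij), 6),
                 tolerance = 1e-12)
  }
  # letters: g1 and g3 indistinguishable, g2 separate
  expect_equal(unname(res3$letters["g1"]), unname(res3$letters["g3"]))
  expect_false(res3$letters["g2"] == res3$letters["g1"])
})

test_that("module regressions recover exact and orthogonal relationships", {
  z <- rbind(m1a = c(-1.2, 0.3, 1.1, -0.5, 0.3),
             m1b = c(-0.8, 0.1, 0.9, -0.7, 0.5),
             m2a = c(1, -1, 1, -1, 0),
             m2b = c(-1, 1, -1, 1, 0))
  colnames(z) <- paste0("s", 1:5)
  part <- structure(list(assignment = c(m1a = 1L, m1b = 1L, m2a = 2L,
                                        m2b = 2L),
                         modularity_Q = 0.1, algorithm = "fixed", seed = 1L),
                    class = "module_partition")
  ab1 <- colMeans(z[1:2, ])
  n2o <- data.frame(sample_id = paste0("s", 1:5), rate = 2 * ab1 + 1)
  res <- module_abundance_regression(z, part, n2o)
  expect_equal(res$r_squared[res$module == 1], 1, tolerance = 1e-9)
  expect_equal(res$slope[res$module == 1], 2, tolerance = 1e-9)
  # module 2 abundance is identically zero -> degenerate flag
  expect_true(res$degenerate[res$module == 2])

  # constructed orthogonality: slope exactly 0
  z2 <- rbind(a = c(-1, 1, -1, 1), b = c(-1, 1, -1, 1))
  colnames(z2) <- paste0("s", 1:4)
  part2 <- structure(list(assignment = c(a = 1L, b = 1L), modularity_Q = 0,
                          algorithm = "fixed", seed = 1L),
                     class = "module_partition")
  n2o2 <- data.frame(sample_id = paste0("s", 1:4), rate = c(1, 1, 5, 5))
  res2 <- module_abundance_regression(z2, part2, n2o2)
  expect_lt(abs(res2$slope), 1e-12)

  bad <- data.frame(sample_id = paste0("s", 1:3), rate = 1:3)
  expect_error(module_abundance_regression(z2, part2, bad),
               class = "n2onet_consistency_error")
})

test_that("Pearson screening matches the closed-form covariance ratio", {
  n2o <- data.frame(sample_id = paste0("s", 1:6),
                    rate = c(0.1, 0.5, 0.3, 0.9, 0.7, 0.2))
  feats <- data.frame(same = n2o$rate, anti = -n2o$rate,
                      other = c(1, 2, 1.5, 3, 2.5, 1.2),
                      flat = rep(2, 6))
  rownames(feats) <- n2o$sample_id
  res <- pearson_screen(feats, n2o)
  expect_equal(res$r[res$feature == "same"], 1)
  expect_equal(res$r[res$feature == "anti"], -1)
  r_manual <- cov(feats$other, n2o$rate) / (sd(feats$other) * sd(n2o$rate))
  expect_equal(res$r[res$feature == "other"], r_manual, tolerance = 1e-12)
  expect_true(res$excluded[res$feature == "flat"])
  expect_equal(res$stars[res$feature == "same"], "***")
})
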