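jg <- function(sigma, mean = rep(0, nrow(sigma))) {
  structure(list(mean = mean, sigma = sigma), class = "joint_gaussian")
}

test_that("Hellinger distance matches closed forms and its metric properties", {
  set.seed(31)
  s <- random_pd_matrix(4)
  expect_equal(hellinger_distance(jg(s), jg(s)), 0)
  # univariate variances 1 vs 4
  expect_equal(hellinger_distance(jg(matrix(1, 1, 1)), jg(matrix(4, 1, 1))),
               sqrt(1 - sqrt(2) / sqrt(2.5)), tolerance = 1e-12)
  # monotone approach to 1 as the variance ratio diverges
  hs <- vapply(c(4, 40, 400, 4000), function(v)
    hellinger_distance(jg(matrix(1, 1, 1)), jg(matrix(v, 1, 1))), numeric(1))
  expect_true(all(diff(hs) > 0))
  expect_lt(1 - hs[4], 0.1)
  for (k in 1:20) {
    s1 <- random_pd_matrix(3)
    s2 <- random_pd_matrix(3)
    h12 <- hellinger_distance(jg(s1), jg(s2))
    expect_equal(h12, hellinger_distance(jg(s2), jg(s1)), tolerance = 1e-12)
    expect_gte(h12, 0)
    expect_lte(h12, 1)
  }
  expect_error(hellinger_distance(jg(matrix(1, 1, 1), mean = 0),
                                  jg(matrix(1, 1, 1), mean = 1)),
               "means differ")
})

test_that("block-diagonal covariances factorize the Hellinger affinity", {
  set.seed(32)
  b1a <- random_pd_matrix(2); b1b <- random_pd_matrix(3)
  b2a <- random_pd_matrix(2); b2b <- random_pd_matrix(3)
  blockdiag <- function(a, b) {
    out <- matrix(0, nrow(a) + nrow(b), ncol(a) + ncol(b))
    out[seq_len(nrow(a)), seq_len(ncol(a))] <- a
    out[-seq_len(nrow(a)), -seq_len(ncol(a))] <- b
    out
  }
  h_full <- hellinger_distance(jg(blockdiag(b1a, b1b)), jg(blockdiag(b2a, b2b)))
  h_a <- hellinger_distance(jg(b1a), jg(b2a))
  h_b <- hellinger_distance(jg(b1b), jg(b2b))
  expect_equal(1 - h_full^2, (1 - h_a^2) * (1 - h_b^2), tolerance = 1e-10)
})

test_that("re-fitting preserves structure, equalizes means, and is idempotent", {
  bn <- random_gbn(4, 801L)
  d <- sample_gbn(bn, 200, seed = 802L)
  refit <- refit_parameters(bn$structure, d)
  expect_identical(refit$structure$arcs, bn$structure$arcs)
  expect_equal(refit$params, fit_parameters(bn$structure, d)$params)
  # empty structure refit: marginal variances (ML) of the data
  emp <- refit_parameters(dag(colnames(d)), d)
  expect_equal(vapply(emp$params, `[[`, numeric(1), "variance"),
               vapply(d, function(x) mean((x - mean(x))^2), numeric(1)))
  # any two structures fitted on the same data imply the same mean vector
  other <- random_dag(4, 0.5, seed = 803L, nodes = colnames(d))
  mu1 <- bn_to_joint(refit_parameters(bn$structure, d))$mean
  mu2 <- bn_to_joint(refit_parameters(other, d))$mean
  expect_equal(mu1, mu2, tolerance = 1e-8)
  expect_equal(unname(mu1), unname(colMeans(d)), tolerance = 1e-8)
})

test_that("network comparison is zero on self and reports shared structure", {
  bn <- random_gbn(4, 804L, dead_zone = 0.4)
  d <- standardize_table(sample_gbn(bn, 150, seed = 805L))
  fit <- fit_parameters(bn$structure, d)
  self <- compare_networks(fit, fit, d, d, standardize = FALSE)
  expect_equal(self$hellinger_on_A, 0, tolerance = 1e-10)
  expect_equal(self$hellinger_on_B, 0, tolerance = 1e-10)
  expect_true(all(self$markov_blanket_agreement))
  expect_equal(length(self$common_arcs),
               nrow(bn$structure$arcs))
  # disjoint structures share no arcs
  ga <- dag(c("P", "Q", "R"), rbind(c("P", "Q")))
  gb <- dag(c("P", "Q", "R"), rbind(c("Q", "R")))
  set.seed(33)
  da <- as.data.frame(matrix(rnorm(120), ncol = 3,
                             dimnames = list(NULL, c("P", "Q", "R"))))
  db <- as.data.frame(matrix(rnorm(120), ncol = 3,
                             dimnames = list(NULL, c("P", "Q", "R"))))
  cmp <- compare_networks(fit_parameters(ga, da), fit_parameters(gb, db),
                          da, db)
  expect_length(cmp$common_arcs, 0L)
  expect_error(compare_networks(fit_parameters(ga, da),
                                fit_parameters(dag(c("P", "Q")), da[1:2]),
                                da, da), "different variable sets")
})

test_that("equal structures with rescaled variances reduce to the univariate product", {
  # independent nodes, variances 1 vs 4 per coordinate: affinity factorizes,
  # so H^2 = 1 - (sqrt(2)/sqrt(2.5))^n
  n <- 3
  s1 <- diag(n)
  s2 <- diag(n) * 4
  h <- hellinger_distance(jg(s1), jg(s2))
  expect_equal(h, sqrt(1 - (sqrt(2) / sqrt(2.5))^n), tolerance = 1e-12)
})

test_that("correlation networks threshold strictly and nest across thresholds", {
  bn <- random_gbn(5, 806L, dead_zone = 0.4)
  d <- sample_gbn(bn, 100, seed = 807L)
  expect_equal(nrow(correlation_network(d, 1)$edges), 0L)
  full <- correlation_network(d, 0)
  expect_equal(nrow(full$edges), choose(5, 2))
  e4 <- correlation_network(d, 0.4)$edges
  e5 <- correlation_network(d, 0.5)$edges
  expect_true(all(paste(e5[, 1], e5[, 2]) %in% paste(e4[, 1], e4[, 2])))
  # affine rescaling leaves the edge set unchanged
  d2 <- d
  d2[[1]] <- d2[[1]] * 7 + 2
  expect_identical(correlation_network(d2, 0.4)$edges, e4)
  dc <- d
  dc$const <- 1
  expect_error(correlation_network(dc, 0.4), "const")
  f <- withr::local_tempfile(fileext = ".graphml")
  write_correlation_graphml(correlation_network(d, 0.4), f)
  expect_true(any(grepl("graphml", readLines(f))))
})

test_that("Welch tables detect large effects and are label-symmetric", {
  set.seed(34)
  da <- data.frame(v1 = rnorm(40, 0), v2 = rnorm(40, 0))
  db <- data.frame(v1 = rnorm(20, 3), v2 = rnorm(20, 0))
  tab <- welch_t_table(da, db, group_names = c("human", "mouse"))
  expect_equal(tab$variable, c("v1", "v2"))
  expect_lt(tab$p_value[1], 0.001)
  expect_gt(tab$p_value[2], 0.05)
  expect_true(all(c("mean_human", "sd_mouse") %in% names(tab)))
  swapped <- welch_t_table(db, da)
  expect_equal(tab$p_value, swapped$p_value, tolerance = 1e-12)
  same <- welch_t_table(da, da)
  expect_true(all(same$p_value == 1))
})

test_that("subgroup correlations expose Simpson-style sign reversal", {
  # within each depth subgroup y increases with x, but the deep subgroup's
  # mean shifts down so the pooled correlation reverses sign
  set.seed(35)
  n <- 40
  deep <- rep(c(FALSE, TRUE), each = n / 2)
  x <- rnorm(n, 0, 0.5)
  y <- x + ifelse(deep, -4, 4) + rnorm(n, 0, 0.1)
  d <- data.frame(depth = ifelse(deep, 0.6, 0.1) + runif(n, 0, 0.02),
                  x = x + ifelse(deep, 2, -2), y = y)
  res <- subgroup_correlations(d, "depth", 0.28, "y")
  rx <- res[res$variable == "x", ]
  expect_lt(rx$rho_all, -0.5)
  expect_gt(rx$rho_below, 0.5)
  expect_gt(rx$rho_above, 0.5)
  # cutpoint below every value: the below subgroup is missing
  res2 <- subgroup_correlations(d, "depth", 0.01, "y")
  rx2 <- res2[res2$variable == "x", ]
  expect_true(is.na(rx2$rho_below))
  expect_equal(rx2$rho_above, rx$rho_all, tolerance = 1e-12)
})
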