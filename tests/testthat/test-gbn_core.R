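test_that("parameter fitting recovers truth and uses the ML variance", {
  # empty structure: intercept = column mean, variance = biased column variance
  set.seed(11)
  d <- data.frame(A = rnorm(50, 3, 2), B = rnorm(50, -1, 0.5))
  fit <- fit_parameters(dag(c("A", "B")), d)
  expect_equal(fit$params$A$intercept, mean(d$A))
  expect_equal(fit$params$A$variance, mean((d$A - mean(d$A))^2))
  # consistency on a known chain
  chain <- gbn(dag(c("X", "Y"), rbind(c("X", "Y"))),
               list(X = list(intercept = 0, coefficients = setNames(numeric(0), character(0)), variance = 1),
                    Y = list(intercept = 0, coefficients = c(X = 2), variance = 1)))
  big <- sample_gbn(chain, 100000, seed = 12)
  refit <- fit_parameters(chain$structure, big)
  expect_lt(abs(refit$params$Y$coefficients[["X"]] - 2), 0.05)
  expect_identical(fit_parameters(chain$structure, big),
                   fit_parameters(chain$structure, big))
  # rank-deficient parent design is a named error
  dup <- data.frame(X = rnorm(20))
  dup$Z <- dup$X
  dup$Y <- rnorm(20)
  gg <- dag(c("X", "Z", "Y"), rbind(c("X", "Y"), c("Z", "Y")))
  expect_error(fit_parameters(gg, dup), "singular fit for node Y")
})

test_that("BIC matches the closed-form univariate Gaussian case", {
  set.seed(13)
  x <- rnorm(100)
  d <- data.frame(X = x)
  s2 <- mean((x - mean(x))^2)
  loglik <- sum(dnorm(x, mean(x), sqrt(s2), log = TRUE))
  expect_equal(bic_score(dag("X"), d), loglik - (2 / 2) * log(100),
               tolerance = 1e-10)
})

test_that("BIC is score equivalent and penalizes null parents at large N", {
  set.seed(14)
  d <- data.frame(X = rnorm(200), Y = rnorm(200))
  d$Y <- 0.8 * d$X + d$Y
  sxy <- bic_score(dag(c("X", "Y"), rbind(c("X", "Y"))), d)
  syx <- bic_score(dag(c("X", "Y"), rbind(c("Y", "X"))), d)
  expect_equal(sxy, syx, tolerance = 1e-9)
  # an irrelevant parent lowers the score once the penalty dominates
  set.seed(15)
  big <- data.frame(X = rnorm(5000), Y = rnorm(5000))
  expect_lt(bic_score(dag(c("X", "Y"), rbind(c("X", "Y"))), big),
            bic_score(dag(c("X", "Y")), big))
})

test_that("joint conversion and precision matrix are exact mutual inverses", {
  # analytic chain values
  chain <- gbn(dag(c("X", "Y"), rbind(c("X", "Y"))),
               list(X = list(intercept = 0, coefficients = setNames(numeric(0), character(0)), variance = 1),
                    Y = list(intercept = 0, coefficients = c(X = 2), variance = 1)))
  expect_equal(unname(bn_to_joint(chain)$sigma), matrix(c(1, 2, 2, 5), 2),
               tolerance = 1e-12)
  expect_equal(unname(precision_matrix(chain)), matrix(c(5, -2, -2, 1), 2),
               tolerance = 1e-12)
  iso <- random_parameters(dag(paste0("V", 1:4)), var_range = c(1, 1), seed = 2)
  expect_equal(unname(bn_to_joint(iso)$sigma), diag(4), tolerance = 1e-12)
  expect_equal(unname(precision_matrix(iso)), diag(4), tolerance = 1e-12)
  for (seed in 1:20) {
    bn <- random_gbn(6, seed)
    prod <- precision_matrix(bn) %*% bn_to_joint(bn)$sigma
    expect_lt(max(abs(prod - diag(6))), 1e-8)
  }
})

test_that("implied means solve mu = b0 + W mu", {
  g <- dag(c("X", "Y"), rbind(c("X", "Y")))
  bn <- gbn(g, list(X = list(intercept = 1, coefficients = setNames(numeric(0), character(0)), variance = 1),
                    Y = list(intercept = 2, coefficients = c(X = 3), variance = 1)))
  expect_equal(unname(bn_to_joint(bn)$mean), c(1, 5))
})

test_that("partial correlations match the Schur-complement residual oracle", {
  expect_equal(unname(partial_correlations(diag(3))), diag(3))
  # chain X -> Y -> Z: X and Z conditionally independent given Y
  g <- dag(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
  bn <- random_parameters(g, seed = 16)
  rho <- partial_correlations(precision_matrix(bn))
  expect_equal(rho["X", "Z"], 0, tolerance = 1e-12)
  for (seed in 1:10) {
    bn <- random_gbn(5, seed + 30L)
    sigma <- bn_to_joint(bn)$sigma
    rho <- partial_correlations(precision_matrix(bn))
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(rho[i, j], oracle_partial_cor(sigma, i, j),
                   tolerance = 1e-10)
    }
  }
  expect_error(partial_correlations(matrix(c(-1, 0, 0, 1), 2)),
               "non-positive diagonal")
})

test_that("partial correlations from fitted networks are scale invariant", {
  bn0 <- random_gbn(5, 77)
  d <- sample_gbn(bn0, 300, seed = 78)
  struct <- bn0$structure
  rho1 <- partial_correlations(precision_matrix(fit_parameters(struct, d)))
  d2 <- d
  d2[[2]] <- d2[[2]] * 10
  rho2 <- partial_correlations(precision_matrix(fit_parameters(struct, d2)))
  expect_equal(rho1, rho2, tolerance = 1e-10)
})

test_that("precision entries vanish exactly at moral non-adjacency", {
  for (seed in 1:10) {
    bn <- random_gbn(5, seed + 60L)
    A <- amat(bn$structure)
    omega <- precision_matrix(bn)
    nodes <- bn$structure$nodes
    for (i in 1:4) for (j in (i + 1):5) {
      x <- nodes[i]; y <- nodes[j]
      moral <- A[x, y] || A[y, x] || any(A[x, ] & A[y, ])
      if (!moral) expect_identical(omega[x, y], 0)
    }
  }
})

test_that("Markov blankets cover parents, children and spouses", {
  g <- dag(c("X", "Y", "Z"), rbind(c("X", "Z"), c("Y", "Z")))
  expect_setequal(markov_blanket(g, "X"), c("Y", "Z"))
  expect_equal(markov_blanket(dag(c("A", "B")), "A"), character(0))
  expect_error(markov_blanket(g, "Q"), "unknown node")
  # conditional-independence oracle: rho of (node, other | MB) is 0 when
  # `other` is outside the blanket
  for (seed in 1:5) {
    bn <- random_gbn(6, seed + 90L)
    sigma <- bn_to_joint(bn)$sigma
    nodes <- bn$structure$nodes
    for (v in nodes) {
      mb <- markov_blanket(bn$structure, v)
      for (o in setdiff(nodes, c(v, mb))) {
        idx <- match(c(v, o, mb), nodes)
        sub <- sigma[idx, idx, drop = FALSE]
        expect_lt(abs(oracle_partial_cor(sub, 1, 2)), 1e-8)
      }
    }
  }
})

test_that("DAG to CPDAG handles canonical cases and serializes", {
  cp <- dag_to_cpdag(dag(c("X", "Y"), rbind(c("X", "Y"))))
  expect_equal(nrow(cp$directed), 0L)
  expect_equal(nrow(cp$undirected), 1L)
  vp <- dag_to_cpdag(dag(c("X", "Y", "Z"), rbind(c("X", "Z"), c("Y", "Z"))))
  expect_equal(nrow(vp$directed), 2L)
  expect_equal(nrow(vp$undirected), 0L)
  # serialization round trips
  g <- random_dag(5, 0.4, seed = 17)
  f <- withr::local_tempfile(fileext = ".json")
  bn <- random_parameters(g, seed = 18)
  gbn_to_json(bn, f)
  back <- gbn_from_json(f)
  expect_equal(back$params, bn$params, tolerance = 1e-12)
  expect_setequal(paste(back$structure$arcs[, 1], back$structure$arcs[, 2]),
                  paste(g$arcs[, 1], g$arcs[, 2]))
  dotf <- withr::local_tempfile(fileext = ".dot")
  write_dot(g, dotf)
  expect_true(any(grepl("->", readLines(dotf))))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  expect_true(any(grepl("graphml", readLines(gml))))
})

test_that("CPDAGs match brute-force equivalence enumeration on random 5-node DAGs", {
  for (seed in 1:10) {
    g <- random_dag(5, 0.4, seed = seed + 200L)
    cp <- cpdag_keys(dag_to_cpdag(g))
    orc <- oracle_cpdag(g)
    expect_identical(cp$directed, orc$directed)
    expect_identical(cp$undirected, orc$undirected)
  }
})
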