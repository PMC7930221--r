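#' Gaussian Bayesian network
#'
#' Couples a DAG with linear-Gaussian local conditionals: each node i carries
#' an intercept, one coefficient per parent, and a residual variance, so the
#' joint density is the product of N(x_i ; b0_i + b_i' pa(x_i), s2_i) terms
#' and is itself multivariate normal.
#'
#' @param structure a `dag`.
#' @param params named list (one entry per node) of lists with elements
#'   `intercept` (scalar), `coefficients` (named numeric, names = parents),
#'   `variance` (positive scalar).
#' @return object of class `"gbn"`.
#' @export
gbn <- function(structure, params) {
  stopifnot(inherits(structure, "dag"))
  if (!setequal(names(params), structure$nodes))
    stop("params must name every node exactly once")
  for (v in structure$nodes) {
    p <- params[[v]]
    pa <- sort(parents(structure, v))
    if (!setequal(names(p$coefficients), pa))
      stop("coefficients of ", v, " must be named by its parents")
    if (!is.finite(p$variance) || p$variance <= 0)
      stop("residual variance of ", v, " must be strictly positive")
  }
  base::structure(list(structure = structure, params = params[structure$nodes]),
                  class = "gbn")
}

#' @export
print.gbn <- function(x, ...) {
  cat("Gaussian Bayesian network,", length(x$structure$nodes), "nodes,",
      nrow(x$structure$arcs), "arcs\n")
  invisible(x)
}

#' Standardize a feature table
#'
#' Centers each column and scales to unit standard deviation (denominator
#' N - 1). Network learning and precision-matrix estimation operate on
#' standardized variables.
#'
#' @param data data frame of numeric columns.
#' @return data frame of z-scores.
#' @export
standardize_table <- function(data) {
  data <- as.data.frame(data)
  sds <- vapply(data, stats::sd, numeric(1))
  if (any(!is.finite(sds)) || any(sds == 0))
    stop("cannot standardize constant column(s): ",
         paste(names(data)[!is.finite(sds) | sds == 0], collapse = ", "))
  as.data.frame(scale(data), check.names = FALSE)
}

# Gram matrix of (1, X); all OLS fits and scores derive from it, which makes
# family-score evaluation O(p^3) independent of N inside the search loop.
gram_matrix <- function(data) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  M <- cbind(`(Intercept)` = 1, X)
  list(C = crossprod(M), N = nrow(X), vars = colnames(X))
}

# OLS of `node` on `pars` from the Gram matrix; variance uses the ML
# denominator N so that the BIC stays a true penalized log-likelihood.
family_fit <- function(gram, node, pars) {
  C <- gram$C
  N <- gram$N
  idx <- c("(Intercept)", pars)
  Cpp <- C[idx, idx, drop = FALSE]
  Cpy <- C[idx, node]
  beta <- tryCatch(solve(Cpp, Cpy),
                   error = function(e) stop("singular fit for node ", node,
                                            " (rank-deficient parents)",
                                            call. = FALSE))
  rss <- C[node, node] - 2 * sum(beta * Cpy) + drop(crossprod(beta, Cpp %*% beta))
  rss <- max(rss, 0)
  list(intercept = unname(beta[1L]),
       coefficients = stats::setNames(beta[-1L], pars),
       variance = rss / N)
}

# Per-node BIC contribution: logL_i - (|Pa| + 2)/2 * log N, natural logs.
family_bic <- function(gram, node, pars) {
  fit <- family_fit(gram, node, pars)
  s2 <- fit$variance
  if (s2 <= 0) s2 <- .Machine$double.eps
  N <- gram$N
  loglik <- -N / 2 * (log(2 * pi * s2) + 1)
  loglik - (length(pars) + 2) / 2 * log(N)
}

#' Fit the parameters of a Gaussian BN by maximum likelihood
#'
#' Each node is regressed on its parents by ordinary least squares; residual
#' variances use the maximum-likelihood denominator N (not N - p - 1).
#'
#' @param structure a `dag`.
#' @param data data frame whose columns cover `structure$nodes`.
#' @return a `gbn`.
#' @export
fit_parameters <- function(structure, data) {
  stopifnot(inherits(structure, "dag"))
  data <- as.data.frame(data)
  missing_cols <- setdiff(structure$nodes, colnames(data))
  if (length(missing_cols) > 0L)
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "))
  gram <- gram_matrix(data[structure$nodes])
  params <- lapply(structure$nodes, function(v)
    family_fit(gram, v, sort(parents(structure, v))))
  names(params) <- structure$nodes
  gbn(structure, params)
}

#' Re-fit a network structure on another data set
#'
#' Keeps the DAG and re-estimates all local parameters on `other_data`; used
#' before Hellinger comparison so both distributions share the means of the
#' same sample.
#'
#' @param structure a `dag` (or a `gbn`, whose structure is taken).
#' @param other_data data frame covering the structure's variables.
#' @export
refit_parameters <- function(structure, other_data) {
  if (inherits(structure, "gbn")) structure <- structure$structure
  fit_parameters(structure, other_data)
}

#' BIC score of a structure on data
#'
#' Penalized Gaussian log-likelihood, decomposable over nodes:
#' sum_i \[ logL_i - (k_i / 2) log N \] with k_i = |Pa(i)| + 2 (intercept,
#' coefficients, variance). Natural logarithms; higher is better.
#'
#' @inheritParams fit_parameters
#' @return scalar score in nats.
#' @export
bic_score <- function(structure, data) {
  stopifnot(inherits(structure, "dag"))
  data <- as.data.frame(data)
  gram <- gram_matrix(data[structure$nodes])
  sum(vapply(structure$nodes, function(v)
    family_bic(gram, v, sort(parents(structure, v))), numeric(1)))
}

# n x n coefficient matrix W (row i = node i's parent coefficients) and
# diagonal S of residual variances, in the node order of the structure.
gbn_matrices <- function(bn) {
  nodes <- bn$structure$nodes
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  s2 <- numeric(n)
  b0 <- numeric(n)
  for (i in seq_len(n)) {
    p <- bn$params[[nodes[i]]]
    if (length(p$coefficients) > 0L)
      W[nodes[i], names(p$coefficients)] <- p$coefficients
    s2[i] <- p$variance
    b0[i] <- p$intercept
  }
  list(W = W, s2 = s2, b0 = b0, nodes = nodes)
}

#' Joint multivariate Gaussian implied by a Gaussian BN
#'
#' With W the matrix of parent coefficients (row per child) and S the
#' diagonal of residual variances, mu solves mu = b0 + W mu and
#' Sigma = (I - W)^-1 S (I - W)^-T.
#'
#' @param bn a `gbn`.
#' @return object of class `"joint_gaussian"` with `mean` and `sigma`.
#' @export
bn_to_joint <- function(bn) {
  stopifnot(inherits(bn, "gbn"))
  m <- gbn_matrices(bn)
  n <- length(m$nodes)
  IW <- diag(n) - m$W
  mu <- solve(IW, m$b0)
  Ainv <- solve(IW)
  sigma <- Ainv %*% (m$s2 * t(Ainv))
  sigma <- (sigma + t(sigma)) / 2
  dimnames(sigma) <- list(m$nodes, m$nodes)
  structure(list(mean = stats::setNames(mu, m$nodes), sigma = sigma),
            class = "joint_gaussian")
}

#' Precision matrix implied by a Gaussian BN
#'
#' Omega = (I - W)' S^-1 (I - W), computed directly from the network
#' parameters without inverting Sigma, so it exists even when the empirical
#' covariance is singular (N <= n).
#'
#' @param bn a `gbn`.
#' @return symmetric positive-definite matrix with variable dimnames.
#' @export
precision_matrix <- function(bn) {
  stopifnot(inherits(bn, "gbn"))
  m <- gbn_matrices(bn)
  IW <- diag(length(m$nodes)) - m$W
  omega <- t(IW) %*% ((1 / m$s2) * IW)
  omega <- (omega + t(omega)) / 2
  dimnames(omega) <- list(m$nodes, m$nodes)
  omega
}

#' Partial correlations from a precision matrix
#'
#' rho_XY|Z = -Omega_XY / sqrt(Omega_XX Omega_YY), the correlation of X and Y
#' given all remaining variables; unit diagonal by convention.
#'
#' @param omega symmetric precision matrix (e.g. from [precision_matrix()]).
#' @return symmetric matrix of partial correlations.
#' @export
partial_correlations <- function(omega) {
  d <- diag(omega)
  if (any(d <= 0)) stop("invalid precision matrix: non-positive diagonal")
  rho <- -omega / sqrt(outer(d, d))
  diag(rho) <- 1
  rho
}

#' Serialize a Gaussian BN's parameters to JSON
#'
#' One object per node: intercept, coefficients keyed by parent name, and
#' residual variance.
#'
#' @param bn a `gbn`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
gbn_to_json <- function(bn, path = NULL) {
  obj <- lapply(bn$params, function(p) list(
    intercept = p$intercept,
    coefficients = as.list(p$coefficients),
    variance = p$variance))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname gbn_to_json
#' @param json path to a JSON file or a JSON string written by `gbn_to_json`.
#' @export
gbn_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  nodes <- names(obj)
  arcs <- do.call(rbind, lapply(nodes, function(v) {
    pa <- names(obj[[v]]$coefficients)
    if (length(pa) == 0L) NULL else cbind(from = pa, to = v)
  }))
  params <- lapply(obj, function(p) list(
    intercept = p$intercept,
    coefficients = stats::setNames(as.numeric(unlist(p$coefficients, use.names = FALSE)),
                                   names(p$coefficients)),
    variance = p$variance))
  gbn(dag(nodes, arcs), params)
}
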