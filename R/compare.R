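#' Hellinger distance between two multivariate Gaussians
#'
#' Closed form for equal-mean Gaussians:
#' H = sqrt(1 - det(S1)^(1/4) det(S2)^(1/4) / det((S1 + S2)/2)^(1/2)),
#' evaluated via Cholesky log-determinants for numerical stability. The
#' distance is bounded in \[0, 1\], zero iff the covariances coincide. Both
#' inputs must share their mean vector (enforced to `mean_tol`): upstream,
#' parameters of both networks are re-fitted on the same data set so this
#' holds by construction.
#'
#' @param joint1,joint2 `joint_gaussian` objects of equal dimension.
#' @param mean_tol guard tolerance for mean equality (default 1e-8 on the
#'   standardized scale).
#' @return scalar in \[0, 1\].
#' @export
hellinger_distance <- function(joint1, joint2, mean_tol = 1e-8) {
  stopifnot(inherits(joint1, "joint_gaussian"),
            inherits(joint2, "joint_gaussian"))
  s1 <- joint1$sigma
  s2 <- joint2$sigma
  if (!all(dim(s1) == dim(s2)))
    stop("covariance matrices have different dimensions")
  if (max(abs(joint1$mean - joint2$mean)) > mean_tol)
    stop("means differ beyond tolerance; re-fit both networks on the same ",
         "data before comparing")
  logdet <- function(s) 2 * sum(log(diag(chol(s))))
  h2 <- 1 - exp(0.25 * logdet(s1) + 0.25 * logdet(s2) -
                0.5 * logdet((s1 + s2) / 2))
  sqrt(min(max(h2, 0), 1))
}

# CPDAG edges as canonical strings: directed keep orientation, undirected
# are order-normalized; used for the common-arc comparison
cpdag_edge_keys <- function(cp) {
  d <- if (nrow(cp$directed) > 0L)
    paste0(cp$directed[, 1L], "->", cp$directed[, 2L]) else character(0)
  u <- if (nrow(cp$undirected) > 0L)
    paste0(pmin(cp$undirected[, 1L], cp$undirected[, 2L]), "--",
           pmax(cp$undirected[, 1L], cp$undirected[, 2L])) else character(0)
  c(d, u)
}

#' Compare two fitted Gaussian BNs across their data sets
#'
#' Reports two Hellinger distances, one per data set: the structure learned
#' on group A is re-fitted on group B's data and compared with the network
#' fitted on B (distance on B), and vice versa. Re-fitting on a common data
#' set equalizes the means, so each distance reflects covariance-structure
#' differences only. Also reports the arcs common to both CPDAGs (matching
#' adjacency and orientation class) and per-variable Markov-blanket
#' agreement.
#'
#' @param bnA,bnB `gbn`s fitted on their own (standardized) group data.
#' @param dataA,dataB the two groups' feature tables over the same
#'   variables.
#' @param standardize z-score each table before re-fitting (default TRUE,
#'   matching how the networks are learned).
#' @return object of class `"bn_comparison"`: `hellinger_on_A`,
#'   `hellinger_on_B`, `common_arcs`, `markov_blanket_agreement`,
#'   `cpdag_A`, `cpdag_B`.
#' @export
compare_networks <- function(bnA, bnB, dataA, dataB, standardize = TRUE) {
  stopifnot(inherits(bnA, "gbn"), inherits(bnB, "gbn"))
  vars <- bnA$structure$nodes
  if (!setequal(vars, bnB$structure$nodes))
    stop("networks are defined over different variable sets")
  dataA <- as.data.frame(dataA)[vars]
  dataB <- as.data.frame(dataB)[vars]
  if (standardize) {
    dataA <- standardize_table(dataA)
    dataB <- standardize_table(dataB)
  }
  on_data <- function(struct_own, struct_other, dat) {
    hellinger_distance(bn_to_joint(refit_parameters(struct_own, dat)),
                       bn_to_joint(refit_parameters(struct_other, dat)))
  }
  h_on_A <- on_data(bnA, bnB, dataA)
  h_on_B <- on_data(bnB, bnA, dataB)
  cpA <- dag_to_cpdag(bnA$structure)
  cpB <- dag_to_cpdag(bnB$structure)
  common <- intersect(cpdag_edge_keys(cpA), cpdag_edge_keys(cpB))
  mb <- vapply(sort(vars), function(v)
    setequal(markov_blanket(bnA$structure, v),
             markov_blanket(bnB$structure, v)), logical(1))
  structure(list(hellinger_on_A = h_on_A, hellinger_on_B = h_on_B,
                 common_arcs = sort(common),
                 markov_blanket_agreement = mb,
                 cpdag_A = cpA, cpdag_B = cpB),
            class = "bn_comparison")
}

#' @export
print.bn_comparison <- function(x, ...) {
  cat("Hellinger distance on data A:", format(x$hellinger_on_A), "\n")
  cat("Hellinger distance on data B:", format(x$hellinger_on_B), "\n")
  cat("Common CPDAG arcs:", if (length(x$common_arcs) == 0L) "none"
      else paste(x$common_arcs, collapse = ", "), "\n")
  cat("Variables with identical Markov blankets:",
      sum(x$markov_blanket_agreement), "of",
      length(x$markov_blanket_agreement), "\n")
  invisible(x)
}

#' Marginal correlation network
#'
#' Pearson correlations on the empirical (unregularized) covariance; an
#' undirected edge links X and Y iff |rho| is strictly above `tau`.
#'
#' @param data data frame of numeric columns, N >= 3.
#' @param tau correlation threshold (the motivating study used 0.4 for
#'   human and 0.5 for mouse cells).
#' @return object of class `"correlation_network"`: `nodes`, `rho`
#'   (correlation matrix), `tau`, `edges` (2-column matrix with `from <
#'   to`).
#' @export
correlation_network <- function(data, tau) {
  data <- as.data.frame(data)
  if (nrow(data) < 3L) stop("need at least 3 observations")
  sds <- vapply(data, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("correlation undefined for constant column(s): ",
         paste(names(data)[sds == 0], collapse = ", "))
  rho <- stats::cor(data)
  nodes <- colnames(rho)
  edges <- NULL
  if (length(nodes) >= 2L) {
    pairs <- utils::combn(sort(nodes), 2L)
    for (k in seq_len(ncol(pairs)))
      if (abs(rho[pairs[1L, k], pairs[2L, k]]) > tau)
        edges <- rbind(edges, pairs[, k])
  }
  structure(list(nodes = nodes, rho = rho, tau = tau,
                 edges = normalize_arcs(edges)),
            class = "correlation_network")
}

#' Write a correlation network as GraphML
#'
#' Undirected graph with |rho| edge weights.
#'
#' @param net a `correlation_network`.
#' @param path output file.
#' @export
write_correlation_graphml <- function(net, path) {
  e <- as.data.frame(net$edges)
  if (nrow(e) > 0L)
    e$weight <- abs(net$rho[as.matrix(e[, 1:2])])
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Per-variable group comparison table
#'
#' Means and standard deviations per group plus the two-sided p-value of
#' Welch's unequal-variance two-sample t-test, one row per shared variable.
#'
#' @param dataA,dataB data frames over a common variable set (>= 2
#'   non-missing values per variable per group).
#' @param group_names length-2 labels used in column names.
#' @return data frame: variable, mean/sd per group, t statistic, p_value.
#' @export
welch_t_table <- function(dataA, dataB, group_names = c("A", "B")) {
  vars <- intersect(colnames(dataA), colnames(dataB))
  if (length(vars) == 0L) stop("no shared variables")
  rows <- lapply(vars, function(v) {
    a <- dataA[[v]][!is.na(dataA[[v]])]
    b <- dataB[[v]][!is.na(dataB[[v]])]
    if (length(a) < 2L || length(b) < 2L)
      stop("variable ", v, " has fewer than 2 values in a group")
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(variable = v, mean_A = mean(a), sd_A = stats::sd(a),
               mean_B = mean(b), sd_B = stats::sd(b),
               t = unname(tt$statistic), p_value = tt$p.value)
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("_A$", paste0("_", group_names[1L]), names(out))
  names(out) <- sub("_B$", paste0("_", group_names[2L]), names(out))
  rownames(out) <- NULL
  out
}

#' Correlations with a target variable, overall and within depth subgroups
#'
#' Splits the cells at `cutpoint` on `split_var` (below: value <= cutpoint;
#' above: value > cutpoint) and reports the Pearson correlation of every
#' other variable with `target_var` overall and within each subgroup. A
#' subgroup with fewer than 3 cells yields `NA` (flagged, not an error).
#' Pooled and within-subgroup correlations can disagree in sign
#' (Simpson-style reversal) when subgroup means shift oppositely.
#'
#' @param data data frame of numeric columns.
#' @param split_var name of the splitting variable (e.g. `rel_depth`).
#' @param cutpoint split value (the motivating study used 0.28).
#' @param target_var variable to correlate against.
#' @return data frame: variable, rho_all, rho_below, rho_above, n_below,
#'   n_above.
#' @export
subgroup_correlations <- function(data, split_var, cutpoint, target_var) {
  data <- as.data.frame(data)
  stopifnot(split_var %in% colnames(data), target_var %in% colnames(data))
  below <- data[[split_var]] <= cutpoint
  vars <- setdiff(colnames(data), target_var)
  safe_cor <- function(x, y) {
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y)
  }
  rows <- lapply(vars, function(v) data.frame(
    variable = v,
    rho_all = safe_cor(data[[v]], data[[target_var]]),
    rho_below = safe_cor(data[[v]][below], data[[target_var]][below]),
    rho_above = safe_cor(data[[v]][!below], data[[target_var]][!below]),
    n_below = sum(below), n_above = sum(!below)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
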