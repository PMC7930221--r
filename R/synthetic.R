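#' Random DAG over n nodes
#'
#' Draws a uniform topological order, then includes each forward arc
#' independently with probability `edge_prob`. Acyclicity holds by
#' construction.
#'
#' @param n number of nodes (positive integer).
#' @param edge_prob arc inclusion probability in \[0, 1\].
#' @param seed integer seed; every generator in this package takes an
#'   explicit seed and never touches global RNG state outside its own call.
#' @param nodes optional node names (default `V1..Vn`).
#' @return a `dag`.
#' @export
random_dag <- function(n, edge_prob, seed, nodes = paste0("V", seq_len(n))) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != as.integer(n))
    stop("n must be a positive integer")
  if (edge_prob < 0 || edge_prob > 1) stop("edge_prob must be in [0, 1]")
  n <- as.integer(n)
  stopifnot(length(nodes) == n)
  withr::local_seed(seed)
  ord <- sample(nodes)
  arcs <- NULL
  if (n >= 2L) {
    pairs <- utils::combn(n, 2L)
    keep <- stats::runif(ncol(pairs)) < edge_prob
    if (any(keep))
      arcs <- cbind(from = ord[pairs[1L, keep]], to = ord[pairs[2L, keep]])
  }
  dag(nodes, arcs)
}

# uniform draw from [lo, hi] minus the open dead zone (-dz, dz)
draw_coef <- function(k, lo, hi, dz) {
  if (lo == hi) {
    if (abs(lo) < dz) stop("degenerate coef_range lies inside the dead zone")
    return(rep(lo, k))
  }
  neg <- c(lo, min(hi, -dz))   # admissible negative piece
  pos <- c(max(lo, dz), hi)    # admissible positive piece
  len_neg <- max(0, neg[2L] - neg[1L])
  len_pos <- max(0, pos[2L] - pos[1L])
  if (len_neg + len_pos <= 0)
    stop("coef_range lies entirely inside the dead zone (-", dz, ", ", dz, ")")
  u <- stats::runif(k, 0, len_neg + len_pos)
  ifelse(u < len_neg, neg[1L] + u, pos[1L] + (u - len_neg))
}

#' Random linear-Gaussian parameters for a DAG
#'
#' Intercepts are fixed at 0 (structure learning and partial correlations are
#' location-invariant). Parent coefficients are uniform on `coef_range`
#' excluding a dead zone `(-dead_zone, dead_zone)` so no true arc is
#' vacuously weak; residual variances are uniform on `var_range`.
#'
#' @param structure a `dag`.
#' @param coef_range length-2 numeric interval for coefficients.
#' @param var_range strictly positive length-2 interval for residual
#'   variances.
#' @param seed integer seed.
#' @param dead_zone half-width of the excluded coefficient band (default
#'   0.1); raise it (e.g. 0.5) for strong-signal scenarios.
#' @return a `gbn`.
#' @export
random_parameters <- function(structure, coef_range = c(-1, 1),
                              var_range = c(0.5, 2), seed,
                              dead_zone = 0.1) {
  stopifnot(inherits(structure, "dag"), length(coef_range) == 2L,
            length(var_range) == 2L)
  if (any(var_range <= 0)) stop("var_range must be strictly positive")
  coef_range <- sort(coef_range)
  var_range <- sort(var_range)
  withr::local_seed(seed)
  params <- lapply(structure$nodes, function(v) {
    pa <- sort(parents(structure, v))
    co <- if (length(pa) > 0L)
      stats::setNames(draw_coef(length(pa), coef_range[1L], coef_range[2L],
                                dead_zone), pa)
    else stats::setNames(numeric(0), character(0))
    list(intercept = 0,
         coefficients = co,
         variance = stats::runif(1, var_range[1L], var_range[2L]))
  })
  names(params) <- structure$nodes
  gbn(structure, params)
}

#' Ancestral sampling from a Gaussian BN
#'
#' Nodes are visited in topological order; each is drawn from
#' Normal(b0 + b' parents, s2). Deterministic given the seed.
#'
#' @param bn a `gbn`.
#' @param N number of rows (>= 1).
#' @param seed integer seed.
#' @return data frame with N rows, columns in the structure's node order.
#' @export
sample_gbn <- function(bn, N, seed) {
  stopifnot(inherits(bn, "gbn"))
  if (N < 1) stop("N must be >= 1")
  N <- as.integer(N)
  nodes <- bn$structure$nodes
  ord <- topological_sort(bn$structure)
  withr::local_seed(seed)
  X <- matrix(0, N, length(nodes), dimnames = list(NULL, nodes))
  for (v in ord) {
    p <- bn$params[[v]]
    mu <- p$intercept
    if (length(p$coefficients) > 0L)
      mu <- mu + X[, names(p$coefficients), drop = FALSE] %*% p$coefficients
    X[, v] <- mu + stats::rnorm(N, 0, sqrt(p$variance))
  }
  as.data.frame(X)
}

#' Ground-truth scenario for arc-confidence experiments
#'
#' Builds a random strong-signal Gaussian BN over `n` variables (all true
#' coefficients at least `dead_zone` in magnitude) and samples `N`
#' observations from it. Every unordered variable pair is labelled
#' nonspurious (in the true skeleton) or spurious, so bootstrap confidence
#' estimates can be scored against ground truth.
#'
#' @param n number of variables (>= 3).
#' @param N sample size (>= 2); `N = 42` and `N = 21` mirror the
#'   human/mouse sample shapes of the motivating study.
#' @param seed integer seed.
#' @param edge_prob arc density of the true DAG (default 0.25).
#' @param dead_zone minimum coefficient magnitude (default 0.5, a strong
#'   signal relative to unit-order residual variances).
#' @return object of class `"gt_scenario"`: `true_bn`, `sample_size`,
#'   `seed`, `variable_names`, `data` (the sampled table), `nonspurious`
#'   and `spurious` (2-column matrices of unordered pairs).
#' @export
make_confidence_scenario <- function(n, N, seed, edge_prob = 0.25,
                                     dead_zone = 0.5) {
  if (n < 3) stop("n must be >= 3")
  if (N < 2) stop("N must be >= 2")
  g <- random_dag(n, edge_prob, seed = seed)
  bn <- random_parameters(g, coef_range = c(-1, 1), var_range = c(0.5, 1.5),
                          seed = seed + 1L, dead_zone = dead_zone)
  dat <- sample_gbn(bn, N, seed = seed + 2L)
  pairs <- t(utils::combn(sort(g$nodes), 2L))
  colnames(pairs) <- c("from", "to")
  skel <- unique(t(apply(g$arcs, 1L, sort)))
  in_skel <- if (nrow(g$arcs) == 0L) rep(FALSE, nrow(pairs)) else
    paste(pairs[, 1L], pairs[, 2L]) %in% paste(skel[, 1L], skel[, 2L])
  structure(list(true_bn = bn, sample_size = as.integer(N),
                 seed = as.integer(seed), variable_names = g$nodes,
                 data = dat,
                 nonspurious = pairs[in_skel, , drop = FALSE],
                 spurious = pairs[!in_skel, , drop = FALSE]),
            class = "gt_scenario")
}

#' Toy SWC fixtures with analytically known morphometrics
#'
#' In-memory neuron reconstructions used as geometric oracles:
#' \describe{
#'   \item{straight_branch}{soma plus a single unbranched basal path of three
#'     unit compartments along +Y: one branch, length 3, tortuosity 1,
#'     height 3, width 0, depth 0.}
#'   \item{right_angle_bifurcation}{basal stem of length 1 along +Y, then
#'     daughters ending along +X and +Y from the fork: remote bifurcation
#'     angle pi/2.}
#'   \item{symmetric_Y}{basal stem of length 2, two unit daughters at +/-45
#'     degrees from the stem axis: branch lengths 2, 1, 1 (mean 4/3, total
#'     4), one bifurcation at path distance 2, remote angle pi/2.}
#'   \item{two_arbor_cell}{a basal symmetric-Y arbor pointing down -Y
#'     (radius 0.2 everywhere) plus an apical arbor (radius 0.5): stem of
#'     length 2 along +Y, then daughters to (1, 3, 0) and (-1, 3, 0), so
#'     apical branch lengths are 2, sqrt(2), sqrt(2) (total 2 + 2 sqrt(2)),
#'     the apical bifurcation sits at path distance 2 and its remote angle
#'     is pi/2. Exercises the basal/apical split with every feature
#'     defined.}
#' }
#' All radii are 0.1 unless stated; coordinates are micrometers.
#'
#' @param case_name one of the fixture names above.
#' @return a `swc_neuron`.
#' @export
toy_swc <- function(case_name) {
  node <- function(id, type, x, y, z, r, parent)
    data.frame(id = id, type = type, x = x, y = y, z = z, radius = r,
               parent = parent)
  fx <- switch(case_name,
    straight_branch = rbind(
      node(1, 1, 0, 0, 0, 1.0, -1),
      node(2, 3, 0, 0, 0, 0.1, 1),
      node(3, 3, 0, 1, 0, 0.1, 2),
      node(4, 3, 0, 2, 0, 0.1, 3),
      node(5, 3, 0, 3, 0, 0.1, 4)),
    right_angle_bifurcation = rbind(
      node(1, 1, 0, 0, 0, 1.0, -1),
      node(2, 3, 0, 0, 0, 0.1, 1),
      node(3, 3, 0, 1, 0, 0.1, 2),
      node(4, 3, 1, 1, 0, 0.1, 3),
      node(5, 3, 0, 2, 0, 0.1, 3)),
    symmetric_Y = {
      s <- sqrt(2) / 2
      rbind(
        node(1, 1, 0, 0, 0, 1.0, -1),
        node(2, 3, 0, 0, 0, 0.1, 1),
        node(3, 3, 0, 1, 0, 0.1, 2),
        node(4, 3, 0, 2, 0, 0.1, 3),
        node(5, 3, s, 2 + s, 0, 0.1, 4),
        node(6, 3, -s, 2 + s, 0, 0.1, 4))
    },
    two_arbor_cell = {
      s <- sqrt(2) / 2
      rbind(
        node(1, 1, 0, 0, 0, 1.0, -1),
        node(2, 3, 0, 0, 0, 0.2, 1),
        node(3, 3, 0, -1, 0, 0.2, 2),
        node(4, 3, 0, -2, 0, 0.2, 3),
        node(5, 3, s, -2 - s, 0, 0.2, 4),
        node(6, 3, -s, -2 - s, 0, 0.2, 4),
        node(7, 4, 0, 0, 0, 0.5, 1),
        node(8, 4, 0, 1, 0, 0.5, 7),
        node(9, 4, 0, 2, 0, 0.5, 8),
        node(10, 4, 1, 3, 0, 0.5, 9),
        node(11, 4, -1, 3, 0, 0.5, 9))
    },
    stop("unknown toy SWC case: ", case_name))
  swc_neuron(fx)
}
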