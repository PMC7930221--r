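# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever the package result is under test.

# acyclicity via igraph (independent of topological_sort)
oracle_is_acyclic <- function(nodes, arcs) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(arcs), directed = TRUE,
    vertices = data.frame(name = nodes))
  igraph::is_dag(g)
}

# canonical v-structure keys of an adjacency matrix (A[p, c] = p -> c)
oracle_vstructures <- function(A) {
  nodes <- rownames(A)
  adj <- A | t(A)
  out <- character(0)
  for (z in nodes) {
    pa <- nodes[A[, z]]
    if (length(pa) < 2L) next
    for (i in seq_len(length(pa) - 1L)) for (j in (i + 1L):length(pa)) {
      if (!adj[pa[i], pa[j]]) {
        xy <- sort(c(pa[i], pa[j]))
        out <- c(out, paste(xy[1L], z, xy[2L]))
      }
    }
  }
  sort(out)
}

# brute-force CPDAG: enumerate every same-skeleton orientation, keep the
# acyclic ones with identical v-structures, and take the orientation union
oracle_cpdag <- function(g) {
  nodes <- g$nodes
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(g$arcs) > 0L) A[g$arcs] <- TRUE
  skel <- which((A | t(A)) & upper.tri(A), arr.ind = TRUE)
  m <- nrow(skel)
  target_v <- oracle_vstructures(A)
  members <- list()
  if (m == 0L) {
    members <- list(A)
  } else {
    for (mask in 0:(2^m - 1)) {
      B <- matrix(FALSE, n, n, dimnames = dimnames(A))
      for (k in seq_len(m)) {
        i <- skel[k, 1L]; j <- skel[k, 2L]
        if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0L) B[i, j] <- TRUE
        else B[j, i] <- TRUE
      }
      arcs <- which(B, arr.ind = TRUE)
      arcs <- cbind(nodes[arcs[, 1L]], nodes[arcs[, 2L]])
      if (!oracle_is_acyclic(nodes, arcs)) next
      if (!identical(oracle_vstructures(B), target_v)) next
      members[[length(members) + 1L]] <- B
    }
  }
  stopifnot(length(members) >= 1L)
  directed <- NULL
  undirected <- NULL
  for (k in seq_len(max(m, 0L))) {
    if (m == 0L) break
    i <- skel[k, 1L]; j <- skel[k, 2L]
    fwd <- vapply(members, function(B) B[i, j], logical(1))
    if (all(fwd)) directed <- rbind(directed, c(nodes[i], nodes[j]))
    else if (all(!fwd)) directed <- rbind(directed, c(nodes[j], nodes[i]))
    else undirected <- rbind(undirected,
                             sort(c(nodes[i], nodes[j])))
  }
  key <- function(mm, sep) {
    if (is.null(mm)) return(character(0))
    sort(paste(mm[, 1L], sep, mm[, 2L]))
  }
  list(directed = key(directed, "->"), undirected = key(undirected, "--"),
       n_members = length(members), members = members)
}

cpdag_keys <- function(cp) {
  list(directed = if (nrow(cp$directed) > 0L)
         sort(paste(cp$directed[, 1L], "->", cp$directed[, 2L])) else character(0),
       undirected = if (nrow(cp$undirected) > 0L)
         sort(paste(cp$undirected[, 1L], "--", cp$undirected[, 2L])) else character(0))
}

# partial correlation of the first two variables given the rest, from the
# population covariance via the Schur complement (the residual-regression
# identity), independent of the precision-matrix route
oracle_partial_cor <- function(sigma, i, j) {
  rest <- setdiff(seq_len(nrow(sigma)), c(i, j))
  s <- sigma[c(i, j), c(i, j)]
  if (length(rest) > 0L) {
    s <- s - sigma[c(i, j), rest, drop = FALSE] %*%
      solve(sigma[rest, rest, drop = FALSE],
            sigma[rest, c(i, j), drop = FALSE])
  }
  s[1L, 2L] / sqrt(s[1L, 1L] * s[2L, 2L])
}

# every DAG structure over `nodes`, as a list of arc matrices (test-local
# re-derivation; slower but independent of enumerate_dags internals)
oracle_all_dags <- function(nodes) {
  n <- length(nodes)
  pairs <- utils::combn(nodes, 2L)
  m <- ncol(pairs)
  out <- list()
  states <- rep(0L, m)
  repeat {
    arcs <- matrix(character(0), ncol = 2)
    for (k in seq_len(m)) {
      if (states[k] == 1L) arcs <- rbind(arcs, pairs[, k])
      if (states[k] == 2L) arcs <- rbind(arcs, rev(pairs[, k]))
    }
    if (oracle_is_acyclic(nodes, arcs)) out[[length(out) + 1L]] <- arcs
    k <- 1L
    while (k <= m) {
      states[k] <- states[k] + 1L
      if (states[k] < 3L) break
      states[k] <- 0L
      k <- k + 1L
    }
    if (k > m) break
  }
  out
}

# random positive-definite covariance with unit-order scale
random_pd_matrix <- function(n) {
  a <- matrix(stats::rnorm(n * n), n)
  crossprod(a) / n + diag(n) * 0.1
}

# random gbn helper used by several suites
random_gbn <- function(n, seed, edge_prob = 0.4, dead_zone = 0.1) {
  g <- random_dag(n, edge_prob, seed = seed)
  random_parameters(g, coef_range = c(-1, 1), var_range = c(0.5, 2),
                    seed = seed + 1000L, dead_zone = dead_zone)
}
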