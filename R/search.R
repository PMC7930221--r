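# Cached family scores: BIC is decomposable, so a move's delta only touches
# the families of the child (add/delete) or of both endpoints (reverse).
make_score_cache <- function(gram) {
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  function(node, pars) {
    key <- paste(node, paste(sort(pars), collapse = ","), sep = "|")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- family_bic(gram, node, sort(pars))
      cache[[key]] <- val
    }
    val
  }
}

# canonical unordered-pair keys for blacklist lookups
pair_keys <- function(pairs) {
  if (is.null(pairs) || NROW(pairs) == 0L) return(character(0))
  pairs <- normalize_arcs(pairs)
  paste(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
}

#' Score-based DAG learning by tabu search
#'
#' Local search over single-arc additions, deletions and reversals that
#' optimizes the decomposable BIC score, starting from the empty graph.
#' Score-degrading moves are allowed; moves that undo a recently applied
#' operator are tabu for `tabu_list_size` iterations (an otherwise-tabu move
#' is admitted if it beats the best score seen, the standard aspiration
#' criterion). The search stops after `max_nonimproving` consecutive
#' accepted moves without improving the best score, and the best structure
#' seen is returned.
#'
#' @param data data frame of numeric columns (the variables).
#' @param tabu_list_size number of recent undoing moves kept tabu
#'   (default 30).
#' @param max_nonimproving accepted non-improving moves tolerated before
#'   stopping (default 30); 0 gives plain greedy hill climbing.
#' @param blacklist unordered variable pairs (2-column matrix/data frame)
#'   excluded from the structure in both directions.
#' @param seed unused by the deterministic search (ties break
#'   lexicographically); kept for API symmetry with the bootstrap.
#' @param nodes variables to use (default: all columns of `data`).
#' @return the learned `dag`.
#' @export
tabu_search <- function(data, tabu_list_size = 30L, max_nonimproving = 30L,
                        blacklist = NULL, seed = NULL, nodes = NULL) {
  data <- as.data.frame(data)
  if (is.null(nodes)) nodes <- colnames(data)
  if (nrow(data) < 3L) stop("need at least 3 observations")
  stopifnot(tabu_list_size >= 0L, max_nonimproving >= 0L)
  gram <- gram_matrix(data[nodes])
  fam <- make_score_cache(gram)
  black <- pair_keys(blacklist)
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  pa <- stats::setNames(lapply(nodes, function(v) character(0)), nodes)
  node_score <- vapply(nodes, function(v) fam(v, character(0)), numeric(1))
  cur_score <- sum(node_score)
  best_score <- cur_score
  best_A <- A
  tabu <- character(0)
  nonimp <- 0L
  eps <- 1e-10
  max_iter <- 100L * n * n + 1000L
  move_key <- function(op, p, c) paste(op, p, c, sep = "|")
  for (iter in seq_len(max_iter)) {
    cand <- list()
    for (p in nodes) for (c in nodes) {
      if (p == c) next
      if (A[p, c]) {
        # delete p -> c
        d_del <- fam(c, setdiff(pa[[c]], p)) - node_score[c]
        cand[[length(cand) + 1L]] <- list(op = "delete", p = p, c = c,
                                          delta = d_del)
        # reverse p -> c (legal iff no other directed path p ~> c)
        A[p, c] <- FALSE
        ok <- !reachable(A, p, c)
        A[p, c] <- TRUE
        if (ok) {
          d_rev <- (fam(c, setdiff(pa[[c]], p)) - node_score[c]) +
                   (fam(p, c(pa[[p]], c)) - node_score[p])
          cand[[length(cand) + 1L]] <- list(op = "reverse", p = p, c = c,
                                            delta = d_rev)
        }
      } else if (!A[c, p]) {
        # add p -> c
        if (paste(min(p, c), max(p, c)) %in% black) next
        if (reachable(A, c, p)) next
        d_add <- fam(c, c(pa[[c]], p)) - node_score[c]
        cand[[length(cand) + 1L]] <- list(op = "add", p = p, c = c,
                                          delta = d_add)
      }
    }
    if (length(cand) == 0L) break
    # deterministic ordering: best delta, then op, child, parent
    deltas <- vapply(cand, `[[`, numeric(1), "delta")
    ops <- vapply(cand, `[[`, character(1), "op")
    ps <- vapply(cand, `[[`, character(1), "p")
    cs <- vapply(cand, `[[`, character(1), "c")
    keys <- vapply(cand, function(m) move_key(m$op, m$p, m$c), character(1))
    is_tabu <- keys %in% tabu
    aspired <- cur_score + deltas > best_score + eps
    admissible <- !is_tabu | aspired
    if (!any(admissible)) break
    ord <- order(-deltas, match(ops, c("add", "delete", "reverse")), cs, ps)
    ord <- ord[admissible[ord]]
    mv <- cand[[ord[1L]]]
    # apply
    if (mv$op == "add") {
      A[mv$p, mv$c] <- TRUE
      pa[[mv$c]] <- c(pa[[mv$c]], mv$p)
      node_score[mv$c] <- fam(mv$c, pa[[mv$c]])
      undo <- move_key("delete", mv$p, mv$c)
    } else if (mv$op == "delete") {
      A[mv$p, mv$c] <- FALSE
      pa[[mv$c]] <- setdiff(pa[[mv$c]], mv$p)
      node_score[mv$c] <- fam(mv$c, pa[[mv$c]])
      undo <- move_key("add", mv$p, mv$c)
    } else {
      A[mv$p, mv$c] <- FALSE
      A[mv$c, mv$p] <- TRUE
      pa[[mv$c]] <- setdiff(pa[[mv$c]], mv$p)
      pa[[mv$p]] <- c(pa[[mv$p]], mv$c)
      node_score[mv$c] <- fam(mv$c, pa[[mv$c]])
      node_score[mv$p] <- fam(mv$p, pa[[mv$p]])
      undo <- move_key("reverse", mv$c, mv$p)
    }
    cur_score <- sum(node_score)
    if (tabu_list_size > 0L) {
      tabu <- c(tabu, undo)
      if (length(tabu) > tabu_list_size)
        tabu <- tabu[(length(tabu) - tabu_list_size + 1L):length(tabu)]
    }
    if (cur_score > best_score + eps) {
      best_score <- cur_score
      best_A <- A
      nonimp <- 0L
    } else {
      nonimp <- nonimp + 1L
      if (nonimp > max_nonimproving) break
    }
  }
  dag_from_amat(best_A)
}

# all DAG adjacency structures over the given nodes, as arc matrices
enumerate_dags <- function(nodes, blacklist = NULL) {
  n <- length(nodes)
  if (n == 1L) return(list(normalize_arcs(NULL)))
  pairs <- utils::combn(nodes, 2L)
  black <- pair_keys(blacklist)
  keep <- !(paste(pairs[1L, ], pairs[2L, ]) %in% black)
  pairs <- pairs[, keep, drop = FALSE]
  m <- ncol(pairs)
  out <- list()
  states <- rep(0L, m)  # 0 absent, 1 forward, 2 backward
  repeat {
    arcs <- NULL
    for (k in seq_len(m)) {
      if (states[k] == 1L) arcs <- rbind(arcs, pairs[, k])
      if (states[k] == 2L) arcs <- rbind(arcs, rev(pairs[, k]))
    }
    g <- list(nodes = nodes, arcs = normalize_arcs(arcs))
    if (!is.null(topological_sort(g))) out[[length(out) + 1L]] <- g$arcs
    # increment base-3 counter
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

#' Globally BIC-optimal DAG by enumeration
#'
#' Test oracle: enumerates every DAG over the columns of `data` (refusing
#' more than 5 variables) and returns the highest-scoring one. Ties break
#' toward fewer arcs, then the lexicographically smallest arc list.
#'
#' @inheritParams tabu_search
#' @export
exhaustive_search <- function(data, blacklist = NULL, nodes = NULL) {
  data <- as.data.frame(data)
  if (is.null(nodes)) nodes <- colnames(data)
  if (length(nodes) > 5L)
    stop("exhaustive enumeration is limited to 5 variables")
  gram <- gram_matrix(data[nodes])
  fam <- make_score_cache(gram)
  score_arcs <- function(arcs) {
    sum(vapply(nodes, function(v)
      fam(v, arcs[arcs[, 2L] == v, 1L]), numeric(1)))
  }
  best <- NULL
  best_score <- -Inf
  best_key <- ""
  for (arcs in enumerate_dags(nodes, blacklist)) {
    s <- score_arcs(arcs)
    key <- sprintf("%04d %s", nrow(arcs),
                   paste(sort(paste(arcs[, 1L], arcs[, 2L])), collapse = ";"))
    if (s > best_score + 1e-10 ||
        (abs(s - best_score) <= 1e-10 && key < best_key)) {
      best <- arcs
      best_score <- s
      best_key <- key
    }
  }
  dag(nodes, best)
}
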