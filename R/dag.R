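#' Directed acyclic graph over named variables
#'
#' Constructs a validated DAG used as the structure of a Gaussian Bayesian
#' network. Arcs are ordered (parent, child) pairs of variable names.
#'
#' @param nodes character vector of distinct variable names.
#' @param arcs two-column character matrix or data frame (from, to); may have
#'   zero rows for the empty graph.
#' @return an object of class `"dag"` with elements `nodes` and `arcs`.
#' @export
dag <- function(nodes, arcs = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L) stop("a DAG needs at least one node")
  if (anyDuplicated(nodes)) stop("node names must be unique")
  arcs <- normalize_arcs(arcs)
  if (nrow(arcs) > 0L) {
    unknown <- setdiff(c(arcs[, 1L], arcs[, 2L]), nodes)
    if (length(unknown) > 0L)
      stop("arcs reference unknown variables: ", paste(unknown, collapse = ", "))
    if (any(arcs[, 1L] == arcs[, 2L])) stop("self-loops are not allowed")
    if (anyDuplicated(paste(arcs[, 1L], arcs[, 2L]))) stop("duplicate arcs")
  }
  g <- structure(list(nodes = nodes, arcs = arcs), class = "dag")
  if (is.null(topological_sort(g))) stop("arc set contains a cycle")
  g
}

# coerce arc input to a canonical 2-column character matrix
normalize_arcs <- function(arcs) {
  if (is.null(arcs) || (is.data.frame(arcs) && nrow(arcs) == 0L)) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  }
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs)
  if (is.character(arcs) && is.null(dim(arcs)) && length(arcs) == 2L)
    arcs <- matrix(arcs, ncol = 2L)
  if (!is.matrix(arcs) || ncol(arcs) != 2L)
    stop("arcs must be a two-column (from, to) matrix")
  storage.mode(arcs) <- "character"
  colnames(arcs) <- c("from", "to")
  rownames(arcs) <- NULL
  arcs
}

#' @export
print.dag <- function(x, ...) {
  cat("DAG with", length(x$nodes), "nodes and", nrow(x$arcs), "arcs\n")
  if (nrow(x$arcs) > 0L)
    cat(paste0("  ", x$arcs[, 1L], " -> ", x$arcs[, 2L]), sep = "\n")
  invisible(x)
}

#' Adjacency matrix of a DAG
#'
#' @param g a `dag`.
#' @return logical matrix `A` with `A[p, c]` TRUE iff arc p -> c exists.
#' @export
amat <- function(g) {
  stopifnot(inherits(g, "dag"))
  n <- length(g$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$arcs) > 0L) A[g$arcs] <- TRUE
  A
}

#' @rdname amat
#' @param A logical adjacency matrix with dimnames.
#' @export
dag_from_amat <- function(A) {
  idx <- which(A, arr.ind = TRUE)
  arcs <- cbind(from = rownames(A)[idx[, 1L]], to = colnames(A)[idx[, 2L]])
  dag(rownames(A), arcs)
}

#' Parents and children of a node
#' @param g a `dag`.
#' @param node variable name.
#' @export
parents <- function(g, node) {
  stopifnot(node %in% g$nodes)
  g$arcs[g$arcs[, 2L] == node, 1L]
}

#' @rdname parents
#' @export
children <- function(g, node) {
  stopifnot(node %in% g$nodes)
  g$arcs[g$arcs[, 1L] == node, 2L]
}

#' Topological order of a DAG
#'
#' Kahn's algorithm; ties resolved by node-name order for determinism.
#'
#' @param g a `dag` (or a list with `nodes`/`arcs` not yet validated).
#' @return character vector of nodes in topological order, or `NULL` if the
#'   arc set contains a cycle.
#' @export
topological_sort <- function(g) {
  nodes <- g$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(g$arcs) > 0L) {
    tb <- table(g$arcs[, 2L])
    indeg[names(tb)] <- as.integer(tb)
  }
  order <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  indeg <- indeg[indeg > 0L]
  while (length(avail) > 0L) {
    v <- avail[1L]
    avail <- avail[-1L]
    order <- c(order, v)
    ch <- g$arcs[g$arcs[, 1L] == v, 2L]
    for (c in ch) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) {
        avail <- sort(c(avail, c))
        indeg <- indeg[names(indeg) != c]
      }
    }
  }
  if (length(order) != length(nodes)) NULL else order
}

# TRUE iff `to` is reachable from `from` following directed arcs of A
reachable <- function(A, from, to) {
  if (from == to) return(TRUE)
  n <- nrow(A)
  seen <- logical(n)
  names(seen) <- rownames(A)
  stack <- from
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    nxt <- colnames(A)[A[v, ]]
    if (to %in% nxt) return(TRUE)
    stack <- c(stack, nxt[!seen[nxt]])
  }
  FALSE
}

#' Markov blanket of a node
#'
#' Parents, children and co-parents (other parents of the node's children).
#'
#' @param g a `dag`.
#' @param node variable name.
#' @return character vector (possibly empty), never containing `node`.
#' @export
markov_blanket <- function(g, node) {
  if (!node %in% g$nodes) stop("unknown node: ", node)
  ch <- children(g, node)
  spouses <- unlist(lapply(ch, function(c) parents(g, c)), use.names = FALSE)
  sort(setdiff(unique(c(parents(g, node), ch, spouses)), node))
}

#' Convert a DAG to its CPDAG
#'
#' Computes the completed partially directed acyclic graph representing the
#' Markov equivalence class of `g`: the skeleton is kept, v-structure arcs
#' stay directed, and the orientation-propagation (Meek) rules are applied to
#' a fixpoint; every remaining edge is undirected.
#'
#' @param g a `dag`.
#' @return object of class `"cpdag"`: `nodes`, `directed` (2-col matrix),
#'   `undirected` (2-col matrix, each pair stored once with `from < to`).
#' @export
dag_to_cpdag <- function(g) {
  stopifnot(inherits(g, "dag"))
  A <- amat(g)
  nodes <- g$nodes
  adj <- A | t(A)                        # skeleton
  D <- matrix(FALSE, nrow(A), ncol(A), dimnames = dimnames(A)) # compelled
  # v-structures: x -> z <- y with x, y non-adjacent
  for (z in nodes) {
    pa <- nodes[A[, z]]
    if (length(pa) < 2L) next
    for (i in seq_len(length(pa) - 1L)) for (j in (i + 1L):length(pa)) {
      if (!adj[pa[i], pa[j]]) {
        D[pa[i], z] <- TRUE
        D[pa[j], z] <- TRUE
      }
    }
  }
  U <- adj & !(D | t(D))                 # undirected (symmetric)
  # Meek rules until fixpoint; orienting a-b to a->b moves it from U to D
  repeat {
    changed <- FALSE
    und <- which(U, arr.ind = TRUE)   # both orientations of each edge
    for (k in seq_len(nrow(und))) {
      a <- nodes[und[k, 1L]]; b <- nodes[und[k, 2L]]
      if (!U[a, b]) next
      orient <- FALSE
      # R1: c -> a, c and b non-adjacent  =>  a -> b
      for (c in nodes[D[, a]]) if (!adj[c, b]) { orient <- TRUE; break }
      # R2: a -> c -> b exists  =>  a -> b
      if (!orient) {
        for (c in nodes[D[a, ]]) if (D[c, b]) { orient <- TRUE; break }
      }
      # R3: a - c -> b and a - d -> b with c, d non-adjacent  =>  a -> b
      if (!orient) {
        cand <- nodes[U[a, ] & D[, b]]
        if (length(cand) >= 2L) {
          for (i in seq_len(length(cand) - 1L)) {
            for (j in (i + 1L):length(cand)) {
              if (!adj[cand[i], cand[j]]) { orient <- TRUE; break }
            }
            if (orient) break
          }
        }
      }
      if (orient) {
        D[a, b] <- TRUE
        U[a, b] <- U[b, a] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  di <- which(D, arr.ind = TRUE)
  directed <- cbind(from = nodes[di[, 1L]], to = nodes[di[, 2L]])
  ui <- which(U & upper.tri(U), arr.ind = TRUE)
  undirected <- cbind(from = nodes[pmin(ui[, 1L], ui[, 2L])],
                      to = nodes[pmax(ui[, 1L], ui[, 2L])])
  if (nrow(directed) > 0L)
    directed <- directed[order(directed[, 1L], directed[, 2L]), , drop = FALSE]
  if (nrow(undirected) > 0L)
    undirected <- undirected[order(undirected[, 1L], undirected[, 2L]), , drop = FALSE]
  structure(list(nodes = nodes, directed = directed, undirected = undirected),
            class = "cpdag")
}

#' @export
print.cpdag <- function(x, ...) {
  cat("CPDAG with", length(x$nodes), "nodes,", nrow(x$directed),
      "directed and", nrow(x$undirected), "undirected edges\n")
  if (nrow(x$directed) > 0L)
    cat(paste0("  ", x$directed[, 1L], " -> ", x$directed[, 2L]), sep = "\n")
  if (nrow(x$undirected) > 0L)
    cat(paste0("  ", x$undirected[, 1L], " -- ", x$undirected[, 2L]), sep = "\n")
  invisible(x)
}

#' Test two CPDAGs for equality
#' @param a,b `cpdag` objects over the same variable set.
#' @export
cpdag_equal <- function(a, b) {
  if (!setequal(a$nodes, b$nodes)) return(FALSE)
  key <- function(m) sort(paste(m[, 1L], m[, 2L]))
  identical(key(a$directed), key(b$directed)) &&
    identical(key(a$undirected), key(b$undirected))
}

#' Convert a DAG to an igraph object
#' @param g a `dag`.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "dag"))
  igraph::graph_from_data_frame(as.data.frame(g$arcs), directed = TRUE,
                                vertices = data.frame(name = g$nodes))
}

#' Write a DAG as GraphML, DOT, or an arc-list CSV
#'
#' @param g a `dag`.
#' @param path output file.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_dot <- function(g, path) {
  lines <- c("digraph G {",
             paste0("  \"", g$nodes, "\";"),
             if (nrow(g$arcs) > 0L)
               paste0("  \"", g$arcs[, 1L], "\" -> \"", g$arcs[, 2L], "\";"),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_arcs_csv <- function(g, path) {
  utils::write.csv(as.data.frame(g$arcs), path, row.names = FALSE)
  invisible(path)
}
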