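#' Bootstrap replicate networks
#'
#' Draws `B` nonparametric bootstrap resamples (size N, with replacement)
#' and learns a structure on each with [tabu_search()] (no blacklist).
#' Standardization is computed once on the original sample and applied
#' before resampling, so replicates stay comparable. A degenerate resample
#' (any constant column, possible at small N) is rejected and redrawn from
#' the replicate's own RNG stream. Replicate seeds are derived
#' deterministically from the master seed.
#'
#' @param data data frame of numeric columns.
#' @param B number of replicates (>= 1).
#' @param seed master integer seed.
#' @param standardize z-score the data first (default TRUE).
#' @param ... passed to [tabu_search()] (tabu settings).
#' @return list of `B` `dag`s, with attribute `"seeds"`.
#' @export
bootstrap_networks <- function(data, B, seed, standardize = TRUE, ...) {
  if (B < 1) stop("B must be >= 1")
  data <- as.data.frame(data)
  if (standardize) data <- standardize_table(data)
  N <- nrow(data)
  rep_seeds <- withr::with_seed(seed,
    sample.int(2147483646L, as.integer(B)))
  nets <- vector("list", B)
  for (b in seq_len(B)) {
    boot <- withr::with_seed(rep_seeds[b], {
      repeat {
        idx <- sample.int(N, N, replace = TRUE)
        d <- data[idx, , drop = FALSE]
        sds <- vapply(d, stats::sd, numeric(1))
        if (all(sds > 0)) break
        message("replicate ", b, ": degenerate resample (constant column), redrawing")
      }
      d
    })
    nets[[b]] <- tabu_search(boot, ...)
  }
  attr(nets, "seeds") <- rep_seeds
  nets
}

#' Arc confidence from replicate structures
#'
#' The confidence in the directed arc X -> Y is the fraction of replicate
#' networks containing it.
#'
#' @param structures non-empty list of `dag`s over a common variable set.
#' @return object of class `"arc_confidence"`: `nodes`, `p` (matrix of
#'   directed-arc frequencies), `B`.
#' @export
arc_confidence <- function(structures) {
  if (length(structures) < 1L) stop("need at least one structure")
  nodes <- structures[[1L]]$nodes
  for (g in structures)
    if (!setequal(g$nodes, nodes))
      stop("structures have inconsistent variable sets")
  counts <- matrix(0, length(nodes), length(nodes),
                   dimnames = list(nodes, nodes))
  for (g in structures)
    if (nrow(g$arcs) > 0L) counts[g$arcs] <- counts[g$arcs] + 1
  structure(list(nodes = nodes, p = counts / length(structures),
                 B = length(structures)),
            class = "arc_confidence")
}

#' Combined (direction-agnostic) confidence of a link
#'
#' p(X -> Y) + p(X <- Y) for each unordered pair, since arc directions are
#' rarely established with confidence at small N.
#'
#' @param conf an `arc_confidence`.
#' @return symmetric matrix of combined confidences (diagonal 0).
#' @export
combined_confidence <- function(conf) {
  stopifnot(inherits(conf, "arc_confidence"))
  conf$p + t(conf$p)
}

#' Blacklist of low-confidence links
#'
#' An unordered pair \{X, Y\} is deemed spurious, and blacklisted for the
#' definitive structure learning, iff p(X -> Y) + p(X <- Y) <= t
#' (inclusive).
#'
#' @param conf an `arc_confidence`.
#' @param t threshold in \[0, 1\] (the motivating study used 0.7).
#' @return 2-column character matrix of unordered pairs (from < to).
#' @export
build_blacklist <- function(conf, t) {
  stopifnot(inherits(conf, "arc_confidence"), t >= 0, t <= 1)
  comb <- combined_confidence(conf)
  nodes <- conf$nodes
  out <- NULL
  if (length(nodes) >= 2L) {
    pairs <- utils::combn(sort(nodes), 2L)
    for (k in seq_len(ncol(pairs))) {
      if (comb[pairs[1L, k], pairs[2L, k]] <= t)
        out <- rbind(out, c(pairs[1L, k], pairs[2L, k]))
    }
  }
  normalize_arcs(out)
}

#' Export arc confidences as a table
#'
#' @param conf an `arc_confidence`.
#' @param t threshold used to flag blacklisted pairs (default 0.7).
#' @return data frame: from, to, confidence, combined_confidence,
#'   blacklisted.
#' @export
arc_confidence_table <- function(conf, t = 0.7) {
  comb <- combined_confidence(conf)
  nodes <- conf$nodes
  grid <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, , drop = FALSE]
  grid <- grid[order(grid$from, grid$to), , drop = FALSE]
  grid$confidence <- conf$p[cbind(grid$from, grid$to)]
  grid$combined_confidence <- comb[cbind(grid$from, grid$to)]
  grid$blacklisted <- grid$combined_confidence <= t
  rownames(grid) <- NULL
  grid
}

#' Bootstrap confidence of nonspurious vs spurious arcs
#'
#' Runs the bootstrap on a ground-truth scenario and summarizes the
#' combined link confidences separately for nonspurious pairs (in the true
#' skeleton) and spurious pairs (all others). With a strong signal the
#' nonspurious distribution should stochastically dominate the spurious
#' one; at mouse-scale N the classes are expected to overlap, which is the
#' motivation for a conservative threshold such as t = 0.7.
#'
#' @param scenario a `gt_scenario` from [make_confidence_scenario()].
#' @param B bootstrap replicates.
#' @param ... passed to [bootstrap_networks()].
#' @return list with per-class summaries (`min`, `median`, `q3`, `max`,
#'   `n`), the per-pair confidences, and the scenario's labels.
#' @export
confidence_separation_experiment <- function(scenario, B, ...) {
  stopifnot(inherits(scenario, "gt_scenario"))
  nets <- bootstrap_networks(scenario$data, B = B, seed = scenario$seed + 3L,
                             ...)
  comb <- combined_confidence(arc_confidence(nets))
  take <- function(pairs) {
    if (nrow(pairs) == 0L) return(numeric(0))
    comb[pairs]
  }
  summarize <- function(x) {
    if (length(x) == 0L)
      return(list(min = NA_real_, median = NA_real_, q3 = NA_real_,
                  max = NA_real_, n = 0L, empty = TRUE))
    list(min = min(x), median = stats::median(x),
         q3 = unname(stats::quantile(x, 0.75)), max = max(x),
         n = length(x), empty = FALSE)
  }
  ns <- take(scenario$nonspurious)
  sp <- take(scenario$spurious)
  list(nonspurious = summarize(ns), spurious = summarize(sp),
       confidences = list(nonspurious = ns, spurious = sp))
}
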