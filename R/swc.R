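#' Neuron reconstruction in SWC form
#'
#' Validates a node table against the SWC invariants: unique 1-based ids,
#' every non-root parent id refers to a node appearing earlier in the file
#' (which also rules out cycles), type codes per the SWC convention
#' (1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite).
#'
#' @param nodes data frame with columns id, type, x, y, z, radius, parent.
#' @return object of class `"swc_neuron"` (the validated data frame).
#' @export
swc_neuron <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% colnames(nodes)))
    stop("SWC table must have columns: ", paste(need, collapse = ", "))
  nodes <- as.data.frame(nodes)[need]
  if (nrow(nodes) < 1L) stop("empty SWC table")
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup) > 0L)
    stop("duplicate SWC id(s): ", paste(unique(dup), collapse = ", "))
  for (i in seq_len(nrow(nodes))) {
    p <- nodes$parent[i]
    if (p == -1) next
    j <- match(p, nodes$id)
    if (is.na(j))
      stop("line ", i, ": parent id ", p, " does not exist")
    if (j >= i)
      stop("line ", i, ": parent id ", p,
           " must appear earlier in the file")
  }
  if (!any(nodes$parent == -1)) stop("no root node (parent = -1) found")
  rownames(nodes) <- NULL
  class(nodes) <- c("swc_neuron", "data.frame")
  nodes
}

#' Read / write SWC files
#'
#' Standard 7-column whitespace-separated SWC text; `#` comment lines are
#' ignored.
#'
#' @param path file path.
#' @return [read_swc()] returns a validated `swc_neuron`.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  swc_neuron(tab)
}

#' @rdname read_swc
#' @param x a `swc_neuron`.
#' @export
write_swc <- function(x, path) {
  stopifnot(inherits(x, "swc_neuron"))
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   x$id, x$type, x$x, x$y, x$z, x$radius, x$parent)
  writeLines(c("# id type x y z radius parent", lines), path)
  invisible(path)
}

# SWC type codes for the two dendritic arbor classes
arbor_type_code <- function(arbor_class) {
  switch(match.arg(arbor_class, c("basal", "apical")), basal = 3L, apical = 4L)
}

# internal arbor view: node rows of the class, index maps, children lists;
# insertion nodes are arbor nodes whose parent is outside the arbor (soma
# compartments are excluded from all branch geometry).
arbor_view <- function(recon, arbor_class) {
  code <- arbor_type_code(arbor_class)
  in_arbor <- recon$type == code
  ids <- recon$id[in_arbor]
  if (length(ids) == 0L) return(NULL)
  sub <- recon[in_arbor, , drop = FALSE]
  idx <- stats::setNames(seq_len(nrow(sub)), sub$id)
  kids <- vector("list", nrow(sub))
  roots <- integer(0)
  for (i in seq_len(nrow(sub))) {
    p <- sub$parent[i]
    if (p %in% ids) {
      j <- idx[[as.character(p)]]
      kids[[j]] <- c(kids[[j]], i)
    } else {
      roots <- c(roots, i)
    }
  }
  list(nodes = sub, children = kids, roots = roots, idx = idx)
}

seg_len <- function(nodes, i, j) {
  sqrt((nodes$x[i] - nodes$x[j])^2 + (nodes$y[i] - nodes$y[j])^2 +
       (nodes$z[i] - nodes$z[j])^2)
}

#' Decompose an arbor into branches
#'
#' A branch is the maximal path between consecutive topological events
#' (arbor insertion points, bifurcations, terminals). Branches partition the
#' arbor's compartments; the compartment connecting the insertion node to
#' the soma is not part of the arbor.
#'
#' @param recon a `swc_neuron`.
#' @param arbor_class `"basal"` or `"apical"`.
#' @return list of branches, each a list with `path` (row indices within the
#'   arbor), `node_ids`, `length`, `chord`, `diameter` (compartment-length-
#'   weighted mean of 2 x radius), and `ends_in_bifurcation`; empty list if
#'   the arbor class is absent.
#' @export
extract_branches <- function(recon, arbor_class) {
  stopifnot(inherits(recon, "swc_neuron"))
  av <- arbor_view(recon, arbor_class)
  if (is.null(av)) return(list())
  nodes <- av$nodes
  nkids <- lengths(av$children)
  # event nodes: insertion roots and bifurcations; one branch per child of
  # an event node, running down to the next event (bifurcation or terminal)
  events <- unique(c(av$roots, which(nkids >= 2L)))
  branches <- list()
  for (v in events) for (first in av$children[[v]]) {
    path <- c(v, first)
    cur <- first
    while (nkids[cur] == 1L) {
      cur <- av$children[[cur]][1L]
      path <- c(path, cur)
    }
    lens <- vapply(seq_len(length(path) - 1L), function(k)
      seg_len(nodes, path[k], path[k + 1L]), numeric(1))
    diam <- nodes$radius[path[-1L]] + nodes$radius[path[-length(path)]]
    total <- sum(lens)
    branches[[length(branches) + 1L]] <- list(
      path = path,
      node_ids = nodes$id[path],
      length = total,
      chord = seg_len(nodes, path[1L], path[length(path)]),
      diameter = if (total > 0) sum(lens * diam) / total else mean(diam),
      ends_in_bifurcation = nkids[path[length(path)]] >= 2L)
  }
  branches
}

# row indices (within the arbor) of bifurcation nodes
bifurcation_indices <- function(av) which(lengths(av$children) >= 2L)

#' Mean branch length of an arbor
#'
#' Average over branches of the per-branch sum of compartment lengths. The
#' alternative literal bifurcation-point weighting (average over branches
#' that terminate in a bifurcation) is available via `weighting`.
#'
#' @param branches list from [extract_branches()].
#' @param weighting `"branches"` (default) or `"bifurcations"`.
#' @return micrometers, or `NA_real_` for an empty arbor.
#' @export
mean_branch_length <- function(branches, weighting = c("branches", "bifurcations")) {
  weighting <- match.arg(weighting)
  if (length(branches) == 0L) return(NA_real_)
  lens <- vapply(branches, `[[`, numeric(1), "length")
  if (weighting == "bifurcations") {
    keep <- vapply(branches, `[[`, logical(1), "ends_in_bifurcation")
    if (!any(keep)) return(NA_real_)
    lens <- lens[keep]
  }
  mean(lens)
}

#' Mean tortuosity of an arbor
#'
#' Per-branch geodesic length over endpoint chord length, averaged over
#' branches; each term is at least 1.
#'
#' @param branches list from [extract_branches()].
#' @return dimensionless, or `NA_real_` for an empty arbor.
#' @export
mean_tortuosity <- function(branches) {
  if (length(branches) == 0L) return(NA_real_)
  chords <- vapply(branches, `[[`, numeric(1), "chord")
  if (any(chords <= 0)) stop("malformed branch: coincident endpoints")
  mean(vapply(branches, `[[`, numeric(1), "length") / chords)
}

#' Total dendritic length and mean branch diameter of an arbor
#'
#' `total_length` sums branch lengths (equivalently, all compartment lengths
#' of the arbor). `mean_diameter` averages over branches the per-branch
#' compartment-length-weighted mean diameter (2 x radius, endpoints
#' averaged per compartment).
#'
#' @param branches list from [extract_branches()].
#' @return micrometers, or `NA_real_` for an empty arbor.
#' @export
total_length <- function(branches) {
  if (length(branches) == 0L) return(NA_real_)
  sum(vapply(branches, `[[`, numeric(1), "length"))
}

#' @rdname total_length
#' @export
mean_diameter <- function(branches) {
  if (length(branches) == 0L) return(NA_real_)
  mean(vapply(branches, `[[`, numeric(1), "diameter"))
}

#' Mean path distance from insertion to bifurcations
#'
#' For each bifurcation node, the along-tree sum of compartment lengths from
#' the arbor's insertion point up to the bifurcation; averaged over
#' bifurcations.
#'
#' @param recon a `swc_neuron`.
#' @param arbor_class `"basal"` or `"apical"`.
#' @return micrometers, or `NA_real_` if the arbor has no bifurcation.
#' @export
mean_path_distance <- function(recon, arbor_class) {
  av <- arbor_view(recon, arbor_class)
  if (is.null(av)) return(NA_real_)
  bif <- bifurcation_indices(av)
  if (length(bif) == 0L) return(NA_real_)
  # accumulate path distance from each insertion root down the arbor
  dist <- rep(NA_real_, nrow(av$nodes))
  for (r in av$roots) {
    dist[r] <- 0
    stack <- r
    while (length(stack) > 0L) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (c in av$children[[v]]) {
        dist[c] <- dist[v] + seg_len(av$nodes, v, c)
        stack <- c(stack, c)
      }
    }
  }
  mean(dist[bif])
}

#' Mean remote bifurcation angle
#'
#' At each bifurcation, the planar angle between the vectors from the fork
#' point to the end nodes of the daughter branches; multifurcations
#' contribute the mean over all daughter pairs. Averaged over bifurcations.
#'
#' @inheritParams mean_path_distance
#' @return radians in (0, pi\], or `NA_real_` without bifurcations.
#' @export
mean_remote_bifurcation_angle <- function(recon, arbor_class) {
  av <- arbor_view(recon, arbor_class)
  if (is.null(av)) return(NA_real_)
  branches <- extract_branches(recon, arbor_class)
  if (length(branches) == 0L) return(NA_real_)
  starts <- vapply(branches, function(b) b$path[1L], integer(1))
  tips <- vapply(branches, function(b) b$path[length(b$path)], integer(1))
  bif <- bifurcation_indices(av)
  if (length(bif) == 0L) return(NA_real_)
  angles <- vapply(bif, function(v) {
    dtips <- tips[starts == v]
    vecs <- lapply(dtips, function(tp) c(av$nodes$x[tp] - av$nodes$x[v],
                                         av$nodes$y[tp] - av$nodes$y[v],
                                         av$nodes$z[tp] - av$nodes$z[v]))
    norms <- vapply(vecs, function(u) sqrt(sum(u^2)), numeric(1))
    if (any(norms == 0)) stop("zero-length daughter vector at bifurcation")
    pairs <- utils::combn(length(vecs), 2L)
    mean(vapply(seq_len(ncol(pairs)), function(k) {
      u <- vecs[[pairs[1L, k]]]; w <- vecs[[pairs[2L, k]]]
      acos(min(1, max(-1, sum(u * w) / (norms[pairs[1L, k]] * norms[pairs[2L, k]]))))
    }, numeric(1)))
  }, numeric(1))
  mean(angles)
}

#' Bounding-box extents of an arbor
#'
#' Max minus min of the arbor nodes' coordinates per axis: height (Y),
#' width (X), depth (Z). Extents are reconstruction-frame (not
#' rotation-invariant).
#'
#' @inheritParams mean_path_distance
#' @return named numeric (height, width, depth), or all `NA` if absent.
#' @export
arbor_extent <- function(recon, arbor_class) {
  av <- arbor_view(recon, arbor_class)
  if (is.null(av))
    return(c(height = NA_real_, width = NA_real_, depth = NA_real_))
  c(height = diff(range(av$nodes$y)),
    width = diff(range(av$nodes$x)),
    depth = diff(range(av$nodes$z)))
}

#' Morphometric feature vector of a reconstruction
#'
#' Computes the nine per-arbor features (distance, length, tortuosity,
#' angle, diameter, height, width, depth, total_length) separately for the
#' basal and apical dendrites, the apical set prefixed `a.`, and appends the
#' externally supplied normalized cortical depth (`rel_depth`, 0 at the pia,
#' 1 at the white matter). Features undefined for a cell (absent arbor, no
#' bifurcation) are `NA`.
#'
#' @param recon a `swc_neuron` with at least one dendritic node.
#' @param rel_depth soma depth normalized to \[0, 1\]; passed through.
#' @return one-row data frame with 19 columns.
#' @export
compute_features <- function(recon, rel_depth = NA_real_) {
  stopifnot(inherits(recon, "swc_neuron"))
  if (!any(recon$type %in% c(3L, 4L)))
    stop("reconstruction has no dendritic nodes")
  one_class <- function(cl) {
    br <- extract_branches(recon, cl)
    ext <- arbor_extent(recon, cl)
    c(distance = mean_path_distance(recon, cl),
      length = mean_branch_length(br),
      tortuosity = mean_tortuosity(br),
      angle = mean_remote_bifurcation_angle(recon, cl),
      diameter = mean_diameter(br),
      ext,
      total_length = total_length(br))
  }
  basal <- one_class("basal")
  apical <- one_class("apical")
  names(apical) <- paste0("a.", names(apical))
  out <- as.data.frame(as.list(c(basal, apical)), check.names = FALSE)
  out$rel_depth <- rel_depth
  out
}

#' Build a feature table from a directory of SWC files
#'
#' Joins per-cell morphometrics with a metadata table (columns `cell_id`,
#' `species`, `rel_depth`; SWC files named `<cell_id>.swc`). Cells with any
#' missing analyzed feature are dropped with a warning.
#'
#' @param swc_dir directory of SWC files.
#' @param metadata data frame or CSV path with cell_id, species, rel_depth.
#' @param drop_incomplete drop cells with undefined features (default TRUE).
#' @return data frame: cell_id, species, then the 19 feature columns.
#' @export
swc_feature_table <- function(swc_dir, metadata, drop_incomplete = TRUE) {
  if (is.character(metadata)) metadata <- utils::read.csv(metadata)
  need <- c("cell_id", "species", "rel_depth")
  stopifnot(all(need %in% colnames(metadata)))
  if (anyDuplicated(metadata$cell_id)) stop("duplicate cell_id in metadata")
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    f <- file.path(swc_dir, paste0(metadata$cell_id[i], ".swc"))
    feats <- compute_features(read_swc(f), metadata$rel_depth[i])
    cbind(data.frame(cell_id = metadata$cell_id[i],
                     species = metadata$species[i]), feats)
  })
  tab <- do.call(rbind, rows)
  if (drop_incomplete) {
    bad <- !stats::complete.cases(tab)
    if (any(bad)) {
      warning("dropping ", sum(bad), " cell(s) with undefined features: ",
              paste(tab$cell_id[bad], collapse = ", "))
      tab <- tab[!bad, , drop = FALSE]
    }
  }
  rownames(tab) <- NULL
  tab
}
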