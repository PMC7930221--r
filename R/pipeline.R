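#' Load a per-cell feature table
#'
#' Reads a CSV (rows = cells, columns = named continuous variables),
#' optionally joins a metadata CSV by `cell_id`, restricts to a variable
#' subset, drops rows with missing subset values (logged), and attaches a
#' group label.
#'
#' @param path CSV path with a header row.
#' @param subset character vector of columns to keep (default: all numeric
#'   columns).
#' @param metadata_path optional CSV with `cell_id` plus extra columns
#'   (e.g. `rel_depth`) joined by `cell_id`.
#' @param group optional group label, stored as attribute `"group"`.
#' @return data frame of numeric columns in `subset` order.
#' @export
load_feature_table <- function(path, subset = NULL, metadata_path = NULL,
                               group = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if ("cell_id" %in% colnames(tab) && anyDuplicated(tab$cell_id))
    stop("duplicate cell_id rows in ", path)
  if (!is.null(metadata_path)) {
    meta <- utils::read.csv(metadata_path, check.names = FALSE)
    if (!"cell_id" %in% colnames(meta)) stop("metadata lacks cell_id")
    if (anyDuplicated(meta$cell_id)) stop("duplicate cell_id in metadata")
    tab <- merge(tab, meta, by = "cell_id", sort = FALSE)
  }
  if (is.null(subset))
    subset <- colnames(tab)[vapply(tab, is.numeric, logical(1))]
  missing_cols <- setdiff(subset, colnames(tab))
  if (length(missing_cols) > 0L)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  for (v in subset) {
    if (!is.numeric(tab[[v]]))
      stop("non-numeric values in column ", v)
  }
  out <- tab[, subset, drop = FALSE]
  keep <- stats::complete.cases(out)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " row(s) with missing values")
    out <- out[keep, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("no complete rows left after filtering")
  rownames(out) <- NULL
  attr(out, "group") <- group
  out
}

#' Assemble a run configuration
#'
#' Defaults mirror the motivating study's settings: B = 2000 bootstrap
#' replicates, inclusive blacklist threshold t = 0.7, tabu list of 30 with
#' up to 30 non-improving iterations, and correlation thresholds per group.
#'
#' @param groups named list of data frames (or CSV paths), one per group;
#'   exactly two groups are required for cross-group comparison.
#' @param subsets named list of character vectors defining the variable
#'   subsets to analyze (e.g. electrophysiology, morphology, combined).
#' @param B bootstrap replicates.
#' @param t blacklist threshold.
#' @param tabu_list_size,max_nonimproving tabu-search settings.
#' @param correlation_thresholds named numeric, one threshold per group.
#' @param correlation_subset name of the subset on which correlation
#'   networks are built (default: the last subset).
#' @param seed master seed; per-stage substreams are derived from it by
#'   name so adding a subset does not perturb existing results.
#' @param out_dir output directory.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(groups, subsets, B = 2000L, t = 0.7,
                       tabu_list_size = 30L, max_nonimproving = 30L,
                       correlation_thresholds = NULL,
                       correlation_subset = NULL,
                       seed = 1L, out_dir = tempfile("neurogbn_run_")) {
  stopifnot(is.list(groups), length(groups) == 2L,
            !is.null(names(groups)), is.list(subsets),
            !is.null(names(subsets)), B >= 1, t >= 0, t <= 1)
  groups <- lapply(groups, function(g)
    if (is.character(g)) load_feature_table(g) else as.data.frame(g))
  for (s in names(subsets)) for (g in names(groups)) {
    miss <- setdiff(subsets[[s]], colnames(groups[[g]]))
    if (length(miss) > 0L)
      stop("subset ", s, " references columns absent from group ", g, ": ",
           paste(miss, collapse = ", "))
  }
  if (is.null(correlation_thresholds))
    correlation_thresholds <- stats::setNames(rep(0.4, length(groups)),
                                              names(groups))
  if (is.null(correlation_subset))
    correlation_subset <- names(subsets)[length(subsets)]
  structure(list(groups = groups, subsets = subsets, B = as.integer(B),
                 t = t, tabu_list_size = as.integer(tabu_list_size),
                 max_nonimproving = as.integer(max_nonimproving),
                 correlation_thresholds = correlation_thresholds,
                 correlation_subset = correlation_subset,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Expects fields `groups` (name -> feature-table CSV path), `subsets`
#' (name -> column list), and optionally `B`, `t`, `tabu_list_size`,
#' `max_nonimproving`, `correlation_thresholds`, `correlation_subset`,
#' `seed`, `out_dir`.
#'
#' @param path JSON file.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- list(groups = as.list(cfg$groups),
               subsets = lapply(cfg$subsets, as.character))
  for (f in c("B", "t", "tabu_list_size", "max_nonimproving",
              "correlation_subset", "seed", "out_dir"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  if (!is.null(cfg$correlation_thresholds))
    args$correlation_thresholds <- unlist(cfg$correlation_thresholds)
  do.call(run_config, args)
}

# deterministic substream seed from the master seed and a stage label
substream_seed <- function(master, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(master) %% 1000003) * 1009 + h) %% 2147483646L + 1L
}

#' Run the full comparative study
#'
#' For every group x subset: bootstrap arc confidences, blacklist at t,
#' definitive tabu structure, fitted parameters, CPDAG, Markov blankets,
#' precision matrix and partial correlations. For every subset: the
#' cross-group comparison (two Hellinger distances, common CPDAG arcs,
#' Markov-blanket agreement). On the designated subset: per-group marginal
#' correlation networks. All artifacts are written under `config$out_dir`
#' with a manifest recording the configuration hash and derived seeds.
#'
#' @param config a `run_config`.
#' @param verbose log stage progress (default TRUE).
#' @return (invisibly) a list with per-group-and-subset results, comparison
#'   reports, correlation networks, and the manifest.
#' @export
run_study <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  gnames <- names(config$groups)
  results <- list()
  seeds <- list()
  files <- character(0)
  emit <- function(name) { files <<- c(files, name); file.path(out_dir, name) }
  for (s in names(config$subsets)) {
    vars <- config$subsets[[s]]
    for (g in gnames) {
      label <- paste0("bootstrap.", g, ".", s)
      sd_gs <- substream_seed(config$seed, label)
      seeds[[label]] <- sd_gs
      say("[", g, " / ", s, "] bootstrap (B = ", config$B, ")")
      dat <- standardize_table(config$groups[[g]][vars])
      nets <- bootstrap_networks(dat, B = config$B, seed = sd_gs,
                                 standardize = FALSE,
                                 tabu_list_size = config$tabu_list_size,
                                 max_nonimproving = config$max_nonimproving)
      conf <- arc_confidence(nets)
      black <- build_blacklist(conf, config$t)
      say("[", g, " / ", s, "] blacklisted ", nrow(black), " of ",
          choose(length(vars), 2), " pairs; learning definitive structure")
      struct <- tabu_search(dat, tabu_list_size = config$tabu_list_size,
                            max_nonimproving = config$max_nonimproving,
                            blacklist = black)
      bn <- fit_parameters(struct, dat)
      omega <- precision_matrix(bn)
      res <- list(data = dat, confidence = conf, blacklist = black,
                  structure = struct, bn = bn,
                  cpdag = dag_to_cpdag(struct),
                  markov_blankets = lapply(stats::setNames(nm = sort(vars)),
                                           function(v) markov_blanket(struct, v)),
                  omega = omega,
                  partial_correlations = partial_correlations(omega))
      results[[paste(g, s, sep = ".")]] <- res
      stem <- paste0(g, ".", s)
      utils::write.csv(arc_confidence_table(conf, config$t),
                       emit(paste0(stem, ".confidence.csv")), row.names = FALSE)
      write_arcs_csv(struct, emit(paste0(stem, ".arcs.csv")))
      write_dot(struct, emit(paste0(stem, ".dot")))
      write_graphml(struct, emit(paste0(stem, ".graphml")))
      gbn_to_json(bn, emit(paste0(stem, ".params.json")))
    }
  }
  comparisons <- list()
  for (s in names(config$subsets)) {
    a <- results[[paste(gnames[1L], s, sep = ".")]]
    b <- results[[paste(gnames[2L], s, sep = ".")]]
    say("[", s, "] cross-group comparison")
    cmp <- compare_networks(a$bn, b$bn,
                            config$groups[[gnames[1L]]][config$subsets[[s]]],
                            config$groups[[gnames[2L]]][config$subsets[[s]]])
    comparisons[[s]] <- cmp
    rep <- list(subset = s, groups = gnames,
                hellinger = stats::setNames(
                  c(cmp$hellinger_on_A, cmp$hellinger_on_B), gnames),
                common_arcs = cmp$common_arcs,
                markov_blanket_agreement = as.list(cmp$markov_blanket_agreement))
    writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               emit(paste0("comparison.", s, ".json")))
  }
  corr_nets <- list()
  cs <- config$correlation_subset
  for (g in gnames) {
    net <- correlation_network(config$groups[[g]][config$subsets[[cs]]],
                               config$correlation_thresholds[[g]])
    corr_nets[[g]] <- net
    write_correlation_graphml(net, emit(paste0(g, ".", cs,
                                               ".correlation.graphml")))
  }
  cfg_json <- jsonlite::toJSON(list(
    groups = lapply(config$groups, dim), subsets = config$subsets,
    B = config$B, t = config$t, tabu_list_size = config$tabu_list_size,
    max_nonimproving = config$max_nonimproving,
    correlation_thresholds = as.list(config$correlation_thresholds),
    correlation_subset = cs, seed = config$seed),
    auto_unbox = TRUE, digits = NA)
  cfg_file <- emit("config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_file)),
                   seed = config$seed, substream_seeds = seeds,
                   files = sort(files))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  say("study complete: ", length(files) + 1L, " artifacts in ", out_dir)
  invisible(list(results = results, comparisons = comparisons,
                 correlation_networks = corr_nets, manifest = manifest,
                 out_dir = out_dir))
}
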