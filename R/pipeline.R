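#' Configuration for the two-network anomaly pipeline
#'
#' Bundles and validates all inputs and tuning parameters of
#' [run_anomaly_pipeline()].  Matrix arguments may be vectors of paths, in
#' which case the cohort mean network is used (average first, threshold
#' second).
#'
#' @param control_matrix,disease_matrix path(s) to connectivity matrix
#'   files (see [read_network()]).
#' @param control_labels,disease_labels optional label file paths.
#' @param outdir output directory (created if missing).
#' @param tau sparsification threshold (default 0.4).
#' @param d face order, one of 3, 4, 5 (default 5).
#' @param mode face mode (default `"chordal"`).
#' @param cutoff outlier cutoff, numeric or `"auto"`.
#' @param replicates null-model replicates for z-scores (default 100).
#' @param swap_factor swaps per replicate as a multiple of the edge count.
#' @param seed integer seed.
#' @param top_k number of top outliers to z-score.
#' @param extra_edges optional list of extra label pairs to z-score.
#' @return a validated list of class `anomaly_config`.
#' @export
anomaly_config <- function(control_matrix, disease_matrix, outdir,
                           control_labels = NULL, disease_labels = NULL,
                           tau = 0.4, d = 5, mode = "chordal",
                           cutoff = "auto", replicates = 100,
                           swap_factor = 5, seed = 1, top_k = 5,
                           extra_edges = NULL) {
  if (!(d %in% 3:5)) stop("d must be 3, 4 or 5")
  if (replicates < 2) stop("replicates must be at least 2")
  if (tau < 0) stop("tau must be non-negative")
  structure(list(control_matrix = control_matrix,
                 disease_matrix = disease_matrix,
                 control_labels = control_labels,
                 disease_labels = disease_labels,
                 outdir = outdir, tau = tau, d = d, mode = mode,
                 cutoff = cutoff, replicates = replicates,
                 swap_factor = swap_factor, seed = seed, top_k = top_k,
                 extra_edges = extra_edges),
            class = "anomaly_config")
}

.read_cohort <- function(paths, labels_path) {
  nets <- lapply(paths, read_network, labels_path = labels_path)
  if (length(nets) == 1L) nets[[1L]] else mean_network(nets)
}

#' Run the full two-network anomaly analysis
#'
#' Orchestrates load (with optional cohort averaging), sparsification,
#' curvature computation for both networks, curvature differences, outlier
#' selection, normalisation, the edge-weight baseline and null-model
#' z-scores for the strongest outliers, and writes the results to
#' `outdir`:
#' \describe{
#'   \item{`outliers.tsv`}{all outlier edges with their differences.}
#'   \item{`focal_edges.tsv`}{the z-scored edges with both curvatures,
#'     difference and z.}
#'   \item{`comparison.tsv`}{edge-weight difference versus normalised
#'     curvature difference for the z-scored edges.}
#'   \item{`run_log.txt`}{provenance: package version, seed, configuration.}
#' }
#'
#' @param config an [anomaly_config()].
#' @return invisibly, a list with the `curvature_anomaly` fit and the
#'   output file paths.
#' @export
run_anomaly_pipeline <- function(config) {
  if (!inherits(config, "anomaly_config")) stop("config must be an anomaly_config")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$outdir,
                     c("outliers.tsv", "focal_edges.tsv", "comparison.tsv",
                       "run_log.txt"))
  names(paths) <- c("outliers", "focal", "comparison", "log")
  ok <- FALSE
  on.exit(if (!ok) unlink(paths[file.exists(paths)]))
  control <- .read_cohort(config$control_matrix, config$control_labels)
  disease <- .read_cohort(config$disease_matrix, config$disease_labels)
  fit <- curvature_anomaly(control, disease, d = config$d,
                           mode = config$mode, tau = config$tau,
                           cutoff = config$cutoff, top_k = config$top_k,
                           extra_edges = config$extra_edges,
                           replicates = config$replicates,
                           swap_factor = config$swap_factor,
                           seed = config$seed)
  out <- fit$records[abs(fit$records$delta) > fit$cutoff, , drop = FALSE]
  write_anomaly_table(out, paths[["outliers"]])
  focal <- fit$records[!is.na(fit$records$z), , drop = FALSE]
  utils::write.table(
    focal[c("edge_u", "edge_v", "curv_control", "curv_disease", "delta", "z")],
    paths[["focal"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    focal[c("edge_u", "edge_v", "weight_delta", "norm_delta")],
    paths[["comparison"]], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- config[setdiff(names(config), "extra_edges")]
  writeLines(c(
    sprintf("netcurv %s", as.character(utils::packageVersion("netcurv"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    vapply(names(cfg), function(k)
      sprintf("%s: %s", k, paste(format(cfg[[k]]), collapse = ", ")), "")),
    paths[["log"]])
  ok <- TRUE
  invisible(list(fit = fit, paths = paths))
}

#' Curvature table for a single network file
#'
#' Reads one connectivity matrix, optionally sparsifies it, and writes the
#' per-edge curvature table as TSV (`node_u`, `node_v`, `curvature`).
#'
#' @param matrix_path,labels_path input files, see [read_network()].
#' @param out output TSV path.
#' @param tau sparsification threshold (0 keeps all positive edges).
#' @param d,mode curvature parameters.
#' @return invisibly, the [curvature_map()] table.
#' @export
run_curvature <- function(matrix_path, out, labels_path = NULL, tau = 0.4,
                          d = 5, mode = "chordal") {
  net <- read_network(matrix_path, labels_path = labels_path)
  net <- sparsify(net, tau)
  tab <- curvature_map(net, d = d, mode = mode)
  colnames(tab) <- c("node_u", "node_v", "curvature")
  utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
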