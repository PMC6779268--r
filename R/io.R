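#' Read a time-series dataset
#'
#' Delimited-text matrices use a header row of node labels and one row per
#' time point; a JSON sidecar `<path>.json` (if present) supplies metadata
#' such as the sampling rate and a ground-truth adjacency. Benchmark-style
#' containers are JSON bundles holding several simulated subjects, each
#' with a `ts` matrix and a `net` ground-truth adjacency, and yield a list
#' of datasets.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or
#'   `"benchmark"`.
#' @return an `fc_dataset` (list with `ts` time x nodes matrix, `fs`,
#'   optional `truth` adjacency, `meta`), or a list of them for benchmark
#'   containers.
#' @export
read_dataset <- function(path, format = c("auto", "csv", "tsv",
                                          "benchmark")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     json = "benchmark",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "benchmark") return(read_benchmark(path))
  df <- tryCatch(
    if (format == "csv") read.csv(path, comment.char = "#")
    else read.delim(path, comment.char = "#"),
    error = function(e) stop("malformed file ", path, ": ",
                             conditionMessage(e)))
  ts <- as.matrix(df)
  if (!is.numeric(ts)) stop("malformed file ", path, ": non-numeric values")
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::fromJSON(sidecar)
  if (nrow(ts) < ncol(ts)) ts <- t(ts)  # normalize to time x nodes
  fs <- if (!is.null(meta$fs)) meta$fs else 1
  truth <- if (!is.null(meta$truth)) as.matrix(meta$truth) else NULL
  fc_dataset(ts, fs = fs, truth = truth, meta = meta)
}

fc_dataset <- function(ts, fs = 1, truth = NULL, meta = list()) {
  ts <- as.matrix(ts)
  if (!is.null(truth)) {
    truth <- as.matrix(truth)
    if (nrow(truth) != ncol(ts) || ncol(truth) != ncol(ts))
      stop("truth adjacency must be square with dimension = n_nodes")
  }
  structure(list(ts = ts, fs = fs, truth = truth, meta = meta),
            class = "fc_dataset")
}

#' @export
print.fc_dataset <- function(x, ...) {
  cat(sprintf("<fc_dataset> %d time points x %d nodes at %g Hz%s\n",
              nrow(x$ts), ncol(x$ts), x$fs,
              if (is.null(x$truth)) "" else ", with ground truth"))
  invisible(x)
}

read_benchmark <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyMatrix = TRUE),
                  error = function(e) stop("malformed container ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(obj$subjects)) stop("malformed container ", path,
                                  ": missing 'subjects'")
  fs <- if (!is.null(obj$fs)) obj$fs else 1
  subjects <- obj$subjects
  if (is.data.frame(subjects))
    subjects <- lapply(seq_len(nrow(subjects)), function(i)
      list(ts = subjects$ts[[i]], net = subjects$net[[i]]))
  lapply(subjects, function(s) {
    ts <- as.matrix(s$ts)
    if (nrow(ts) < ncol(ts)) ts <- t(ts)
    fc_dataset(ts, fs = fs,
               truth = if (is.null(s$net)) NULL else as.matrix(s$net),
               meta = list(source = path))
  })
}

#' Write a dataset to delimited text with a JSON metadata sidecar
#'
#' @param dataset an `fc_dataset` or plain matrix.
#' @param path output CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  if (!inherits(dataset, "fc_dataset")) dataset <- fc_dataset(dataset)
  ts <- dataset$ts
  if (is.null(colnames(ts))) colnames(ts) <- paste0("node", seq_len(ncol(ts)))
  write.csv(as.data.frame(ts), path, row.names = FALSE)
  meta <- dataset$meta
  meta$fs <- dataset$fs
  meta$version <- .fc_version()
  if (!is.null(dataset$truth)) meta$truth <- dataset$truth
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Serialize trained sign maps to versioned JSON
#'
#' @param maps an `fc_signmaps` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signmaps <- function(maps, path) {
  stopifnot(inherits(maps, "fc_signmaps"))
  obj <- list(version = maps$version, grid = maps$grid,
              n_sims = maps$n_sims, weight = maps$weight,
              Sr = unname(maps$Sr), Si = unname(maps$Si))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Read sign maps written by [write_signmaps()]
#'
#' @param path JSON path.
#' @return an `fc_signmaps` object.
#' @export
read_signmaps <- function(path) {
  obj <- jsonlite::fromJSON(path)
  grid <- as.numeric(obj$grid)
  Sr <- matrix(as.integer(obj$Sr), length(grid), length(grid))
  Si <- matrix(as.integer(obj$Si), length(grid), length(grid))
  dimnames(Sr) <- dimnames(Si) <- list(k = grid, l = grid)
  structure(list(Sr = Sr, Si = Si, grid = grid,
                 n_sims = as.integer(obj$n_sims),
                 weight = as.numeric(obj$weight),
                 version = as.character(obj$version)),
            class = "fc_signmaps")
}

#' Write analysis results
#'
#' Deterministic field order with the package version embedded: edge lists
#' and grids as CSV with a version comment line, maps as versioned JSON.
#'
#' @param results edge-list data.frame, `fc_grid`, or `fc_signmaps`.
#' @param path output path.
#' @param kind `"edges"`, `"grid"` or `"maps"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, kind = c("edges", "grid", "maps")) {
  kind <- match.arg(kind)
  if (kind == "maps") return(write_signmaps(results, path))
  df <- if (kind == "grid") {
    stopifnot(inherits(results, "fc_grid"))
    results$results[, c("method", "up_level", "down_level", "success", "n")]
  } else {
    as.data.frame(results)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fraccum %s %s", .fc_version(), kind), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
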