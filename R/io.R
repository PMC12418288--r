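#' Read and write the pipeline's CSV artifacts
#'
#' Labelled binary matrices (presence-absence, incidence) are written with
#' their row-label column first (`host_id` / `parasite_id`); distance
#' matrices keep their `kind` tag in a sidecar-free way via the file name
#' chosen by the caller. All writers/readers round-trip losslessly.
#'
#' @param m matrix with row and column names.
#' @param path output file.
#' @param label name of the row-label column.
#' @name matrix_io
NULL

#' @rdname matrix_io
#' @export
write_matrix_csv <- function(m, path, label = "host_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- label
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a distance matrix with its kind tag
#' @param d distance matrix (see [dist_kind()]).
#' @param path output CSV.
#' @export
write_dist_csv <- function(d, path) {
  write_matrix_csv(d, path, label = "host_id")
}

#' Read a distance matrix written by [write_dist_csv()]
#' @param path CSV path.
#' @param kind optional kind tag to attach.
#' @export
read_dist_csv <- function(path, kind = NULL) {
  d <- read_matrix_csv(path)
  if (!is.null(kind)) attr(d, "kind") <- kind
  d
}

#' Write/read the host trait table
#' @param traits trait data frame with `host_id`.
#' @param path CSV path.
#' @name traits_io
#' @export
write_traits_csv <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname traits_io
#' @export
read_traits_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the JSON sidecar recording config and planted truth
#'
#' @param config a [world_config()].
#' @param path JSON path.
#' @export
write_world_sidecar <- function(config, path) {
  x <- unclass(config)
  x$grid <- unclass(x$grid)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
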