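#' Write / read an epochs container
#'
#' Serialises a [meg_epochs()] object as a plain-text directory bundle:
#' `meta.json` (dimensions, labels, sampling rate, layout, optional
#' generator config) and `data.csv` (one row per trial, channels-by-times
#' features in channel-major order). The format is self-describing and
#' diff-friendly; values round-trip to full double precision.
#'
#' @param epochs a [meg_epochs()] object.
#' @param path directory to create (must not exist or be empty).
#' @param config optional [sim_config()] stored alongside for provenance.
#' @return `write_epochs()`: `path`, invisibly.
#' @export
write_epochs <- function(epochs, path, config = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  meta <- list(
    n_trials = d[1L], n_channels = d[2L], n_times = d[3L],
    sfreq = epochs$sfreq, t0 = epochs$t0, labels = epochs$labels,
    layout = if (!is.null(epochs$layout)) list(
      n_sites = epochs$layout$n_sites,
      seed_positions = unname(as.vector(epochs$layout$positions))) else NULL,
    config = if (!is.null(config)) {
      cfg <- unclass(config)
      cfg$patterns <- lapply(cfg$patterns, unclass)
      cfg
    } else NULL
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  m <- matrix(epochs$data, nrow = d[1L])  # [trials x (channels*times)]
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     file.path(path, "data.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @return `read_epochs()`: a `meg_epochs` object. A layout with the stored
#'   site count is rebuilt deterministically when present.
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(file.path(path, "data.csv"), sep = ","))
  data <- array(as.numeric(m),
                dim = c(meta$n_trials, meta$n_channels, meta$n_times))
  layout <- NULL
  if (!is.null(meta$layout) && !is.null(meta$config$seed))
    layout <- make_sensor_layout(meta$layout$n_sites, meta$config$seed)
  else if (!is.null(meta$layout))
    layout <- make_sensor_layout(meta$layout$n_sites)
  meg_epochs(data, meta$labels, meta$sfreq, meta$t0, layout)
}

#' Write a split to JSON / read it back
#'
#' @param split a [stratified_split()] result.
#' @param path JSON file path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(split, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(train = as.integer(s$train), validation = as.integer(s$validation))
}
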