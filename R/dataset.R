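#' Construct a dataset container
#'
#' Light container for observed data shared by all models: the response
#' (a vector, or an outputs x samples matrix for multi-channel time series),
#' a design matrix or time grid, and the known, fixed observation noise
#' standard deviation(s).  Noise variances are treated as known throughout.
#'
#' @param y Numeric response vector, or matrix with one row per output
#'   channel and one column per sample/time point.
#' @param X Optional design matrix (regression models).
#' @param t Optional time grid (time-series models).
#' @param noise_sd Noise standard deviation, one value per output channel
#'   (recycled if scalar); zero is permitted only for noise-free synthetic
#'   data.
#' @param truth Optional list of generating parameter values, carried along
#'   by the synthetic-data generators.
#' @return An object of class `ais_dataset`.
#' @export
ais_dataset <- function(y, X = NULL, t = NULL, noise_sd, truth = NULL) {
  if (!all(is.finite(y))) stop("y must be finite")
  noise_sd <- as.numeric(noise_sd)
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  structure(
    list(y = y, X = X, t = t, noise_sd = noise_sd, truth = truth),
    class = "ais_dataset"
  )
}

#' @export
print.ais_dataset <- function(x, ...) {
  ny <- if (is.matrix(x$y)) paste(dim(x$y), collapse = " x ") else length(x$y)
  cat("<ais_dataset> y:", ny, " noise_sd:",
      format(x$noise_sd, digits = 4), "\n")
  invisible(x)
}

#' Write / read a dataset as CSV with a JSON sidecar
#'
#' The response is written as CSV (columns = output channels, rows = samples
#' or time points, plus the time grid and any design columns), and the noise
#' standard deviation, time grid and generating truth go to a `.json`
#' sidecar next to it.
#'
#' @param data An [ais_dataset()].
#' @param path Path of the CSV file to write; the sidecar gets the same path
#'   with extension `.json`.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   an [ais_dataset()].
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "ais_dataset"))
  y <- data$y
  df <- if (is.matrix(y)) {
    as.data.frame(t(y))
  } else {
    data.frame(y = y)
  }
  if (is.matrix(y) && is.null(colnames(y))) {
    names(df) <- paste0("y", seq_len(nrow(y)))
  }
  if (!is.null(data$t)) df <- cbind(t = data$t, df)
  if (!is.null(data$X)) {
    Xd <- as.data.frame(data$X)
    names(Xd) <- paste0("x", seq_len(ncol(data$X)))
    df <- cbind(df, Xd)
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    noise_sd = data$noise_sd,
    y_is_matrix = is.matrix(y),
    n_outputs = if (is.matrix(y)) nrow(y) else 1L,
    has_t = !is.null(data$t),
    n_design = if (is.null(data$X)) 0L else ncol(data$X),
    truth = data$truth
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  i <- 1L
  t <- NULL
  if (isTRUE(meta$has_t)) {
    t <- df[[1L]]
    i <- i + 1L
  }
  ny <- meta$n_outputs
  ycols <- seq.int(i, i + ny - 1L)
  y <- if (isTRUE(meta$y_is_matrix)) {
    t(as.matrix(df[, ycols, drop = FALSE]))
  } else {
    df[[i]]
  }
  X <- NULL
  if (meta$n_design > 0) {
    X <- as.matrix(df[, seq.int(i + ny, i + ny + meta$n_design - 1L),
                      drop = FALSE])
    dimnames(X) <- NULL
  }
  ais_dataset(y = y, X = X, t = t, noise_sd = meta$noise_sd,
              truth = meta$truth)
}

sidecar_path <- function(path) {
  sub("\\.[^.]+$", ".json", path)
}
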