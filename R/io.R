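#' Read and write model parameters as JSON
#'
#' `H` is stored as a list, `J` as a nested list (row-major), alongside
#' `N`; round-trips exactly at full double precision.
#'
#' @param model an [ising_model].
#' @param path file path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns an [ising_model].
#' @export
write_model_json <- function(model, path) {
  obj <- list(N = model$N, H = model$H,
              J = apply(model$J, 1L, identity, simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  J <- if (is.matrix(obj$J)) obj$J else do.call(rbind, obj$J)
  ising_model(as.numeric(obj$H), J)
}

#' Export a moment series to long-format CSV
#'
#' One row per statistic entry: columns `t`, `i`, `k`, `statistic`
#' (`"m"`, `"C"` or `"D"`; `k` is `NA` for rates) and `value`.
#'
#' @param series a [moment_series].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_moment_series_csv <- function(series, path) {
  N <- series$N
  ts <- 0:series$T_steps
  idx <- expand.grid(i = seq_len(N), k = seq_len(N))
  rows <- lapply(ts, function(t) {
    sl <- t + 1L
    rbind(
      data.frame(t = t, i = seq_len(N), k = NA_integer_, statistic = "m",
                 value = series$m[sl, ]),
      data.frame(t = t, i = idx$i, k = idx$k, statistic = "C",
                 value = as.vector(series$C[, , sl])),
      data.frame(t = t, i = idx$i, k = idx$k, statistic = "D",
                 value = as.vector(series$D[, , sl])))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Load a trajectory ensemble from a plain-text table
#'
#' Reads a whitespace- or comma-separated table with columns
#' `trial`, `time`, then one column per unit, containing `-1/+1` spins
#' (or `0/1` if `convert01 = TRUE`). Provided for ingesting externally
#' recorded binary activity; rejects `0/1` rasters unless conversion is
#' requested explicitly, since silent recoding changes every statistic.
#'
#' @param path file path.
#' @param convert01 convert `0/1` entries to `-1/+1`.
#' @return A `trajectory_ensemble`.
#' @export
read_ensemble_table <- function(path, convert01 = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          check.names = FALSE)
  if (ncol(df) < 3) stop("expected columns: trial, time, unit columns")
  spins <- as.matrix(df[, -(1:2), drop = FALSE])
  if (all(spins %in% c(0, 1))) {
    if (!convert01)
      stop("data look like 0/1; pass convert01 = TRUE to recode to -1/+1")
    spins <- 2 * spins - 1
  }
  if (!all(spins %in% c(-1, 1))) stop("spin entries must be -1/+1 (or 0/1)")
  trials <- sort(unique(df[[1]])); times <- sort(unique(df[[2]]))
  R <- length(trials); Tp1 <- length(times); N <- ncol(spins)
  arr <- array(NA_integer_, c(R, Tp1, N))
  ri <- match(df[[1]], trials); ti <- match(df[[2]], times)
  for (n in seq_len(N)) arr[cbind(ri, ti, n)] <- as.integer(spins[, n])
  if (anyNA(arr)) stop("missing (trial, time) combinations in table")
  structure(arr, seed = NA_integer_, params_id = "external",
            class = c("trajectory_ensemble", "array"))
}
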