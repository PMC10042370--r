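# Tabular I/O: the CSV dialects for marker trials, angle series, metric rows
# and cohort tables, plus YAML run configuration.

#' Write / read an angle-series CSV
#'
#' Dialect: columns `time`, `flexion_extension`, `lateral_bending`,
#' `axial_rotation`; degrees; header row mandatory.
#'
#' @param angles an [angle_series()].
#' @param path file path.
#' @return `read_angles()` returns an [angle_series()].
#' @export
write_angles <- function(angles, path) {
  stopifnot(inherits(angles, "angle_series"))
  fs <- sample_rate_of(angles)
  df <- data.frame(time = (seq_len(nrow(angles)) - 1L) / fs,
                   flexion_extension = angles[, "fe"],
                   lateral_bending = angles[, "lb"],
                   axial_rotation = angles[, "ar"])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_angles
#' @export
read_angles <- function(path) {
  df <- read_csv_checked(path,
                         c("time", "flexion_extension", "lateral_bending",
                           "axial_rotation"))
  dt <- diff(df$time)
  if (any(dt <= 0)) stop("non-increasing timestamps in ", path)
  rate <- 1 / median(dt)
  if (max(abs(dt - 1 / rate)) > 0.25 / rate)
    stop("angle CSV ", path, " is not uniformly sampled; resample markers ",
         "instead")
  angle_series(cbind(fe = df$flexion_extension, lb = df$lateral_bending,
                     ar = df$axial_rotation),
               sample_rate = round(rate, 6))
}

#' Write / read a marker-trial CSV
#'
#' Dialect: columns `time` then `<marker>_<x|y|z>` for the six markers
#' `thorax_1..3`, `pelvis_1..3`, meters; header row mandatory.
#'
#' @param trial a [marker_trial()].
#' @param path file path.
#' @return `read_markers()` returns a [marker_trial()].
#' @export
write_markers <- function(trial, path) {
  stopifnot(inherits(trial, "marker_trial"))
  df <- data.frame(time = trial$time, trial$positions, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  df <- read_csv_checked(path, c("time", marker_columns()))
  rate <- 1 / median(diff(df$time))
  marker_trial(df$time, as.matrix(df[, marker_columns()]),
               nominal_rate = round(rate, 1))
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e)
                   stop("failed to parse ", path, ": ", conditionMessage(e),
                        call. = FALSE))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  bad <- required[!vapply(df[required], is.numeric, logical(1))]
  if (length(bad))
    stop("file ", path, " has non-numeric column(s): ",
         paste(bad, collapse = ", "))
  df
}

#' Read or write a pipeline run configuration as YAML
#'
#' @param path YAML file path.
#' @param config list as returned by [pipeline_config()].
#' @return `read_run_config()` returns a [pipeline_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- lapply(unclass(config), function(x)
    if (inherits(x, "embedding_config")) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  emb <- raw$embedding
  emb$dimension <- NULL
  raw$embedding <- do.call(embedding_config, emb)
  do.call(pipeline_config, raw)
}
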