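# End-to-end orchestration: trial input -> movement metrics row, and cohort
# metrics + metadata -> statistical report.

#' Pipeline configuration
#'
#' All protocol parameters surfaced with the task's values as defaults:
#' 100 Hz resampling, 45 expected cycles of which the final 40 are analyzed,
#' 101-point cycle normalization, and the embedding parameters of
#' [embedding_config()].
#'
#' @param sample_rate resampling rate, Hz.
#' @param n_cycles_expected expected peak count; `NULL` disables the check.
#' @param n_analysis_cycles number of final cycles analyzed.
#' @param n_phase_points samples per normalized cycle (0-100%).
#' @param max_align_shift cross-correlation alignment bound, phase samples.
#' @param prominence_frac,separation_frac peak-detection parameters,
#'   see [detect_cycles()].
#' @param compute_lde logical: compute the local divergence exponent.
#' @param embedding an [embedding_config()].
#' @param seed integer seed recorded with outputs (the trial pipeline itself
#'   is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sample_rate = 100, n_cycles_expected = 45,
                            n_analysis_cycles = 40, n_phase_points = 101,
                            max_align_shift = 10, prominence_frac = 0.25,
                            separation_frac = 0.5, compute_lde = TRUE,
                            embedding = embedding_config(), seed = NULL) {
  stopifnot(inherits(embedding, "embedding_config"))
  structure(list(sample_rate = sample_rate,
                 n_cycles_expected = n_cycles_expected,
                 n_analysis_cycles = as.integer(n_analysis_cycles),
                 n_phase_points = as.integer(n_phase_points),
                 max_align_shift = as.integer(max_align_shift),
                 prominence_frac = prominence_frac,
                 separation_frac = separation_frac,
                 compute_lde = isTRUE(compute_lde),
                 embedding = embedding, seed = seed),
            class = "pipeline_config")
}

resolve_trial_input <- function(input, config) {
  if (inherits(input, "angle_series")) return(input)
  if (inherits(input, "marker_trial"))
    return(markers_to_angles(input, rate = config$sample_rate))
  if (is.character(input) && length(input) == 1L) {
    if (grepl("\\.c3d$", input, ignore.case = TRUE))
      stop("C3D input is not supported; convert the recording to the ",
           "marker CSV dialect (columns time, <marker>_<x|y|z>) first")
    if (!file.exists(input)) stop("input file not found: ", input)
    header <- tryCatch(names(read.csv(input, nrows = 1L,
                                      check.names = FALSE)),
                       error = function(e)
                         stop("failed to read ", input, ": ",
                              conditionMessage(e), call. = FALSE))
    if ("flexion_extension" %in% header) return(read_angles(input))
    return(markers_to_angles(read_markers(input),
                             rate = config$sample_rate))
  }
  stop("unsupported trial input; supply an angle_series, marker_trial or ",
       "CSV path")
}

#' Run the full single-trial analysis
#'
#' Executes resampling, cluster orientations, Euler decomposition (for marker
#' input), cycle detection on the sagittal trace, selection of the final
#' analysis cycles, time normalization, cross-correlation alignment, and the
#' movement-pattern metrics (MeanSD per axis, CyclSD, amplitude per axis,
#' velocity, and the local divergence exponent on the per-cycle-resampled
#' series). Deterministic given input and configuration.
#'
#' @param input an [angle_series()], [marker_trial()], or path to an angle /
#'   marker CSV (C3D recordings must be converted to CSV first).
#' @param config a [pipeline_config()].
#' @param trial_id optional identifier attached to errors and the output row.
#' @return One-row data.frame: `mean_sd_fe`, `mean_sd_lb`, `mean_sd_ar`
#'   (deg), `cycl_sd` (s), `amplitude_fe`, `amplitude_lb`, `amplitude_ar`
#'   (deg), `velocity` (rep/s), `lde` (log divergence per cycle; `NA` if
#'   disabled), `n_cycles`. Attribute `diagnostics` carries peaks, shifts and
#'   the divergence curve.
#' @export
run_trial_pipeline <- function(input, config = pipeline_config(),
                               trial_id = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  run <- function() {
    angles <- resolve_trial_input(input, config)
    fs <- sample_rate_of(angles)
    peaks <- detect_cycles(angles, rate = fs,
                           expected = config$n_cycles_expected,
                           prominence_frac = config$prominence_frac,
                           separation_frac = config$separation_frac)
    bounds <- select_analysis_cycles(peaks, config$n_analysis_cycles)
    durations <- diff(bounds) / fs
    cycles <- normalize_cycles(angles, bounds, config$n_phase_points)
    ali <- align_cycles(cycles, max_shift = config$max_align_shift)
    msd <- mean_sd(ali$cycles)
    raw_cycles <- lapply(seq_len(length(bounds) - 1L), function(i)
      angles[bounds[i]:bounds[i + 1L], , drop = FALSE])
    amp <- amplitude(raw_cycles)
    vel <- velocity(config$n_analysis_cycles,
                    (bounds[length(bounds)] - bounds[1L]) / fs)
    lde_val <- NA_real_
    curve <- NULL
    if (config$compute_lde) {
      span <- angles[bounds[1L]:bounds[length(bounds)], , drop = FALSE]
      lde_val <- lde_from_angles(span, config$n_analysis_cycles,
                                 config$embedding)
      curve <- attr(lde_val, "curve")
    }
    out <- data.frame(mean_sd_fe = msd[["fe"]], mean_sd_lb = msd[["lb"]],
                      mean_sd_ar = msd[["ar"]],
                      cycl_sd = cycl_sd(durations),
                      amplitude_fe = amp[["fe"]], amplitude_lb = amp[["lb"]],
                      amplitude_ar = amp[["ar"]], velocity = vel,
                      lde = as.numeric(lde_val),
                      n_cycles = config$n_analysis_cycles)
    if (!is.null(trial_id)) out <- cbind(trial_id = trial_id, out)
    attr(out, "diagnostics") <- list(peaks = peaks, boundaries = bounds,
                                     shifts = ali$shifts,
                                     divergence_curve = curve)
    out
  }
  tryCatch(run(), error = function(e) {
    id <- if (is.null(trial_id)) {
      if (is.character(input)) input else "<in-memory trial>"
    } else trial_id
    stop("trial ", id, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the cohort-level statistical analysis
#'
#' Applies the log transform to the skewed metrics, dichotomizes EBS at the
#' fixed split, fits the two mixed MANOVAs (variability/stability:
#' MeanSD x3 + CyclSD + LDE; amplitude/velocity: amplitudes x3 + velocity),
#' runs univariate follow-ups for every effect, and the nonparametric
#' descriptive suite.
#'
#' @param table long-format cohort table: one row per participant per
#'   condition with the metric columns and `ebs_threat`, `ebs_reference`.
#' @param alpha significance threshold used for flagging (default 0.05; no
#'   multiple-testing correction).
#' @return A `cohort_report` list: `manova_stability`,
#'   `manova_amplitude`, `univariate` (Table-2-style data.frame),
#'   `nonparametric`, `flagged`.
#' @export
run_cohort <- function(table, alpha = 0.05) {
  logged <- transform_skewed(table)
  dvs1 <- c("mean_sd_fe", "mean_sd_ar", "mean_sd_lb", "cycl_sd", "lde")
  dvs2 <- c("amplitude_fe", "amplitude_ar", "amplitude_lb", "velocity")
  m1 <- mixed_manova(logged, dvs1)
  m2 <- mixed_manova(logged, dvs2)
  univ <- rbind(cbind(analysis = "variability_stability", m1$univariate),
                cbind(analysis = "amplitude_velocity", m2$univariate))
  multiv <- rbind(cbind(analysis = "variability_stability", m1$multivariate),
                  cbind(analysis = "amplitude_velocity", m2$multivariate))
  flagged <- multiv[multiv$p <= alpha, c("analysis", "effect", "p")]
  meta <- table[table$condition == "threat",
                intersect(c("participant", "group", "ebs_threat",
                            "ebs_reference", "pcs", "pass", "height",
                            "weight"), names(table))]
  npar <- nonparametric_suite(meta)
  structure(list(manova_stability = m1, manova_amplitude = m2,
                 multivariate = multiv, univariate = univ,
                 nonparametric = npar, flagged = flagged, alpha = alpha),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort analysis report\n")
  cat("== Multivariate (Wilks) ==\n")
  m <- x$multivariate
  for (i in seq_len(nrow(m)))
    cat(sprintf("  [%s] %-18s Lambda = %.3f F(%d, %g) = %.3f p = %.4f%s\n",
                substr(m$analysis[i], 1, 4), m$effect[i], m$wilks[i],
                m$df1[i], m$df2[i], m$F[i], m$p[i],
                ifelse(m$p[i] <= x$alpha, " *", "")))
  cat("== Nonparametric descriptives ==\n")
  print(x$nonparametric, row.names = FALSE)
  invisible(x)
}

#' Write the cohort report as CSV files
#'
#' Emits `multivariate.csv`, `univariate.csv` (effect, DV, F, p, partial eta
#' squared) and `nonparametric.csv` into `dir`.
#'
#' @param report a `cohort_report` from [run_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(report$multivariate, file.path(dir, "multivariate.csv"),
            row.names = FALSE)
  write.csv(report$univariate, file.path(dir, "univariate.csv"),
            row.names = FALSE)
  write.csv(report$nonparametric, file.path(dir, "nonparametric.csv"),
            row.names = FALSE)
  invisible(dir)
}
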