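# Cohort-level synthetic data: 2 (group: LBP vs back-healthy) x 2 (expected
# back strain: low vs high) between-subject cells, each participant measured
# in two conditions (threat, reference). Metric values are generated directly
# at the summary level, on the log scale for the skewed metrics, with
# participant-level random baselines, so the statistics stage can be
# calibrated (type-I error, power) over many replicates quickly.

# Baseline medians and dispersions of the movement metrics under the
# reference condition. Location/scale of the log-normal draws chosen once
# from the observed summary scales of the task (medians ~1.66 / 0.86 / 0.87
# deg MeanSD, 0.10 s CyclSD, 20.4 / 8.2 / 7.9 deg amplitude, 0.38 rep/s
# velocity, LDE 3.86 +- 0.2 on the natural scale); between/within SDs sized
# so a 22% threat effect on MeanSD_fe yields F ratios of the magnitude seen
# in this paradigm (~20 at N = 60).
cohort_baselines <- function() {
  list(
    log_median = c(mean_sd_fe = log(1.66), mean_sd_lb = log(0.87),
                   mean_sd_ar = log(0.86), cycl_sd = log(0.10),
                   amplitude_fe = log(20.4), amplitude_lb = log(7.9),
                   amplitude_ar = log(8.2), velocity = log(0.38)),
    between_sd = c(mean_sd_fe = 0.21, mean_sd_lb = 0.25, mean_sd_ar = 0.22,
                   cycl_sd = 0.25, amplitude_fe = 0.35, amplitude_lb = 0.40,
                   amplitude_ar = 0.40, velocity = 0.12),
    within_sd = c(mean_sd_fe = 0.25, mean_sd_lb = 0.15, mean_sd_ar = 0.15,
                  cycl_sd = 0.17, amplitude_fe = 0.10, amplitude_lb = 0.12,
                  amplitude_ar = 0.12, velocity = 0.05),
    lde_mean = 3.86, lde_between_sd = 0.20, lde_within_sd = 0.18)
}

#' Configuration of a synthetic cohort
#'
#' @param n_per_group participants per group-by-EBS cell (default 15, giving
#'   the study's 60 participants).
#' @param threat_effect multiplicative threat-condition factor on MeanSD of
#'   flexion-extension; the other threat responses scale with it (CyclSD
#'   `x (1 + 0.5 (f - 1))`, LDE `+ 0.45 (f - 1)`, amplitude_fe
#'   `x (1 + 0.25 (f - 1))`, velocity `x (1 - 0.15 (f - 1))`), so
#'   `threat_effect = 1` is an exact null. Default 1.22 (a 22% increase).
#' @param interaction_effect multiplicative factor on secondary-axis MeanSD
#'   (lateral-bending, axial-rotation) for the LBP-and-high-EBS cell in both
#'   conditions. Default 1.25.
#' @param between_subject_sd multiplier on the participant-baseline
#'   dispersions (1 = calibrated defaults).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 15, threat_effect = 1.22,
                          interaction_effect = 1.25,
                          between_subject_sd = 1, seed = NULL) {
  if (n_per_group < 2) stop("`n_per_group` must be at least 2")
  if (threat_effect <= 0 || interaction_effect <= 0)
    stop("effect factors must be positive")
  if (between_subject_sd < 0) stop("`between_subject_sd` must be >= 0")
  structure(list(n_per_group = as.integer(n_per_group),
                 threat_effect = threat_effect,
                 interaction_effect = interaction_effect,
                 between_subject_sd = between_subject_sd,
                 seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic cohort table
#'
#' One row per participant per condition (threat, reference), with group
#' label, integer EBS scores 0-10 drawn to respect the fixed dichotomization
#' (low <= 3, high >= 4), movement metrics with the configured effects and
#' participant-level random baselines, and clinical covariates on their
#' instrument scales. The EBS score before the threat trial is on average
#' higher than before the reference trial and positively correlated with it.
#'
#' @param config a [cohort_config()].
#' @return A data.frame of `4 * n_per_group * 2` rows with attribute
#'   `ground_truth` recording the configured effects.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_preserved_seed(config$seed, {
    bl <- cohort_baselines()
    npg <- config$n_per_group
    cells <- expand.grid(group = c("LBP", "healthy"),
                         ebs_cell = c("low", "high"),
                         stringsAsFactors = FALSE)
    n <- npg * nrow(cells)
    group <- rep(cells$group, each = npg)
    ebs_cell <- rep(cells$ebs_cell, each = npg)

    ebs_threat <- ifelse(ebs_cell == "low",
                         sample(0:3, n, TRUE, prob = c(0.15, 0.25, 0.35, 0.25)),
                         sample(4:8, n, TRUE, prob = c(0.40, 0.25, 0.15, 0.12,
                                                       0.08)))
    ebs_reference <- pmax(0L, pmin(10L, ebs_threat -
                            sample(0:2, n, TRUE, prob = c(0.45, 0.40, 0.15))))

    metrics <- names(bl$log_median)
    base <- sapply(metrics, function(m)
      bl$log_median[[m]] +
        rnorm(n, 0, bl$between_sd[[m]] * config$between_subject_sd))
    lde_base <- bl$lde_mean +
      rnorm(n, 0, bl$lde_between_sd * config$between_subject_sd)

    # secondary-axis inflation for the LBP & high-EBS cell (both conditions)
    hot <- group == "LBP" & ebs_cell == "high"
    base[hot, "mean_sd_lb"] <- base[hot, "mean_sd_lb"] +
      log(config$interaction_effect)
    base[hot, "mean_sd_ar"] <- base[hot, "mean_sd_ar"] +
      log(config$interaction_effect)

    f <- config$threat_effect
    threat_shift <- c(mean_sd_fe = log(f),
                      mean_sd_lb = log(1 + 0.15 * (f - 1)),
                      mean_sd_ar = log(1 + 0.15 * (f - 1)),
                      cycl_sd = log(1 + 0.5 * (f - 1)),
                      amplitude_fe = log(1 + 0.25 * (f - 1)),
                      amplitude_lb = log(1 + 0.05 * (f - 1)),
                      amplitude_ar = log(1 + 0.05 * (f - 1)),
                      velocity = log(1 - 0.15 * (f - 1)))
    lde_shift <- 0.45 * (f - 1)

    one_condition <- function(condition) {
      shift <- if (condition == "threat") threat_shift else
        setNames(numeric(length(metrics)), metrics)
      vals <- sapply(metrics, function(m)
        exp(base[, m] + shift[[m]] + rnorm(n, 0, bl$within_sd[[m]])))
      lde_val <- lde_base + (if (condition == "threat") lde_shift else 0) +
        rnorm(n, 0, bl$lde_within_sd)
      data.frame(participant = sprintf("P%03d", seq_len(n)),
                 group = group, condition = condition,
                 ebs_threat = ebs_threat, ebs_reference = ebs_reference,
                 as.data.frame(vals), lde = lde_val,
                 stringsAsFactors = FALSE)
    }
    tab <- rbind(one_condition("reference"), one_condition("threat"))

    sex <- character(n)
    for (g in unique(group)) {
      i <- which(group == g)
      sex[i] <- sample(rep(c("M", "F"), length.out = length(i)))
    }
    covar <- data.frame(
      participant = sprintf("P%03d", seq_len(n)),
      sex = sex,
      age = round(pmax(18, rnorm(n, 32, 13.5))),
      height = round(rnorm(n, 1.79, 0.09), 2),
      weight = round(pmax(45, rnorm(n, 74.7, 12)), 1),
      odi = ifelse(group == "LBP",
                   pmin(50L, pmax(0L, round(rnorm(n, 15.7, 12.7)))), NA),
      sbst = ifelse(group == "LBP",
                    pmin(9L, pmax(0L, round(rnorm(n, 1.6, 1.5)))), NA),
      nrs = ifelse(group == "LBP",
                   pmin(10L, pmax(0L, round(rnorm(n, 2.4, 2.1)))), NA),
      pcs = pmin(52L, pmax(0L, round(rnorm(n, 13, 7)))),
      pass = pmin(200L, pmax(0L, round(rnorm(n, 48, 22)))),
      stringsAsFactors = FALSE)
    tab <- merge(tab, covar, by = "participant", sort = FALSE)
    tab <- tab[order(tab$condition, tab$participant), ]
    rownames(tab) <- NULL
    attr(tab, "ground_truth") <- list(config = config,
                                      threat_shift = threat_shift,
                                      lde_shift = lde_shift)
    tab
  })
}
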