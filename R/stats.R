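# Cohort statistics: EBS dichotomization, log transform of skewed metrics,
# three-way mixed MANOVA (Wilks' Lambda, Type III with effect coding),
# univariate follow-ups with partial eta squared, and the descriptive
# nonparametric suite.

metric_log_columns <- function() {
  c("mean_sd_fe", "mean_sd_lb", "mean_sd_ar", "cycl_sd",
    "amplitude_fe", "amplitude_lb", "amplitude_ar", "velocity")
}

#' Dichotomize Expected Back Strain
#'
#' Fixed split of the 0-10 EBS rating: `<= 3` is low, `>= 4` is high.
#' Classification is based on the EBS assessed before the first (threat)
#' trial.
#'
#' @param ebs_value integer vector of EBS scores, 0-10.
#' @return Factor with levels `low`, `high`.
#' @export
ebs_split <- function(ebs_value) {
  if (any(is.na(ebs_value)) || any(ebs_value != round(ebs_value)) ||
      any(ebs_value < 0) || any(ebs_value > 10))
    stop("EBS scores must be integers in 0..10")
  factor(ifelse(ebs_value <= 3, "low", "high"), levels = c("low", "high"))
}

#' Log-transform the skewed movement metrics
#'
#' Applies the natural log to MeanSD (three axes), CyclSD, the three
#' amplitudes and velocity; LDE is left untransformed.
#'
#' @param table cohort table containing the metric columns.
#' @return The table with the listed columns replaced by their logs.
#' @export
transform_skewed <- function(table) {
  cols <- intersect(metric_log_columns(), names(table))
  if (!length(cols)) stop("no skewed metric columns found in table")
  for (col in cols) {
    bad <- which(!(table[[col]] > 0))
    if (length(bad))
      stop("non-positive value in column '", col, "' at row(s) ",
           paste(head(bad, 5L), collapse = ", "),
           "; cannot log-transform")
    table[[col]] <- log(table[[col]])
  }
  attr(table, "log_transformed") <- cols
  table
}

# ---- multivariate linear model machinery (Type III, effect coding) --------

# Fit Y ~ group * ebs with sum-to-zero contrasts; return per-term Wilks
# tests. Terms are tested with Type III hypotheses (each term's coefficients
# zero given all others), which under effect coding are the conventional
# unweighted-means hypotheses for a factorial design.
mlm_type3 <- function(Y, group, ebs, label_prefix = "") {
  Y <- as.matrix(Y)
  df <- data.frame(g = factor(group), e = factor(ebs))
  X <- model.matrix(~ g * e, df,
                    contrasts.arg = list(g = "contr.sum", e = "contr.sum"))
  n <- nrow(Y); p <- ncol(Y)
  XtX <- crossprod(X)
  XtXi <- solve(XtX)
  B <- XtXi %*% crossprod(X, Y)
  E <- crossprod(Y) - crossprod(B, XtX) %*% B
  ve <- n - ncol(X)
  if (ve <= p) stop("error degrees of freedom too small for ", p, " DVs")
  asg <- attr(X, "assign")  # 0 intercept, 1 g, 2 e, 3 g:e
  term_names <- c("(Intercept)", "group", "EBS", "group:EBS")
  res <- lapply(0:3, function(term) {
    idx <- which(asg == term)
    L <- diag(ncol(X))[idx, , drop = FALSE]
    LB <- L %*% B
    H <- crossprod(LB, solve(L %*% XtXi %*% t(L))) %*% LB
    wt <- wilks_test(H, E, q = length(idx), ve = ve)
    c(list(effect = paste0(label_prefix, term_names[term + 1L])), wt,
      list(H = H, E = E))
  })
  names(res) <- term_names
  attr(res, "ve") <- ve
  res
}

# Wilks' Lambda and Rao's F approximation (exact for q = 1 or p <= 2).
wilks_test <- function(H, E, q, ve) {
  p <- ncol(E)
  lambda <- det(E) / det(E + H)
  pq <- p * q
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- pq
  df2 <- s * (ve - (p - q + 1) / 2) - (pq - 2) / 2
  lam_s <- lambda^(1 / s)
  Fstat <- (1 - lam_s) / lam_s * df2 / df1
  list(wilks = lambda, F = Fstat, df1 = df1, df2 = df2,
       p = pf(Fstat, df1, df2, lower.tail = FALSE))
}

# reshape the long cohort table into per-participant matrices of condition
# differences (threat - reference) and condition means for the given DVs
split_conditions <- function(table, dvs) {
  need <- c("participant", "group", "condition", dvs)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("cohort table lacks column(s): ",
                         paste(miss, collapse = ", "))
  thr <- table[table$condition == "threat", , drop = FALSE]
  ref <- table[table$condition == "reference", , drop = FALSE]
  ids <- sort(unique(table$participant))
  bad <- ids[!(ids %in% thr$participant) | !(ids %in% ref$participant)]
  if (length(bad))
    stop("participant(s) missing a condition: ", paste(bad, collapse = ", "))
  thr <- thr[match(ids, thr$participant), , drop = FALSE]
  ref <- ref[match(ids, ref$participant), , drop = FALSE]
  Yt <- as.matrix(thr[, dvs, drop = FALSE])
  Yr <- as.matrix(ref[, dvs, drop = FALSE])
  list(ids = ids, group = thr$group,
       ebs = ebs_split(thr$ebs_threat),
       D = Yt - Yr, M = (Yt + Yr) / 2)
}

#' Three-way mixed MANOVA
#'
#' Tests the within-subject factor (threat vs reference condition) and the
#' between-subject factors (group, dichotomized EBS) and their interactions
#' on a set of dependent variables. With a two-level within factor the
#' multivariate mixed model reduces exactly to two between-subject MANOVAs:
#' per-participant condition differences carry the within-subject effects
#' (the threat main effect is the test of the intercept) and per-participant
#' condition means carry the between-subject effects. Type III hypotheses
#' with effect coding; Wilks' Lambda with Rao's F (exact for these 1-df
#' effects). For the 60-participant 2x2 design the within-effect denominator
#' dfs are 52 for 5 DVs and 53 for 4 DVs.
#'
#' @param table long-format cohort table (one row per participant per
#'   condition) with columns `participant`, `group`, `condition`,
#'   `ebs_threat` and the dependent variables.
#' @param dvs character vector of dependent-variable column names.
#' @return A `mixed_manova` object: data.frame `multivariate` (effect,
#'   Wilks, F, df1, df2, p) and data.frame `univariate` (effect, dv, F, df1,
#'   df2, p, partial eta squared for every effect-DV pair).
#' @export
mixed_manova <- function(table, dvs) {
  sc <- split_conditions(table, dvs)
  p <- length(dvs)
  if (p < 1L) stop("need at least one dependent variable")
  within <- mlm_type3(sc$D, sc$group, sc$ebs, label_prefix = "threat")
  names(within) <- c("threat", "threat:group", "threat:EBS",
                     "threat:group:EBS")
  for (i in seq_along(within))
    within[[i]]$effect <- names(within)[i]
  between <- mlm_type3(sc$M, sc$group, sc$ebs)
  between <- between[c("group", "EBS", "group:EBS")]

  all_eff <- c(within, between)
  multiv <- do.call(rbind, lapply(all_eff, function(w)
    data.frame(effect = w$effect, wilks = w$wilks, F = w$F,
               df1 = w$df1, df2 = w$df2, p = w$p)))
  rownames(multiv) <- NULL

  ve <- attr(within, "ve")
  univ <- do.call(rbind, lapply(all_eff, function(w) {
    data.frame(effect = w$effect, dv = dvs,
               F = diag(as.matrix(w$H)) / (diag(as.matrix(w$E)) / ve),
               df1 = 1L, df2 = ve,
               p = pf(diag(as.matrix(w$H)) / (diag(as.matrix(w$E)) / ve),
                      1, ve, lower.tail = FALSE),
               eta_sq = diag(as.matrix(w$H)) /
                 (diag(as.matrix(w$H)) + diag(as.matrix(w$E))))
  }))
  rownames(univ) <- NULL
  structure(list(multivariate = multiv, univariate = univ, dvs = dvs,
                 n = length(sc$ids), error_df = ve),
            class = "mixed_manova")
}

#' @export
print.mixed_manova <- function(x, ...) {
  cat(sprintf("Mixed MANOVA: %d participants, %d DVs (%s), error df = %d\n",
              x$n, length(x$dvs), paste(x$dvs, collapse = ", "), x$error_df))
  m <- x$multivariate
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-18s Wilks = %.3f  F(%d, %g) = %.3f  p = %.4f\n",
                m$effect[i], m$wilks[i], m$df1[i], m$df2[i], m$F[i], m$p[i]))
  invisible(x)
}

#' Univariate mixed-ANOVA follow-up for one dependent variable
#'
#' Mixed ANOVA with the same factors as [mixed_manova()] for a single DV,
#' reporting F, p and partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`; for a 1-df effect this equals
#' `F / (F + df_error)`).
#'
#' @param table long-format cohort table.
#' @param dv dependent-variable column name.
#' @return Data.frame with one row per effect: F, df1, df2, p, eta_sq.
#' @export
univariate_followup <- function(table, dv) {
  res <- mixed_manova(table, dvs = dv)
  out <- res$univariate
  out$wilks <- NULL
  out
}

#' Partial eta squared from sums of squares
#'
#' @param ss_effect,ss_error effect and error sums of squares.
#' @return `ss_effect / (ss_effect + ss_error)`.
#' @export
partial_eta_sq <- function(ss_effect, ss_error) {
  ss_effect / (ss_effect + ss_error)
}

#' Descriptive nonparametric comparisons
#'
#' Runs the descriptive battery on a participant-level metadata table:
#' Mann-Whitney U tests between groups for the ordinal scores (EBS both
#' conditions, PCS, PASS), a Wilcoxon signed-rank test of EBS before the
#' threat vs the reference condition, independent t-tests for height and
#' weight, and the Spearman rank correlation between the two EBS scores.
#' When all paired differences are zero the signed-rank p-value is reported
#' as 1 (no evidence of a shift).
#'
#' @param meta participant-level data.frame with columns `group`,
#'   `ebs_threat`, `ebs_reference` and optionally `pcs`, `pass`, `height`,
#'   `weight`.
#' @return Data.frame with columns test, variable, statistic, p.
#' @export
nonparametric_suite <- function(meta) {
  if (!all(c("group", "ebs_threat", "ebs_reference") %in% names(meta)))
    stop("metadata must contain group, ebs_threat, ebs_reference")
  g <- factor(meta$group)
  if (nlevels(g) != 2L || any(table(g) == 0L))
    stop("exactly two non-empty groups required")
  lv <- levels(g)
  rows <- list()
  add <- function(test, variable, statistic, p)
    rows[[length(rows) + 1L]] <<- data.frame(test = test, variable = variable,
                                             statistic = statistic, p = p)

  for (v in intersect(c("ebs_threat", "ebs_reference", "pcs", "pass"),
                      names(meta))) {
    x <- meta[[v]][g == lv[1L]]
    y <- meta[[v]][g == lv[2L]]
    if (length(unique(c(x, y))) == 1L)
      stop("all values tied for '", v, "'; Mann-Whitney U undefined")
    w <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    add("mann_whitney_u", v, unname(w$statistic), w$p.value)
  }

  d <- meta$ebs_threat - meta$ebs_reference
  if (all(d == 0)) {
    add("wilcoxon_signed_rank", "ebs_threat_vs_reference", 0, 1)
  } else {
    w <- suppressWarnings(wilcox.test(meta$ebs_threat, meta$ebs_reference,
                                      paired = TRUE, exact = FALSE))
    add("wilcoxon_signed_rank", "ebs_threat_vs_reference",
        unname(w$statistic), w$p.value)
  }

  for (v in intersect(c("height", "weight"), names(meta))) {
    tt <- t.test(meta[[v]][g == lv[1L]], meta[[v]][g == lv[2L]],
                 var.equal = TRUE)
    add("t_test", v, unname(tt$statistic), tt$p.value)
  }

  ct <- suppressWarnings(cor.test(meta$ebs_threat, meta$ebs_reference,
                                  method = "spearman"))
  add("spearman", "ebs_threat_vs_reference", unname(ct$estimate), ct$p.value)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
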