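test_that("EBS dichotomization uses the fixed split", {
  expect_equal(as.character(ebs_split(c(0, 3, 4, 10))),
               c("low", "low", "high", "high"))
  expect_error(ebs_split(11), "0..10")
  expect_error(ebs_split(2.5), "integers")
})

test_that("log transform hits the skewed metrics and spares the LDE", {
  co <- generate_cohort(cohort_config(seed = 1))
  lg <- transform_skewed(co)
  expect_equal(lg$lde, co$lde)
  expect_equal(exp(lg$mean_sd_fe), co$mean_sd_fe, tolerance = 1e-12)
  expect_equal(exp(lg$velocity), co$velocity, tolerance = 1e-12)
  co$cycl_sd[3] <- -0.1
  expect_error(transform_skewed(co), "cycl_sd")
  one <- co[1, ]
  one$mean_sd_fe <- 1
  expect_equal(transform_skewed(one)$mean_sd_fe, 0)
})

test_that("mixed MANOVA reports the design's degrees of freedom", {
  co <- generate_cohort(cohort_config(seed = 2))
  lg <- transform_skewed(co)
  m5 <- mixed_manova(lg, c("mean_sd_fe", "mean_sd_ar", "mean_sd_lb",
                           "cycl_sd", "lde"))
  expect_true(all(m5$multivariate$df1 == 5))
  expect_true(all(m5$multivariate$df2 == 52))
  expect_equal(m5$error_df, 56L)
  m4 <- mixed_manova(lg, c("amplitude_fe", "amplitude_ar", "amplitude_lb",
                           "velocity"))
  expect_true(all(m4$multivariate$df1 == 4))
  expect_true(all(m4$multivariate$df2 == 53))
  expect_true(all(m5$multivariate$wilks > 0 & m5$multivariate$wilks <= 1))
  expect_true(all(m5$univariate$eta_sq >= 0 & m5$univariate$eta_sq < 1))
})

test_that("Wilks' Lambda matches an independent reference implementation", {
  dvs <- c("mean_sd_fe", "mean_sd_ar", "mean_sd_lb", "cycl_sd", "lde")
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  for (s in 1:10) {
    co <- generate_cohort(cohort_config(seed = 100 + s))
    lg <- transform_skewed(co)
    mine <- mixed_manova(lg, dvs)
    thr <- lg[lg$condition == "threat", ]
    ref <- lg[lg$condition == "reference", ]
    ids <- sort(unique(lg$participant))
    thr <- thr[match(ids, thr$participant), ]
    ref <- ref[match(ids, ref$participant), ]
    D <- as.matrix(thr[, dvs]) - as.matrix(ref[, dvs])
    M <- (as.matrix(thr[, dvs]) + as.matrix(ref[, dvs])) / 2
    g <- factor(thr$group)
    e <- ebs_split(thr$ebs_threat)
    wilks_of <- function(st, term) {
      w <- st$multivariate.tests[[term]]
      det(w$SSPE) / det(w$SSPE + w$SSPH)
    }
    sw <- summary(car::Anova(lm(D ~ g * e), type = 3), multivariate = TRUE)
    sb <- summary(car::Anova(lm(M ~ g * e), type = 3), multivariate = TRUE)
    mv <- mine$multivariate
    expect_equal(mv$wilks[mv$effect == "threat"],
                 wilks_of(sw, "(Intercept)"), tolerance = 1e-6)
    expect_equal(mv$wilks[mv$effect == "threat:group"],
                 wilks_of(sw, "g"), tolerance = 1e-6)
    expect_equal(mv$wilks[mv$effect == "threat:group:EBS"],
                 wilks_of(sw, "g:e"), tolerance = 1e-6)
    expect_equal(mv$wilks[mv$effect == "group"],
                 wilks_of(sb, "g"), tolerance = 1e-6)
    expect_equal(mv$wilks[mv$effect == "group:EBS"],
                 wilks_of(sb, "g:e"), tolerance = 1e-6)
  }
})

test_that("partial eta squared identities hold", {
  expect_equal(partial_eta_sq(0, 10), 0)
  # 1-df effect: eta^2 = F / (F + df_error); reproduces 0.259 from F = 19.565
  F <- 19.565
  expect_equal(F / (F + 56), 0.259, tolerance = 5e-4)
  # identity against explicit SS decomposition on a synthetic univariate fit
  co <- generate_cohort(cohort_config(seed = 7))
  lg <- transform_skewed(co)
  uf <- univariate_followup(lg, "mean_sd_fe")
  thr <- lg[lg$condition == "threat", ]
  ref <- lg[lg$condition == "reference", ]
  ids <- sort(unique(lg$participant))
  d <- thr$mean_sd_fe[match(ids, thr$participant)] -
    ref$mean_sd_fe[match(ids, ref$participant)]
  g <- factor(thr$group[match(ids, thr$participant)])
  e <- ebs_split(thr$ebs_threat[match(ids, thr$participant)])
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  fit <- lm(d ~ g * e)
  ss_err <- sum(residuals(fit)^2)
  # threat main effect = intercept hypothesis on the difference scores
  b0 <- coef(fit)[["(Intercept)"]]
  X <- model.matrix(fit)
  ss_threat <- b0^2 / solve(crossprod(X))[1, 1]
  eta_direct <- ss_threat / (ss_threat + ss_err)
  expect_equal(uf$eta_sq[uf$effect == "threat"], eta_direct,
               tolerance = 1e-10)
  expect_equal(uf$F[uf$effect == "threat"],
               (ss_threat / 1) / (ss_err / 56), tolerance = 1e-10)
})

test_that("missing conditions and singular designs are rejected", {
  co <- generate_cohort(cohort_config(seed = 3))
  broken <- co[-which(co$participant == "P001" &
                        co$condition == "threat"), ]
  expect_error(mixed_manova(transform_skewed(broken), "lde"), "P001")
})

test_that("Mann-Whitney U equals the exhaustive pair-count oracle", {
  x <- c(1.2, 3.4, 2.2)
  y <- c(0.5, 3.4, 5.0)
  meta <- data.frame(group = rep(c("a", "b"), each = 3),
                     ebs_threat = c(1, 2, 3, 2, 3, 4),
                     ebs_reference = c(1, 2, 2, 2, 2, 3),
                     pcs = c(x, y))
  out <- nonparametric_suite(meta)
  u <- out$statistic[out$test == "mann_whitney_u" & out$variable == "pcs"]
  expect_equal(u, u_oracle(x, y))
})

test_that("degenerate paired and correlated scores behave as documented", {
  meta <- data.frame(group = rep(c("a", "b"), each = 4),
                     ebs_threat = c(1, 2, 3, 4, 2, 3, 4, 5),
                     ebs_reference = c(1, 2, 3, 4, 2, 3, 4, 5))
  out <- nonparametric_suite(meta)
  # identical paired samples: zero differences, p reported as 1
  w <- out[out$test == "wilcoxon_signed_rank", ]
  expect_equal(w$p, 1)
  # perfectly monotone paired scores: Spearman rho = 1
  s <- out[out$test == "spearman", ]
  expect_equal(s$statistic, 1)
  # all-tied group comparison is an error
  meta2 <- meta
  meta2$ebs_threat <- 2
  meta2$ebs_reference <- 1
  expect_error(nonparametric_suite(meta2), "tied")
})
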