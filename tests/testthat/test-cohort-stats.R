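two_rater_records <- function() {
  data.frame(
    subject_id = rep(c("S1", "S2"), each = 2),
    rater_id = rep(c("R1", "R2"), 2),
    sex = rep(c("male", "female"), each = 2),
    spleen_volume = c(180, 190, 150, 150),
    spleen_length = c(10, 10.4, 8.5, 8.7),
    l1_area = c(7.5, NA, 7.2, 7.4), stringsAsFactors = FALSE)
}

test_that("rater averaging is the field-wise mean over available values", {
  avg <- average_raters(two_rater_records())
  expect_equal(nrow(avg), 2)
  expect_equal(avg$spleen_volume, c(185, 150))
  expect_equal(avg$spleen_length, c(10.2, 8.6))
  # missing value from one rater: the other's value is used and flagged
  expect_equal(avg$l1_area, c(7.5, 7.3))
  expect_identical(avg$incomplete_pair, c(TRUE, FALSE))
  expect_identical(avg$single_rater, c(FALSE, FALSE))
})

test_that("identical duplicate records average to themselves", {
  rec <- two_rater_records()
  rec$spleen_volume <- rep(c(180, 150), each = 2)
  avg <- average_raters(rec)
  expect_equal(avg$spleen_volume, c(180, 150))
})

test_that("single-rater subjects pass through flagged; >2 raters error", {
  rec <- two_rater_records()[c(1, 3, 4), ]
  avg <- average_raters(rec)
  expect_identical(avg$single_rater, c(TRUE, FALSE))
  expect_equal(avg$spleen_volume[1], 180)
  three <- rbind(two_rater_records(),
                 data.frame(subject_id = "S1", rater_id = "R3", sex = "male",
                            spleen_volume = 170, spleen_length = 9.9,
                            l1_area = 7.1))
  expect_error(average_raters(three), "more than two raters.*S1")
})

test_that("volume classification uses a strict threshold and partitions", {
  expect_identical(as.character(classify_volume(c(400, 400 + 1e-9, 120), 400)),
                   c("normal", "high", "normal"))
  expect_error(classify_volume(300, -1))
  set.seed(14)
  vols <- c(rnorm(340, 200, 80), rep(NA, 5))
  cls <- classify_volume(vols, 300)
  expect_identical(sum(cls == "normal", na.rm = TRUE) +
                   sum(cls == "high", na.rm = TRUE) + sum(is.na(cls)),
                   length(vols))
  # threshold at the empirical 90th percentile marks ~10% high
  thr <- quantile(vols, 0.9, na.rm = TRUE)
  frac_high <- mean(classify_volume(vols, thr) == "high", na.rm = TRUE)
  expect_lt(abs(frac_high - 0.10), 0.01)
})

test_that("describe_cohort returns mean, n-1 SD and SEM", {
  cohort <- data.frame(spleen_volume = c(1, 2, 3), sex = "male")
  d <- describe_cohort(cohort, variables = "spleen_volume")
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(d$sem, 1 / sqrt(3), tolerance = 1e-10)
  # single observation: mean only
  one <- describe_cohort(data.frame(spleen_volume = 5),
                         variables = "spleen_volume")
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sd))
})

test_that("describe_cohort is permutation invariant and SEM-consistent", {
  set.seed(3)
  cohort <- data.frame(spleen_volume = rnorm(50, 200, 40),
                       spleen_length = rnorm(50, 9, 2),
                       sex = sample(c("male", "female"), 50, TRUE))
  d1 <- describe_cohort(cohort, group_by = "sex")
  d2 <- describe_cohort(cohort[sample(50), ], group_by = "sex")
  expect_equal(d1, d2)
  expect_equal(d1$sem * sqrt(d1$n), d1$sd)
})

test_that("a noiseless line is fit exactly", {
  cohort <- data.frame(x = 1:20, spleen_volume = 2 * (1:20) + 1)
  fit <- ols_fit(cohort, predictors = "x")
  expect_equal(fit$coefficients$B, c(1, 2), tolerance = 1e-10)
  expect_equal(fit$coefficients$beta[2], 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("standardized beta equals Pearson r with one predictor", {
  set.seed(5)
  cohort <- data.frame(x = rnorm(80))
  cohort$spleen_volume <- 3 * cohort$x + rnorm(80)
  fit <- ols_fit(cohort, predictors = "x")
  expect_equal(fit$coefficients$beta[2], cor(cohort$x, cohort$spleen_volume),
               tolerance = 1e-10)
})

test_that("the full coefficient table matches the normal-equations oracle", {
  set.seed(6)
  n <- 120
  preds <- splenometry:::REGRESSION_PREDICTORS
  cohort <- as.data.frame(matrix(rnorm(n * 9, mean = 10), n, 9))
  names(cohort) <- preds
  cohort$spleen_volume <- -50 + 30 * cohort$spleen_length +
    6 * cohort$abd_tv + rnorm(n, 0, 15)
  fit <- ols_fit(cohort)

  # brute force (X'X)^-1 X'y with textbook formulas, an independent route
  X <- cbind(1, as.matrix(cohort[, preds]))
  y <- cohort$spleen_volume
  B <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% B
  s2 <- sum(res^2) / (n - 9 - 1)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  f <- (r2 / 9) / ((1 - r2) / (n - 9 - 1))
  expect_lt(max(abs(fit$coefficients$B - drop(B))) / max(abs(B)), 1e-8)
  expect_lt(max(abs(fit$coefficients$SE - se) / se), 1e-8)
  expect_rel_equal(fit$r_squared, r2, 1e-10)
  expect_rel_equal(fit$anova_f, f, 1e-10)
  expect_equal(fit$coefficients$t, fit$coefficients$B / fit$coefficients$SE)
  # cross-check p-values against the stock fitter
  lmfit <- summary(lm(spleen_volume ~ ., cohort[, c("spleen_volume", preds)]))
  expect_equal(unname(fit$coefficients$p), unname(lmfit$coefficients[, 4]),
               tolerance = 1e-10)
})

test_that("rank deficiency and constant predictors are named", {
  set.seed(7)
  cohort <- data.frame(a = rnorm(30), spleen_volume = rnorm(30))
  cohort$b <- 2 * cohort$a  # exactly collinear
  expect_error(ols_fit(cohort, predictors = c("a", "b")), "collinear.*b")
  cohort$c <- 5
  expect_error(ols_fit(cohort, predictors = c("a", "c")), "constant.*c")
})

test_that("listwise deletion reports the retained n", {
  set.seed(9)
  cohort <- data.frame(x = rnorm(40), z = rnorm(40))
  cohort$spleen_volume <- cohort$x + rnorm(40)
  cohort$z[1:5] <- NA
  fit <- ols_fit(cohort, predictors = c("x", "z"))
  expect_equal(fit$n, 35)
  expect_equal(fit$n_dropped, 5)
})

test_that("run_study emits all four tables on a smoke cohort", {
  set.seed(10)
  cohort <- generate_cohort(smoke_cohort(8, 12, seed = 3))$truth
  names(cohort)[names(cohort) == "true_volume"] <- "spleen_volume"
  names(cohort)[names(cohort) == "true_length"] <- "spleen_length"
  out <- withr::local_tempdir()
  res <- run_study(cohort, volume_threshold = 300, out_dir = out)
  expect_true(all(file.exists(file.path(out, c("table3.csv", "table4.csv",
                                               "table5.csv", "table6.csv",
                                               "report.txt")))))
  expect_equal(sum(res$classification$frequency), 20)
  expect_s3_class(res$regression, "regression_result")
  # averaging then describing equals describing per-subject means
  expect_equal(res$descriptives,
               describe_cohort(cohort))
})
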