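test_that("coefficient of variation: closed form, scale invariance, errors", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50)
  x <- c(98.3, 100.1, 101.2, 99.4, 100.6)
  expect_equal(coefficient_of_variation(3.7 * x),
               coefficient_of_variation(x), tolerance = 1e-12)
  # five repeats constructed with SD/mean = 0.0117
  y <- 100 + c(-1, -0.5, 0, 0.5, 1) * 0.0117 * 100 / sd(c(-1, -0.5, 0, 0.5, 1))
  expect_equal(coefficient_of_variation(y), 1.17, tolerance = 1e-6)
  expect_error(coefficient_of_variation(c(5)), "2 values")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero")
})

test_that("ICC equals 1 for duplicated raters and matches the fixture estimate", {
  x <- c(10.2, 11.5, 9.8, 12.4, 10.9)
  expect_equal(icc_two_way_random(cbind(x, x))$icc, 1, tolerance = 1e-9)
  t2 <- read.csv(aosa_fixture("table2_interobserver"))
  rep <- icc_two_way_random(measurement_table(
    data.frame(patient = t2$patient, phase = t2$phase,
               observer = t2$observer, `repeat` = 1L, metric = "aosa_deg",
               value = t2$aosa_deg, check.names = FALSE)), form = "single")
  expect_equal(round(rep$icc, 2), 0.96)
  expect_equal(rep$n_subjects, 10L)
  expect_true(rep$icc_ci95[1] <= rep$icc && rep$icc <= rep$icc_ci95[2])
})

test_that("ICC point estimate agrees with the aov variance-components oracle", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    k <- sample(2:4, 1)
    X <- matrix(rnorm(n * k, sd = 1), n, k) +
      rnorm(n, sd = runif(1, 0.2, 3)) +
      rep(rnorm(k, sd = runif(1, 0, 1)), each = n)
    expect_equal(icc_two_way_random(X)$icc, icc_oracle_aov(X),
                 tolerance = 1e-9)
  }
})

test_that("uncorrelated raters give an ICC near zero inside its own CI", {
  set.seed(99)
  X <- matrix(rnorm(40), 20, 2)
  rep <- icc_two_way_random(X)
  expect_lt(abs(rep$icc), 0.4)
  expect_true(rep$icc_ci95[1] <= rep$icc && rep$icc <= rep$icc_ci95[2])
})

test_that("mean-rating form applies the Spearman-Brown style step-up", {
  set.seed(31)
  X <- matrix(rnorm(24), 12, 2) + rnorm(12, sd = 2)
  single <- icc_two_way_random(X, form = "single")
  meank <- icc_two_way_random(X, form = "mean_k")
  expect_gt(meank$icc, single$icc)
  expect_error(icc_two_way_random(X[, 1, drop = FALSE]), "2 subjects")
  Xna <- X; Xna[2, 1] <- NA
  expect_error(icc_two_way_random(Xna), "incomplete")
})

test_that("paired comparison reproduces the aneurysm-subgroup t statistic", {
  t3 <- read.csv(aosa_fixture("table3_aosa"))
  an <- t3[t3$pathology == "aneurysm", ]
  cmp <- paired_t(an$aosa_pre_mean, an$aosa_post_mean)
  expect_equal(cmp$t_stat, 3.47, tolerance = 0.005)
  expect_equal(cmp$df, 3)
  expect_lt(cmp$p_value, 0.05)
  expect_equal(cmp$mean_diff, mean(an$aosa_post_mean - an$aosa_pre_mean))
})

test_that("tortuosity shows no pre/post difference on the cohort fixture", {
  t4 <- read.csv(aosa_fixture("table4_ascending"))
  wide <- tapply(t4$tortuosity, list(t4$patient, t4$phase), mean)
  cmp <- paired_t(wide[, "pre"], wide[, "post"])
  expect_gt(cmp$p_value, 0.05)
})

test_that("paired_t is antisymmetric and rejects degenerate input", {
  pre <- c(10, 12, 9, 14); post <- c(11, 15, 9.5, 13)
  a <- paired_t(pre, post); b <- paired_t(post, pre)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$mean_diff, -b$mean_diff)
  expect_error(paired_t(pre, pre + 2), "zero-variance")
  expect_error(paired_t(pre, post[1:3]), "pair")
  # a pure shift with varying pairs keeps mean_diff = shift
  expect_equal(paired_t(pre, pre + c(2, 2.5, 1.5, 2))$mean_diff, 2)
})

test_that("percent change follows the printed sign convention", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(round(percent_change(113.62, 107.83), 1), -5.1)
  # printed as +2.91 although the printed means give 2.9153; match to the
  # table's own rounding slack
  expect_equal(percent_change(108.05, 111.2), 2.91, tolerance = 0.0075 / 2.91)
  expect_equal(percent_change(113.62, 107.83, "pre_minus_post"),
               -percent_change(113.62, 107.83))
  expect_error(percent_change(0, 5), "zero")
})

test_that("cohort summaries reproduce the printed subgroup aggregates", {
  t3 <- read.csv(aosa_fixture("table3_aosa"))
  long <- data.frame(patient = rep(t3$patient, 2),
                     pathology = rep(t3$pathology, 2),
                     phase = rep(c("pre", "post"), each = nrow(t3)),
                     metric = "aosa_deg",
                     value = c(t3$aosa_pre_mean, t3$aosa_post_mean))
  cs <- cohort_summary(long, group_cols = c("pathology", "phase"))
  an_pre <- cs$summary[cs$summary$pathology == "aneurysm" &
                       cs$summary$phase == "pre", ]
  expect_equal(round(an_pre$mean, 2), 112.36)
  # recomputed SD is 8.2049; the table prints 8.21
  expect_equal(an_pre$sd, 8.21, tolerance = 0.0075 / 8.21)
  # single-observation group: mean returned, SD flagged NA
  one <- cohort_summary(long[long$pathology == "dissection" &
                             long$phase == "pre", ],
                        group_cols = "pathology")
  expect_equal(one$summary$mean, 113.62)
  expect_true(is.na(one$summary$sd))
  expect_error(cohort_summary(long, group_cols = "nope"), "not found")
})

test_that("measurement tables validate schema, phases, and uniqueness", {
  good <- data.frame(patient = 1, phase = "pre", observer = 1,
                     `repeat` = 1:5, metric = "aosa_deg",
                     value = rnorm(5, 110), check.names = FALSE)
  expect_s3_class(measurement_table(good), "measurement_table")
  expect_error(measurement_table(good[, -6]), "missing")
  bad <- good; bad$phase <- "mid"
  expect_error(measurement_table(bad), "phase")
  dup <- rbind(good, good[1, ])
  expect_error(measurement_table(dup), "duplicate")
  path <- tempfile(fileext = ".csv")
  write.csv(good, path, row.names = FALSE)
  expect_equal(nrow(read_measurement_table(path)), 5)
  unlink(path)
})
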