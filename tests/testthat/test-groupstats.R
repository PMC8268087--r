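# Outlier exclusion and the nested group comparison.

make_obs <- function(values_by_specimen, group_of_specimen) {
  tibble::tibble(
    specimen = rep(names(values_by_specimen),
                   lengths(values_by_specimen)),
    group = rep(group_of_specimen[names(values_by_specimen)],
                lengths(values_by_specimen)),
    value = unlist(values_by_specimen, use.names = FALSE))
}

test_that("three-SD rule excludes exactly the constructed outlier", {
  x <- c(rep(1, 5))
  m <- mean(c(x, 10)); s <- sd(c(x, 10))
  spike <- m + 4 * s
  df <- tibble::tibble(value = c(x, spike), group = "g", structure = "AF",
                       stage = "TS24")
  out <- exclude_outliers(df)
  expect_equal(nrow(out$excluded), 1)
  expect_equal(out$excluded$value, spike)

  # nothing within 3 SD is touched
  df2 <- tibble::tibble(value = c(1, 2, 3, 4, 5), group = "g",
                        structure = "AF", stage = "TS24")
  expect_equal(nrow(exclude_outliers(df2)$excluded), 0)
})

test_that("one planted 8-sigma point among N(0,1) draws is the sole exclusion", {
  set.seed(31)
  vals <- c(rnorm(10), 8)
  df <- tibble::tibble(value = vals, group = "g", structure = "AF",
                       stage = "TS24")
  out <- exclude_outliers(df)
  expect_equal(nrow(out$excluded), 1)
  expect_equal(out$excluded$value, 8)
  expect_equal(nrow(out$kept), 10)
})

test_that("exclusion needs at least two observations per cell", {
  df <- tibble::tibble(value = 1, group = "g", structure = "AF",
                       stage = "TS24")
  expect_error(exclude_outliers(df),
               class = "ivdmech_error_insufficient_data")
})

test_that("3 + 3 specimens give the F(1, 4) containment df pair", {
  set.seed(5)
  vals <- setNames(lapply(1:6, function(i) rnorm(6, i)), paste0("s", 1:6))
  grp <- setNames(rep(c("control", "mdg"), each = 3), paste0("s", 1:6))
  cmp <- compare_groups(make_obs(vals, grp))
  expect_equal(cmp$df1, 1)
  expect_equal(cmp$df2, 4)
  # df2 depends on specimen counts only, not indent counts
  vals2 <- setNames(lapply(1:6, function(i) rnorm(20, i)), paste0("s", 1:6))
  cmp2 <- compare_groups(make_obs(vals2, grp))
  expect_equal(cmp2$df2, 4)
})

test_that("balanced comparison equals the specimen-mean ANOVA oracle", {
  set.seed(17)
  vals <- setNames(lapply(1:6, function(i) rnorm(6, i / 2)), paste0("s", 1:6))
  grp <- setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6))
  cmp <- compare_groups(make_obs(vals, grp))

  # brute-force oracle from the sums of squares of the 6 specimen means
  m <- vapply(vals, mean, numeric(1))
  ga <- mean(m[1:3]); gb <- mean(m[4:6]); gg <- mean(m)
  ss_between <- 3 * ((ga - gg)^2 + (gb - gg)^2)
  ss_within <- sum((m[1:3] - ga)^2) + sum((m[4:6] - gb)^2)
  F_oracle <- (ss_between / 1) / (ss_within / 4)
  p_oracle <- pf(F_oracle, 1, 4, lower.tail = FALSE)
  expect_equal(cmp$F_value, F_oracle, tolerance = 1e-10)
  expect_equal(cmp$p_value, p_oracle, tolerance = 1e-10)
})

test_that("comparison agrees with a REML mixed model on balanced data", {
  skip_if_not_installed("lmerTest")
  set.seed(23)
  spec_eff <- rnorm(6, rep(c(0, 1), each = 3), 2)  # clear specimen variance
  df <- make_obs(setNames(lapply(spec_eff, function(m) rnorm(6, m, 0.3)),
                          paste0("s", 1:6)),
                 setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6)))
  cmp <- compare_groups(df)
  lmm <- suppressMessages(lmerTest::lmer(value ~ group + (1 | specimen),
                                         data = df))
  an <- stats::anova(lmm)
  expect_equal(cmp$F_value, an$`F value`[1], tolerance = 1e-6)
  expect_equal(cmp$df2, round(an$DenDF[1]))
})

test_that("F and p are invariant to shifting and rescaling", {
  set.seed(8)
  df <- make_obs(setNames(lapply(1:6, function(i) rnorm(5, i)),
                          paste0("s", 1:6)),
                 setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6)))
  c0 <- compare_groups(df)
  df2 <- dplyr::mutate(df, value = 10 + 3 * value)
  c2 <- compare_groups(df2)
  expect_equal(c0$F_value, c2$F_value, tolerance = 1e-10)
  expect_equal(c0$p_value, c2$p_value, tolerance = 1e-10)
})

test_that("under the null, the type-I error rate sits near 0.05", {
  set.seed(1234)
  reject <- logical(500)
  for (r in seq_len(500)) {
    spec_mean <- rnorm(6, 0, 1)               # specimen effects, no group effect
    df <- tibble::tibble(
      specimen = rep(paste0("s", 1:6), each = 6),
      group = rep(c("a", "b"), each = 18),
      value = rnorm(36, rep(spec_mean, each = 6), 0.5))
    reject[r] <- compare_groups(df)$p_value < 0.05
  }
  rate <- mean(reject)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("groups with fewer than two specimens are rejected", {
  df <- tibble::tibble(specimen = c("s1", "s1", "s2", "s2", "s3", "s3"),
                       group = c("a", "a", "b", "b", "b", "b"),
                       value = rnorm(6))
  expect_error(compare_groups(df),
               class = "ivdmech_error_insufficient_replication")
})

test_that("permuting specimen group labels permutes F symmetrically", {
  set.seed(77)
  m <- rnorm(4)
  df <- tibble::tibble(specimen = rep(paste0("s", 1:4), each = 3),
                       value = rnorm(12, rep(m, each = 3)))
  labelings <- list(c("a", "a", "b", "b"), c("a", "b", "a", "b"),
                    c("b", "a", "a", "b"))
  Fs <- vapply(labelings, function(lab) {
    df$group <- rep(lab, each = 3)
    compare_groups(df)$F_value
  }, numeric(1))
  # complementary labelings give identical F
  df$group <- rep(c("b", "b", "a", "a"), each = 3)
  expect_equal(compare_groups(df)$F_value, Fs[1], tolerance = 1e-12)
  expect_true(all(is.finite(Fs)))
})
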