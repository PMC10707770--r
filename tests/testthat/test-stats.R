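# Statistical stage: arcsine transform, nested RM-ANOVA, Tukey letters, R^2.

test_that("arcsine transform matches closed forms and is monotone", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  expect_equal(arcsine_transform(0.5), pi / 4)
  p <- seq(0, 1, length.out = 101)
  tr <- arcsine_transform(p)
  expect_true(all(diff(tr) > 0))
  expect_true(all(tr >= 0 & tr <= pi / 2))
  expect_error(arcsine_transform(-0.1), "domain error")
  expect_error(arcsine_transform(1.1), "domain error")
})

test_that("balanced split-plot decomposition matches hand computation", {
  # 2 treatments x 3 fruits x 3 zones, one value per fruit x zone
  set.seed(8)
  d <- expand.grid(treatment = c("ctl", "rdi"), fruit = 1:3,
                   zone = c("In", "Md", "Ex"))
  d$y <- round(rnorm(nrow(d), 10, 2), 2)
  fit <- nested_rm_anova(d, "y", between = "treatment")
  eff <- tidy(fit)

  # independent oracle: direct mean-based sums of squares
  t_lv <- unique(d$treatment); z_lv <- unique(d$zone)
  grand <- mean(d$y)
  zc <- length(z_lv); fc <- 3; tc <- length(t_lv)
  ybar_t <- tapply(d$y, d$treatment, mean)
  ybar_u <- tapply(d$y, interaction(d$treatment, d$fruit), mean)
  ybar_z <- tapply(d$y, d$zone, mean)
  ybar_tz <- tapply(d$y, interaction(d$treatment, d$zone), mean)
  ss_treat <- zc * fc * sum((ybar_t - grand)^2)
  trt_of_u <- tapply(d$treatment, interaction(d$treatment, d$fruit),
                     function(x) as.character(x[1]))
  ss_fruit <- zc * sum((ybar_u - ybar_t[trt_of_u])^2)
  ss_zone <- tc * fc * sum((ybar_z - grand)^2)
  tz <- expand.grid(t = t_lv, z = z_lv)
  ss_tz <- fc * sum((ybar_tz[paste(tz$t, tz$z, sep = ".")] -
                       ybar_t[tz$t] - ybar_z[tz$z] + grand)^2)
  ss_total <- sum((d$y - grand)^2)
  ss_resid <- ss_total - ss_treat - ss_fruit - ss_zone - ss_tz

  get <- function(term, col) eff[[col]][eff$term == term]
  expect_equal(get("treatment", "sum_sq"), ss_treat, tolerance = 1e-10)
  expect_equal(get("fruit(between residual)", "sum_sq"), ss_fruit,
               tolerance = 1e-10)
  expect_equal(get("zone", "sum_sq"), ss_zone, tolerance = 1e-10)
  expect_equal(get("zone:treatment", "sum_sq"), ss_tz, tolerance = 1e-10)
  expect_equal(get("within residual", "sum_sq"), ss_resid, tolerance = 1e-10)
  # degrees of freedom of the split-plot strata
  expect_equal(get("treatment", "df"), tc - 1)
  expect_equal(get("fruit(between residual)", "df"), tc * (fc - 1))
  expect_equal(get("zone", "df"), zc - 1)
  expect_equal(get("within residual", "df"), (zc - 1) * tc * (fc - 1))
  # F statistics use the correct error strata
  expect_equal(get("treatment", "statistic"),
               (ss_treat / (tc - 1)) / (ss_fruit / (tc * (fc - 1))),
               tolerance = 1e-10)
  # conservation: total SS = sum of component SS
  expect_equal(sum(eff$sum_sq), ss_total, tolerance = 1e-10)
})

test_that("replicate images are averaged within fruit x zone", {
  set.seed(9)
  d <- expand.grid(treatment = c("a", "b"), fruit = 1:3,
                   zone = c("In", "Md", "Ex"), img = 1:2)
  d$y <- rnorm(nrow(d))
  d_avg <- stats::aggregate(
    y ~ treatment + fruit + zone, data = d, FUN = mean)
  f1 <- nested_rm_anova(d, "y", between = "treatment")
  f2 <- nested_rm_anova(d_avg, "y", between = "treatment")
  expect_equal(tidy(f1)$statistic, tidy(f2)$statistic, tolerance = 1e-10)
})

test_that("degenerate and invalid designs are rejected or flagged", {
  d <- expand.grid(treatment = c("a", "b"), fruit = 1:3,
                   zone = c("In", "Md", "Ex"))
  d$y <- 5
  fit <- nested_rm_anova(d, "y", between = "treatment")
  expect_true(fit$degenerate)
  expect_true(all(is.nan(tidy(fit)$statistic[1])))
  d1 <- d[d$treatment == "a", ]
  expect_error(nested_rm_anova(d1, "y", between = "treatment"),
               "design error")
  d2 <- expand.grid(treatment = c("a", "b"), fruit = 1,
                    zone = c("In", "Md", "Ex"))
  d2$y <- rnorm(6)
  expect_error(nested_rm_anova(d2, "y", between = "treatment"),
               "design error")
})

test_that("the treatment test holds its type-I error under the null", {
  # null simulation at the Stage-I design size: 2 treatments x 9 fruits x
  # 3 zones x 2 images, fruit and residual variance 1
  n_rep <- 400
  ps <- vapply(seq_len(n_rep), function(s) {
    set.seed(20000 + s)
    d <- expand.grid(treatment = c("ctl", "rdi"), fruit = 1:9,
                     zone = c("In", "Md", "Ex"), img = 1:2)
    fruit_eff <- rnorm(18)
    d$y <- fruit_eff[as.integer(interaction(d$treatment, d$fruit))] +
      rnorm(nrow(d))
    fit <- nested_rm_anova(d, "y", between = "treatment")
    fit$effects$p_value[fit$effects$term == "treatment"]
  }, numeric(1))
  rate <- mean(ps < 0.05)
  # 3 binomial SEs around 0.05 at this replicate count
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("a treatment effect of two residual SDs is detected with power > 0.9", {
  n_rep <- 150
  ps <- vapply(seq_len(n_rep), function(s) {
    set.seed(30000 + s)
    d <- expand.grid(treatment = c("ctl", "rdi"), fruit = 1:9,
                     zone = c("In", "Md", "Ex"), img = 1:2)
    fruit_eff <- rnorm(18)
    d$y <- fruit_eff[as.integer(interaction(d$treatment, d$fruit))] +
      rnorm(nrow(d)) + 2 * (d$treatment == "rdi")
    fit <- nested_rm_anova(d, "y", between = "treatment")
    fit$effects$p_value[fit$effects$term == "treatment"]
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.9)
})

test_that("tukey letters match direct studentized-range computations", {
  # two identical groups share a letter
  lt <- tukey_letters(c(a = 5, b = 5), n = 10, ms_error = 1, df_error = 18)
  expect_equal(lt$letters, c("a", "a"))
  # two groups 10 pooled SDs apart are separated
  lt2 <- tukey_letters(c(a = 0, b = 10), n = 10, ms_error = 1, df_error = 18)
  expect_setequal(lt2$letters, c("a", "b"))
  # three groups with only the extremes differing: letters a, ab, b
  m <- c(g1 = 0, g2 = 1.1, g3 = 2.2)
  q <- qtukey(0.95, 3, 27)
  se <- sqrt(1 / 2 * (1 / 10 + 1 / 10))
  stopifnot(2.2 > q * se, 1.1 < q * se)  # fixture sanity
  lt3 <- tukey_letters(m, n = 10, ms_error = 1, df_error = 27)
  lt3 <- lt3[order(lt3$mean), ]
  expect_equal(lt3$letters, c("a", "ab", "b"))
})

test_that("letter displays encode the significance matrix exactly", {
  set.seed(11)
  for (rep in 1:40) {
    k <- sample(2:6, 1)
    means <- stats::setNames(rnorm(k, sd = sample(c(0.5, 1, 3), 1)),
                             paste0("g", 1:k))
    n <- sample(3:12, 1)
    mse <- runif(1, 0.5, 2)
    dfe <- sample(10:40, 1)
    lt <- tukey_letters(means, n = n, ms_error = mse, df_error = dfe)
    # brute-force all-pairs HSD, recomputed here
    q <- qtukey(0.95, k, dfe)
    sig_bf <- abs(outer(means, means, "-")) > q * sqrt(mse / n)
    diag(sig_bf) <- FALSE
    expect_equal(attr(lt, "significant")[names(means), names(means)],
                 sig_bf, ignore_attr = FALSE)
    # sharing a letter <=> not significantly different
    expect_true(letters_encode_matrix(lt))
  }
})

test_that("invalid tukey inputs error", {
  expect_error(tukey_letters(c(a = 1, b = 2), 5, ms_error = 0, df_error = 10),
               "validation error")
  expect_error(tukey_letters(c(a = 1), 5, 1, 10))
})

test_that("r_squared matches direct computation and handles edge cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(r_squared(x, 2 * x), 1)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.4)
  direct <- (sum((x - mean(x)) * (y - mean(y))))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_squared(x, y), direct)
  set.seed(2)
  expect_lt(r_squared(rnorm(1e4), rnorm(1e4)), 0.01)
  expect_error(r_squared(x, rep(1, 5)), "degenerate")
  expect_error(r_squared(1:2, 1:2), "at least 3")
})
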