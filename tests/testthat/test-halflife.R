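test_that("OLS matches the closed-form and lm oracles", {
  # exactly linear
  f <- ols_fit(c(2, 5, 10, 15), c(-0.2, -0.5, -1.0, -1.5))
  expect_equal(f$slope, -0.1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)

  # hand-computed: Sxy = -17.4, Sxx = 98
  g <- ols_fit(c(2, 5, 10, 15), c(-0.30, -0.80, -1.70, -2.60))
  expect_equal(g$slope, -17.4 / 98, tolerance = 1e-12)
  expect_equal(g$intercept, -1.35 - (-17.4 / 98) * 8, tolerance = 1e-12)

  # degenerate constant response: slope 0, R-squared undefined
  d <- ols_fit(c(2, 5, 10), c(-1, -1, -1))
  expect_equal(d$slope, 0)
  expect_true(is.na(d$r_squared))

  expect_error(ols_fit(c(2, 5), c(-1, -2)), "at least 3")
  expect_error(ols_fit(c(2, 2, 5), c(-1, -2, -3)), "distinct")

  # independent oracle: lm on random 3- and 4-point sets
  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:4, 1)
    x <- sort(sample(seq(1, 30, by = 0.5), n))
    y <- rnorm(n)
    mine <- ols_fit(x, y)
    ref <- lm(y ~ x)
    expect_equal(mine$slope, unname(coef(ref)[2]), tolerance = 1e-12)
    expect_equal(mine$intercept, unname(coef(ref)[1]), tolerance = 1e-12)
    expect_equal(mine$r_squared, summary(ref)$r.squared, tolerance = 1e-12)
  }
})

test_that("slope-to-half-life conversion censors non-decaying genes", {
  expect_equal(half_life_from_slope(-0.1), 10)
  expect_equal(half_life_from_slope(-0.2), 5)
  expect_true(is.na(half_life_from_slope(0.05)))
  expect_true(is.na(half_life_from_slope(0)))
})

test_that("the R-squared gate applies the 3-point fallback window", {
  tps <- c(2, 5, 10, 15)
  # noiseless h = 5: accepted on the full window
  e1 <- estimate_half_life(tps, c(-0.4, -1.0, -2.0, -3.0))
  expect_identical(e1$status, "ok_4pt")
  expect_equal(e1$half_life, 5)
  expect_equal(e1$r_squared, 1)

  # the last point breaks linearity; the first three are exactly linear
  y2 <- c(-0.4, -1.0, -2.0, -1.0)
  full <- summary(lm(y2 ~ tps))$r.squared    # oracle for the gate decision
  expect_lte(full, 0.7)
  e2 <- estimate_half_life(tps, y2)
  expect_identical(e2$status, "ok_3pt")
  expect_equal(e2$n_points, 3L)
  expect_equal(e2$half_life, 5, tolerance = 1e-9)

  # flat profile: censored, no half-life
  e3 <- estimate_half_life(tps, c(0, 0, 0, 0))
  expect_identical(e3$status, "censored")
  expect_true(is.na(e3$half_life))

  # rising profile with perfect fit: still censored (slope >= 0)
  e4 <- estimate_half_life(tps, c(0.2, 0.5, 1.0, 1.5))
  expect_identical(e4$status, "censored")

  # missing early timepoint: unresolved
  e5 <- estimate_half_life(c(2, 10, 15), c(-0.4, -2.0, -3.0))
  expect_identical(e5$status, "unresolved")
})

test_that("estimates satisfy the gate invariants", {
  set.seed(7)
  tps <- c(2, 5, 10, 15)
  for (i in 1:300) {
    y <- -(tps / runif(1, 1, 30)) + rnorm(4, 0, runif(1, 0, 1))
    e <- estimate_half_life(tps, y)
    if (e$status %in% c("ok_4pt", "ok_3pt")) {
      expect_gt(e$r_squared, 0.7)
      expect_lt(e$slope, 0)
      expect_equal(e$half_life, -1 / e$slope)
    } else {
      expect_true(is.na(e$half_life))
    }
  }
})

test_that("scaling the log ratios scales slope and half-life reciprocally", {
  tps <- c(2, 5, 10, 15)
  y <- c(-0.35, -0.9, -1.9, -2.8)
  base <- estimate_half_life(tps, y)
  for (c_scale in c(0.5, 2, 3.7)) {
    sc <- estimate_half_life(tps, c_scale * y)
    expect_equal(sc$slope, c_scale * base$slope, tolerance = 1e-12)
    expect_equal(sc$half_life, base$half_life / c_scale, tolerance = 1e-12)
    # R-squared is invariant under affine transforms of y
    aff <- ols_fit(tps, c_scale * y + 1.3)
    expect_equal(aff$r_squared, ols_fit(tps, y)$r_squared, tolerance = 1e-12)
  }
})

test_that("noiseless pipelines recover half-lives exactly end to end", {
  truth <- fixed_truth(c(2, 5, 10, 25))
  fit <- fit_half_lives(build_decay_profiles(noiseless_hybs(truth)))
  est <- fit$estimates[match(truth$gene_id, fit$estimates$gene_id), ]
  expect_true(all(est$status == "ok_4pt"))
  expect_lt(max(abs(est$half_life - truth$true_half_life) /
                  truth$true_half_life), 1e-9)
})

test_that("model object methods are coherent", {
  truth <- fixed_truth(c(3, 6, 12))
  fit <- fit_half_lives(build_decay_profiles(noiseless_hybs(truth)))
  expect_s3_class(fit, "halflife_fit")
  expect_output(print(fit), "full-window fits")

  cf <- coef(fit)
  expect_identical(colnames(cf), c("slope", "intercept"))
  pred <- predict(fit, times = c(0, 2, 5))
  expect_equal(dim(pred), c(3L, 3L))
  # prediction at the fitted times reproduces a noiseless profile
  expect_equal(unname(predict(fit)["gene01", ]),
               unname(fit$profiles["gene01", ]), tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-9)

  s <- summary(fit)
  expect_equal(s$n_ok, 3)
  expect_equal(s$mean, mean(c(3, 6, 12)), tolerance = 1e-9)
  expect_equal(sum(s$histogram$count), 3)
  # 1-minute bins [k, k+1)
  expect_true(all(s$histogram$bin_end - s$histogram$bin_start == 1))

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("summary statistics cover accepted estimates only", {
  est <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    slope = c(-0.2, -0.25, -1 / 9, 0.1),
    intercept = 0, r_squared = c(0.9, 0.95, 0.99, NA),
    n_points = 4L,
    half_life = c(5, 4, 9, NA),
    status = c("ok_4pt", "ok_3pt", "ok_4pt", "censored"),
    stringsAsFactors = FALSE)
  fake <- structure(list(estimates = est, gate = 0.7,
                         timepoints = c(2, 5, 10, 15),
                         profiles = NULL), class = "halflife_fit")
  s <- summary(fake)
  expect_equal(s$mean, 6)
  expect_equal(s$median, 5)
})

test_that("operon averaging uses accepted members at full precision", {
  est <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    slope = -0.2, intercept = 0, r_squared = 0.9, n_points = 4L,
    half_life = c(3.7, 3.0, 3.1, NA, 2.7),
    status = c("ok_4pt", "ok_4pt", "ok_3pt", "censored", "ok_4pt"),
    stringsAsFactors = FALSE)
  map <- data.frame(operon_id = c("opA", "opA", "opA", "opA", "opB", "opC"),
                    gene_id = c("g1", "g2", "g3", "g4", "g5", "g4"))
  op <- operon_half_lives(est, map)
  a <- op[op$operon_id == "opA", ]
  expect_equal(a$mean_half_life, mean(c(3.7, 3.0, 3.1)), tolerance = 1e-12)
  expect_equal(a$n_members, 4)
  expect_equal(a$n_members_estimated, 3)
  # mean lies within the member range
  expect_gte(a$mean_half_life, 3.0)
  expect_lte(a$mean_half_life, 3.7)
  # single-member operon is the identity
  expect_equal(op$mean_half_life[op$operon_id == "opB"], 2.7)
  # operons with no accepted member are omitted and reported
  expect_false("opC" %in% op$operon_id)
  expect_identical(attr(op, "omitted"), "opC")
})
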