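mk_records <- function(conc, mean) {
  data.frame(embryo_id = sprintf("e%d", seq_along(conc)), chemical = "chemX",
             concentration_uM = conc, group = ifelse(conc == 0, "control", "treated"),
             mean = mean)
}

test_that("fold induction is normalised by the control mean", {
  ds <- normalise_records(mk_records(c(0, 0, 10), c(100, 100, 300)))
  expect_equal(ds$fold_induction, c(1, 1, 3))
  ds2 <- normalise_records(mk_records(c(0, 0, 10), c(90, 110, 150)))
  expect_equal(ds2$fold_induction, c(0.9, 1.1, 1.5))
  ds3 <- normalise_records(mk_records(c(0, 0, 5, 10), rep(42, 4)))
  expect_true(all(ds3$fold_induction == 1))
  expect_equal(mean(ds2$fold_induction[ds2$concentration_uM == 0]), 1)
  expect_error(normalise_records(mk_records(c(5, 10), c(1, 2))), "control")
  expect_error(normalise_records(mk_records(c(0, 10), c(0, 2))), "zero")
})

test_that("one-way ANOVA matches the hand sums-of-squares oracle", {
  # identical groups: no between-group variance
  ds <- data.frame(concentration_uM = rep(c(0, 1), each = 3),
                   fold_induction = c(1, 2, 3, 1, 2, 3))
  g0 <- anova_gate(ds)
  expect_equal(g0$F, 0)
  expect_equal(g0$p, 1)
  expect_false(g0$pass)

  # 3 x 3 integer toy data: SSB = 54 on 2 df, SSW = 6 on 6 df, F = 27
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  ds2 <- data.frame(concentration_uM = rep(c(0, 1, 10), each = 3),
                    fold_induction = vals)
  g2 <- anova_gate(ds2)
  grand <- mean(vals)
  gm <- tapply(vals, ds2$concentration_uM, mean)
  ssb <- sum(3 * (gm - grand)^2)
  ssw <- sum((vals - rep(gm, each = 3))^2)
  F_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(F_oracle, 27)
  expect_equal(g2$F, F_oracle, tolerance = 1e-12)
  expect_identical(c(g2$df_between, g2$df_within), c(2L, 6L))
  expect_equal(g2$p, pf(27, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  expect_error(anova_gate(data.frame(concentration_uM = c(0, 0, 1),
                                     fold_induction = c(1, 2, 3))), "n >= 2")
})

test_that("ANOVA gate holds its nominal type-I error under a flat response", {
  # scaled-down null calibration; the full 1000-seed run lives in the
  # acceptance suite
  rejections <- vapply(seq_len(200), function(i) {
    set.seed(5000 + i)
    rec <- mk_records(rep(c(0, 1, 5, 25), each = 15),
                      100 + rnorm(60, sd = 10))
    anova_gate(normalise_records(rec))$pass
  }, logical(1))
  expect_lte(mean(rejections), 0.01)
})

test_that("gaussian fit recovers exact model data to high precision", {
  true <- gaussian_cr_model(b = 0.8, d = 2.5, e = 5)
  doses <- 10^seq(-1.5, 1.5, length.out = 8)
  ds <- data.frame(concentration_uM = rep(c(0, doses), each = 3))
  ds$fold_induction <- predict_cr(true, ds$concentration_uM)
  fit <- fit_gaussian_cr(ds)
  expect_true(fit$converged)
  expect_equal(fit$b, 0.8, tolerance = 1e-6)
  expect_equal(fit$d, 2.5, tolerance = 1e-6)
  expect_equal(fit$e, 5, tolerance = 1e-6)
  expect_false(fit$no_induction)
  expect_lt(fit$sse, 1e-12)
})

test_that("flat data is flagged as no induction", {
  ds <- data.frame(concentration_uM = rep(c(0, 0.5, 2, 8, 32), each = 3),
                   fold_induction = 1)
  fit <- fit_gaussian_cr(ds)
  expect_true(fit$converged)
  expect_true(fit$no_induction)
  expect_equal(fit$d, 1, tolerance = 1e-6)
})

test_that("gaussian model is scale-equivariant in concentration", {
  true <- gaussian_cr_model(b = 0.6, d = 3, e = 2)
  doses <- 10^seq(-1, 1.2, length.out = 6)
  mk <- function(k) {
    ds <- data.frame(concentration_uM = rep(c(0, doses * k), each = 3))
    ds$fold_induction <- predict_cr(gaussian_cr_model(b = 0.6, d = 3, e = 2 * k),
                                    ds$concentration_uM)
    ds
  }
  f1 <- fit_gaussian_cr(mk(1))
  f7 <- fit_gaussian_cr(mk(7))
  expect_equal(f7$b, f1$b, tolerance = 1e-6)
  expect_equal(f7$d, f1$d, tolerance = 1e-6)
  expect_equal(f7$e / f1$e, 7, tolerance = 1e-6)
  expect_equal(ec15(f7)$ec15_uM / ec15(f1)$ec15_uM, 7, tolerance = 1e-6)
})

test_that("linear fit equals the normal-equation oracle", {
  ds <- data.frame(concentration_uM = c(0, 10), fold_induction = c(1, 2))
  fit <- fit_linear_cr(ds)
  expect_equal(fit$a0, 1, tolerance = 1e-12)
  expect_equal(fit$a1, 0.1, tolerance = 1e-12)

  ds2 <- data.frame(concentration_uM = rep(c(0, 5, 10), 3))
  ds2$fold_induction <- 1 + 0.04 * ds2$concentration_uM
  fit2 <- fit_linear_cr(ds2)
  expect_equal(fit2$a1, 0.04, tolerance = 1e-12)
  expect_lt(fit2$sse, 1e-20)

  set.seed(8)
  x <- runif(40, 0, 50); y <- 1 + 0.02 * x + rnorm(40, sd = 0.3)
  fit3 <- fit_linear_cr(data.frame(concentration_uM = x, fold_induction = y))
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(c(fit3$a0, fit3$a1), as.numeric(beta), tolerance = 1e-10)
})

test_that("EC1.5 inversion matches a bisection oracle and stays on the ascending limb", {
  m <- gaussian_cr_model(b = 1, d = 2, e = 10)
  ec <- ec15(m)
  expect_true(ec$valid)
  expect_equal(ec$ec15_uM, exp(log(10) - sqrt(2 * log(2))), tolerance = 1e-12)
  expect_equal(ec$ec15_uM, 3.0806, tolerance = 1e-4)
  # bisection on the forward curve (log-concentration root finding)
  root <- uniroot(function(u) predict_cr(m, exp(u)) - 1.5,
                  lower = log(m$e * 1e-6), upper = log(m$e), tol = 1e-13)$root
  expect_equal(ec$ec15_uM, exp(root), tolerance = 1e-8)

  # peak exactly at the effect level: EC equals the peak concentration
  expect_equal(ec15(gaussian_cr_model(b = 1, d = 1.5, e = 7))$ec15_uM, 7)
  # peak below the effect level: invalid with a reason
  low <- ec15(gaussian_cr_model(b = 1, d = 1.4, e = 7))
  expect_false(low$valid)
  expect_match(low$reason, "peak below")

  set.seed(21)
  for (i in 1:50) {
    mi <- gaussian_cr_model(b = runif(1, 0.2, 3), d = runif(1, 1.6, 5),
                            e = 10^runif(1, -1, 3))
    eci <- ec15(mi)
    expect_true(eci$valid)
    expect_lt(abs(predict_cr(mi, eci$ec15_uM) - 1.5), 1e-6)  # forward consistency
    expect_lte(eci$ec15_uM, mi$e)                            # ascending limb
  }
})

test_that("linear EC inversion respects slope and range validity", {
  m <- linear_cr_model(a0 = 1, a1 = 0.1)
  ec <- ec15(m)
  expect_true(ec$valid)
  expect_equal(ec$ec15_uM, 5)
  expect_false(ec15(linear_cr_model(1, -0.1))$valid)
  expect_false(ec15(linear_cr_model(1, 0.001), max_dose = 10)$valid)  # 500 >> 100
})

test_that("analyze_chemical routes inducers, inert chemicals and errors", {
  set.seed(77)
  true <- gaussian_cr_model(b = 0.8, d = 2.5, e = 5)
  doses <- c(0, 10^seq(-1, 1.5, length.out = 6))
  conc <- rep(doses, each = 12)
  rec <- mk_records(conc, 100 * pmax(predict_cr(true, conc) +
                                       rnorm(length(conc), sd = 0.1), 0.05))
  rep_ind <- analyze_chemical(rec, config = run_config())
  expect_identical(rep_ind$verdict, "gaussian")
  expect_true(rep_ind$ec$valid)
  expect_lt(rep_ind$ec$ec15_uM, max(doses))
  expect_gt(rep_ind$ec$ec15_uM, 0)

  set.seed(78)
  rec_flat <- mk_records(conc, 100 + rnorm(length(conc), sd = 10))
  rep_flat <- analyze_chemical(rec_flat, config = run_config())
  expect_identical(rep_flat$verdict, "no_effect")
  expect_null(rep_flat$model)

  expect_error(analyze_chemical(mk_records(rep(0, 6), rep(100, 6))),
               ">= 2 groups")

  # report round-trips to JSON
  path <- withr::local_tempfile(fileext = ".json")
  write_chemical_report(rep_ind, path)
  j <- jsonlite::read_json(path)
  expect_identical(j$verdict, "gaussian")
  expect_equal(j$ec15_uM, rep_ind$ec$ec15_uM, tolerance = 1e-12)
  expect_equal(j$model$d, rep_ind$model$d, tolerance = 1e-12)
})
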