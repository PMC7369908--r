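test_that("two exactly-linear ligands are interpolated to machine precision", {
  deltas <- data.frame(ligand_id = c("A", "B"), dV_vdw = c(-10, -4),
                       dV_ele = c(-5, -12))
  exps <- data.frame(ligand_id = c("A", "B"),
                     dG_exp = 0.2 * deltas$dV_vdw + 0.3 * deltas$dV_ele)
  p <- fit_lie_parameters(deltas, exps)
  expect_equal(p$alpha, 0.2, tolerance = 1e-12)
  expect_equal(p$beta, 0.3, tolerance = 1e-12)
  expect_identical(p$source, "fitted")
})

test_that("fit contracts: overlap, collinearity, exclusion of missing data", {
  deltas <- data.frame(ligand_id = c("A", "B", "C"), dV_vdw = c(-1, -2, -3),
                       dV_ele = c(-2, -4, -6))
  exps <- data.frame(ligand_id = c("A", "B", "C"), dG_exp = c(-1, -2, -3))
  expect_error(fit_lie_parameters(deltas, exps), "collinearity")
  expect_error(fit_lie_parameters(deltas[1, ], exps[1, ]),
               "insufficient data")
  # ligands without experimental values are dropped, not imputed
  t4 <- table4_fixture()
  exps8 <- experimental_affinities(t4)
  p <- fit_lie_parameters(t4, exps8)
  expect_length(attr(p, "ligand_ids"), 8L)
  expect_false("l-DOPA" %in% attr(p, "ligand_ids"))
})

test_that("no-intercept fit on the reference table recovers the published parameters", {
  t4 <- table4_fixture()
  cal <- calibrate_lie(t4, t4, exps = data.frame(
    ligand_id = t4$ligand_id, dG_exp = t4$dG_exp_ref))
  expect_lt(abs(cal$alpha - 0.197), 0.005)
  expect_lt(abs(cal$beta - 0.342), 0.005)
  # independent cross-check of the normal-equation solve
  m <- t4[!is.na(t4$dG_exp_ref), ]
  ref <- stats::lm(dG_exp_ref ~ 0 + dV_vdw + dV_ele, data = m)
  expect_equal(cal$alpha, unname(stats::coef(ref)[1]), tolerance = 1e-10)
  expect_equal(cal$beta, unname(stats::coef(ref)[2]), tolerance = 1e-10)
})

test_that("no-intercept residuals are orthogonal to both regressors", {
  t4 <- table4_fixture()
  cal <- calibrate_lie(t4, t4)
  r <- cal$points$residual_model2
  expect_lt(abs(sum(r * cal$points$dV_vdw)), 1e-8)
  expect_lt(abs(sum(r * cal$points$dV_ele)), 1e-8)
})

test_that("the fit is scale-equivariant in the response", {
  t4 <- table4_fixture()
  exps <- experimental_affinities(t4)
  p1 <- fit_lie_parameters(t4, exps)
  exps$dG_exp <- 2.5 * exps$dG_exp
  p2 <- fit_lie_parameters(t4, exps)
  expect_equal(p2$alpha, 2.5 * p1$alpha, tolerance = 1e-12)
  expect_equal(p2$beta, 2.5 * p1$beta, tolerance = 1e-12)
})

test_that("r^2 follows the squared-Pearson definition", {
  x <- c(-9, -7, -5, -4)
  expect_equal(coefficient_of_determination(x, x), 1)
  expect_equal(coefficient_of_determination(-x, x), 1)  # sign-invariant
  expect_error(coefficient_of_determination(rep(1, 4), x), "zero variance")
  expect_error(coefficient_of_determination(x[1:2], x[1:2]), ">= 3")
})

test_that("both models' r^2 match the published values on the reference table", {
  t4 <- table4_fixture()
  cal <- calibrate_lie(t4, t4)
  expect_lt(abs(cal$r2_model1 - 0.93), 0.01)
  expect_lt(abs(cal$r2_model2 - 0.94), 0.01)
  # in-sample, the fitted model correlates at least as well as model 1
  expect_gte(cal$r2_model2, cal$r2_model1)
})

test_that("fitted parameters are recovered from noisy synthetic ligands", {
  t4 <- table4_fixture()
  X <- t4[!is.na(t4$dG_exp_ref), c("ligand_id", "dV_vdw", "dV_ele")]
  est <- vapply(1:200, function(seed) {
    set.seed(seed)
    exps <- data.frame(
      ligand_id = X$ligand_id,
      dG_exp = 0.197 * X$dV_vdw + 0.342 * X$dV_ele +
        stats::rnorm(nrow(X), sd = 0.01))
    p <- fit_lie_parameters(X, exps)
    c(p$alpha, p$beta)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 0.197), 0.01)
  expect_lt(abs(mean(est[2, ]) - 0.342), 0.01)
})

test_that("leave-one-out is exact on linear data and sane on the reference", {
  deltas <- data.frame(ligand_id = LETTERS[1:5],
                       dV_vdw = c(-10, -4, -7, -13, -2),
                       dV_ele = c(-5, -12, -9, -3, -15))
  exps <- data.frame(ligand_id = LETTERS[1:5],
                     dG_exp = 0.2 * deltas$dV_vdw + 0.3 * deltas$dV_ele)
  loo <- leave_one_out(deltas, exps)
  expect_equal(loo$loo_rmse, 0, tolerance = 1e-10)

  t4 <- table4_fixture()
  loo <- leave_one_out(t4, experimental_affinities(t4))
  expect_true(is.finite(loo$loo_rmse))
  expect_true(all(loo$predictions$alpha > 0 & loo$predictions$alpha < 1))
  expect_error(leave_one_out(deltas[1:2, ], exps[1:2, ]),
               "insufficient data")
})

test_that("calibration reports round-trip through JSON", {
  t4 <- table4_fixture()
  cal <- calibrate_lie(t4, t4)
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration_report(cal, f)
  back <- read_calibration_report(f)
  expect_equal(back$alpha, cal$alpha, tolerance = 1e-12)
  expect_equal(back$r2_model2, cal$r2_model2, tolerance = 1e-12)
  expect_equal(back$points$pred_model1, cal$points$pred_model1,
               tolerance = 1e-12)
  expect_equal(back$n_ligands, 8L)

  empty <- cal
  empty$points <- cal$points[0, ]
  expect_error(write_calibration_report(empty, f), "validation error")
})
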