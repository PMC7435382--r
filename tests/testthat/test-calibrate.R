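Table1_root2only <- list(pos = c(c = 0.1744), neg = c(c = -0.1373))
Table1_root2_pos <- c(a = 0.0049, b = -0.3337, c = 0.1466)
Table1_root2_neg <- c(a = -0.0043, b = 0.1956, c = -0.1150)
Table2_poly2 <- c(p1 = 0.7420, p2 = 1.5460, p3 = -0.0768)

root2only_pairs <- function(n = 400, xmax = 600, xmin = -400,
                            cpos = 0.1744, cneg = -0.1373, noise = 0) {
  x <- c(seq(1, xmax, length.out = n / 2), seq(xmin, -1, length.out = n / 2))
  y <- ifelse(x >= 0, cpos * sqrt(pmax(x, 0)), cneg * sqrt(pmax(-x, 0)))
  if (noise > 0) y <- y + rnorm(length(y), 0, noise)
  list(dp = x, flow = y)
}

test_that("root fits recover generating coefficients exactly on noise-free data", {
  p <- root2only_pairs()
  m <- fit_root(p, "root2only")
  expect_equal(unname(m$pos_coeffs["c"]), 0.1744, tolerance = 1e-8)
  expect_equal(unname(m$neg_coeffs["c"]), -0.1373, tolerance = 1e-8)
  expect_lt(gof_rmse(m, p), 1e-10)

  # root2 rows: positive and negative branch coefficients
  x <- c(seq(0.5, 500, length.out = 100), seq(-350, -0.5, length.out = 100))
  y <- ifelse(x >= 0,
              Table1_root2_pos["a"] * x + Table1_root2_pos["b"] + Table1_root2_pos["c"] * sqrt(pmax(x, 0)),
              Table1_root2_neg["a"] * (-x) + Table1_root2_neg["b"] + Table1_root2_neg["c"] * sqrt(pmax(-x, 0)))
  m2 <- fit_root(list(dp = x, flow = y), "root2")
  expect_equal(unname(m2$pos_coeffs[c("a", "b", "c")]), unname(Table1_root2_pos),
               tolerance = 1e-6)
  expect_equal(unname(m2$neg_coeffs[c("a", "b", "c")]), unname(Table1_root2_neg),
               tolerance = 1e-6)
  # inactive terms stay zero
  expect_identical(unname(m2$pos_coeffs[c("d", "e")]), c(0, 0))

  # and the fit agrees with the explicit normal-equations oracle
  pos <- x >= 0
  oracle <- oracle_lls(oracle_root_basis(x[pos], c("a", "b", "c")), y[pos])
  expect_equal(unname(m2$pos_coeffs[c("a", "b", "c")]), oracle, tolerance = 1e-8)

  # all-zero targets give all-zero coefficients
  mz <- fit_root(list(dp = x, flow = numeric(length(x))), "root4")
  expect_equal(unname(mz$pos_coeffs), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(mz$neg_coeffs), rep(0, 5), tolerance = 1e-10)
})

test_that("polynomial fits use the constant-first convention and recover generating rows", {
  x <- seq(-30, 40, length.out = 300)
  y <- Table2_poly2["p1"] + Table2_poly2["p2"] * x + Table2_poly2["p3"] * x^2
  m <- fit_poly(list(dp = x, flow = y), degree = 2)
  expect_equal(unname(m$coeffs), unname(Table2_poly2), tolerance = 1e-8)
  # evaluated at 0 the polynomial returns its constant term
  expect_equal(predict(m, 0), unname(Table2_poly2["p1"]), tolerance = 1e-10)

  # constant targets
  mc <- fit_poly(list(dp = x, flow = rep(5, length(x))), degree = 3)
  expect_equal(unname(mc$coeffs), c(5, 0, 0, 0), tolerance = 1e-9)

  # nested-model property: degree-5 fit on quadratic truth
  m5 <- fit_poly(list(dp = x, flow = y), degree = 5)
  expect_lt(max(abs(m5$coeffs[4:6])), 1e-8)
  expect_equal(predict(m5, x), predict(m, x), tolerance = 1e-6)
})

test_that("prediction matches hand arithmetic and handles empty input", {
  p <- root2only_pairs()
  m <- fit_root(p, "root2only")
  expect_equal(predict(m, 100), 1.744, tolerance = 1e-6)
  expect_identical(predict(m, numeric(0)), numeric(0))
  mp <- fit_poly(list(dp = seq(-5, 5, by = 0.1),
                      flow = 0.742 + 1.546 * seq(-5, 5, by = 0.1)), degree = 2)
  expect_identical(predict(mp, numeric(0)), numeric(0))
})

test_that("gof RMSE follows its definition", {
  x <- c(1, 2)
  m <- fit_poly(list(dp = seq(0, 10, by = 0.1), flow = seq(0, 10, by = 0.1)), degree = 2)
  # perfect fit
  expect_equal(gof_rmse(m, list(dp = x, flow = predict(m, x))), 0, tolerance = 1e-10)
  # residuals {+1, -1} -> 1 ; residuals {3, 4} -> sqrt(12.5)
  expect_equal(gof_rmse(m, list(dp = x, flow = predict(m, x) + c(1, -1))), 1)
  expect_equal(gof_rmse(m, list(dp = x, flow = predict(m, x) + c(3, 4))),
               sqrt(12.5), tolerance = 1e-12)
})

test_that("least-absolute-residual refinement resists gross outliers", {
  withr::local_seed(42)
  p <- root2only_pairs(noise = 0.02)
  clean <- fit_root(p, "root2only")
  # corrupt 5% of samples with x10 flow
  idx <- sample(length(p$flow), round(0.05 * length(p$flow)))
  p_bad <- p
  p_bad$flow[idx] <- p_bad$flow[idx] * 10
  shift_lls <- abs(fit_root(p_bad, "root2only")$pos_coeffs["c"] - clean$pos_coeffs["c"])
  shift_lar <- abs(fit_root(p_bad, "root2only", robust = TRUE)$pos_coeffs["c"] -
                     clean$pos_coeffs["c"])
  expect_lt(shift_lar, shift_lls / 3)
})

test_that("goodness of fit is non-increasing along the nested root variants", {
  sess <- quiet_sessions(2, seed = 31, n_fvc = 3, tidal_between = 2)
  pairs <- lapply(sess, function(s) {
    suppressWarnings(make_conditioned_pair(s$inside, s$outside, s$reference_flow))
  })
  gofs <- vapply(c("root2only", "root2", "root3", "root4"), function(v) {
    fit_root(pairs, v)$report$rmse_gof
  }, 0)
  expect_true(all(diff(gofs) <= 1e-12))
})

test_that("degenerate designs are rejected with diagnostics", {
  expect_error(fit_root(list(dp = rep(c(-1, 1), 20), flow = rep(0, 40)), "root2"),
               "rank-deficient")
  expect_error(fit_root(list(dp = seq(1, 10), flow = seq(1, 10)), "root2only"),
               "each sign branch")
  expect_error(fit_poly(list(dp = rep(1, 50), flow = rep(1, 50)), degree = 2),
               "distinct")
})

test_that("monotonicity diagnostic flags non-monotone polynomial edges", {
  x <- seq(-20, 20, length.out = 200)
  m_root <- fit_root(root2only_pairs(), "root2only")
  expect_true(is_monotone(m_root, c(-400, 600)))
  # a downward parabola is not monotone over a symmetric range
  m_par <- fit_poly(list(dp = x, flow = -x^2), degree = 2)
  expect_false(is_monotone(m_par, c(-20, 20)))
})

test_that("models serialise to JSON and restore identically", {
  tmp <- withr::local_tempfile(fileext = ".json")
  p <- root2only_pairs()
  m <- fit_root(p, "root4")
  write_model(m, tmp)
  m2 <- read_model(tmp)
  x <- seq(-300, 500, length.out = 77)
  expect_equal(predict(m2, x), predict(m, x), tolerance = 1e-12)

  mp <- fit_poly(p, degree = 3)
  write_model(mp, tmp)
  expect_equal(predict(read_model(tmp), x), predict(mp, x), tolerance = 1e-12)

  mm <- fit_mlp(p, hidden_units = 3, seed = 2)
  write_model(mm, tmp)
  expect_equal(predict(read_model(tmp), x), predict(mm, x), tolerance = 1e-12)
})
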