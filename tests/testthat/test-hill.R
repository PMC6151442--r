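test_that("hill_effect satisfies its defining identities", {
  for (hp in list(hill_params(77.06, 1.71), hill_params(0.5, 0.3),
                  hill_params(1000, 4))) {
    expect_equal(hill_effect(hp$ec50, hp), 0.5)
    expect_identical(hill_effect(0, hp), 0)
    cc <- sort(10^runif(20, -2, 4))
    eff <- hill_effect(cc, hp)
    expect_true(all(diff(eff) > 0))            # strictly increasing
    expect_true(all(eff >= 0 & eff < 1))
  }
  expect_error(hill_effect(-1, hill_params(1, 1)), ">= 0")
  expect_error(hill_params(-1, 1), "'ec50'")
  expect_error(hill_params(1, 0), "'p'")
})

test_that("ec_x inverts hill_effect and hits printed reference values", {
  set.seed(11)
  for (i in 1:20) {
    hp <- hill_params(10^runif(1, -1, 3), runif(1, 0.2, 4))
    x <- runif(5, 0.01, 0.99)
    expect_equal(hill_effect(ec_x(hp, x), hp), x, tolerance = 1e-10)
    cc <- hp$ec50 * 10^runif(5, -1.5, 1.5)   # effects away from 0/1 saturation
    expect_equal(ec_x(hp, hill_effect(cc, hp)), cc, tolerance = 1e-10)
    expect_true(all(diff(ec_x(hp, sort(x))) > 0))
  }
  expect_equal(ec_x(hill_params(42, 1.3), 0.5), 42)
  expect_error(ec_x(hill_params(1, 1), 1), "inside")

  # concentrations eliciting 10%/20% effect for baohuoside I and
  # 10% for icartin, from two-point fits to their (EC5, EC50) pairs
  bao <- fit_two_point(13.77, 0.05, 77.06, 0.50)
  expect_equal(hill_effect(21.32, bao), 0.10, tolerance = 0.005 / 0.10)
  expect_equal(ec_x(bao, 0.20), 34.26, tolerance = 0.01)
  ica <- fit_two_point(1.90, 0.05, 69.02, 0.50)
  expect_equal(ec_x(ica, 0.10), 4.73, tolerance = 0.01)
})

test_that("two-point fit solves the closed form and round-trips", {
  hp <- fit_two_point(13.77, 0.05, 77.06, 0.50)
  # frozen from independent evaluation of the log-odds/log-dose ratio
  expect_equal(hp$p, 1.7098, tolerance = 1e-4)
  expect_equal(hp$ec50, 77.06, tolerance = 1e-10)
  expect_equal(ec_x(hp, 0.05), 13.77, tolerance = 1e-10)

  # recovers arbitrary generating parameters from two sampled points
  set.seed(7)
  for (i in 1:10) {
    truth <- hill_params(10^runif(1, -1, 2), runif(1, 0.3, 3))
    c1 <- truth$ec50
    hp2 <- fit_two_point(c1, 0.5, 2 * c1, hill_effect(2 * c1, truth))
    expect_equal(hp2$ec50, truth$ec50, tolerance = 1e-10)
    expect_equal(hp2$p, truth$p, tolerance = 1e-10)
  }

  expect_error(fit_two_point(5, 0.2, 5, 0.4), "coincident")
  expect_error(fit_two_point(5, 0, 10, 0.4), "strictly inside")
  expect_error(fit_two_point(5, 0.3, 10, 0.3), "equal effects")
})

test_that("epimedin B two-point fit reproduces its printed EC30", {
  epiB <- fit_two_point(7.14, 0.05, 402.92, 0.50)
  expect_equal(ec_x(epiB, 0.30), 126.22, tolerance = 0.01)
})

test_that("curve fit recovers noise-free parameters and degrades gracefully", {
  truth <- hill_params(77.06, 1.71)
  cc <- c(5, 10, 25, 50, 100, 200, 400)
  fit <- fit_curve(cc, hill_effect(cc, truth))
  expect_equal(fit$ec50, truth$ec50, tolerance = 1e-6)
  expect_equal(fit$p, truth$p, tolerance = 1e-6)

  # two points fall back to the closed form
  fit2 <- fit_curve(c(10, 40), hill_effect(c(10, 40), truth))
  exact <- fit_two_point(10, hill_effect(10, truth), 40, hill_effect(40, truth))
  expect_equal(fit2$ec50, exact$ec50)
  expect_equal(fit2$p, exact$p)

  expect_error(fit_curve(c(1, 2, 3), c(0, 0, 0)), "degenerate")
})

test_that("curve fit is robust to measurement noise", {
  truth <- hill_params(77.06, 1.71)
  cc <- 77.06 * 2^seq(-3, 3)
  set.seed(1)
  err <- replicate(100, {
    eff <- pmin(pmax(hill_effect(cc, truth) + rnorm(7, 0, 0.02), 0), 1)
    abs(fit_curve(cc, eff)$ec50 - truth$ec50) / truth$ec50
  })
  expect_lt(median(err), 0.10)
})

test_that("fits from printed (EC5, EC50) reproduce the full EC ladder", {
  ec <- standards_ec_table()
  levels <- c(0.10, 0.20, 0.30, 0.40)
  cols <- c("EC10", "EC20", "EC30", "EC40")
  for (i in seq_len(nrow(ec))) {
    hp <- fit_two_point(ec$EC5[i], 0.05, ec$EC50[i], 0.50)
    tol <- if (ec$name[i] == "epimedin C") 0.05 else 0.02  # EC5=0.02 is rounded
    for (j in seq_along(levels))
      expect_equal(ec_x(hp, levels[j]), ec[[cols[j]]][i], tolerance = tol,
                   label = sprintf("%s %s", ec$name[i], cols[j]))
  }
})

test_that("EC tables round-trip through delimited text and are validated", {
  ec <- standards_ec_table()
  expect_s3_class(ec, "ec_table")
  expect_equal(nrow(ec), 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ec_table(ec, path)
  expect_equal(read_ec_table(path), ec, ignore_attr = TRUE)

  bad <- as.data.frame(ec)
  bad$EC20[1] <- bad$EC50[1] * 2                 # non-monotone ladder
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_ec_table(path), "increase strictly")
})
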