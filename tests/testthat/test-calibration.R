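table1 <- list(
  pH         = list(channel = "R", scale = "linear", slope = -40.9,
                    intercept = 432.7, r2 = 0.9442, range = c(5, 9)),
  Glucose    = list(channel = "B", scale = "linear", slope = -0.3983,
                    intercept = 122.8, r2 = 0.9104, range = c(50, 300)),
  Ketones    = list(channel = "G", scale = "log10", slope = -69.92,
                    intercept = 189.1, r2 = 0.9872, range = c(5, 100)),
  Hemoglobin = list(channel = "R", scale = "linear", slope = -141.1,
                    intercept = 217, r2 = 0.9461, range = c(0.25, 1.0)),
  Bilirubin  = list(channel = "G", scale = "linear", slope = -22.36,
                    intercept = 195.2, r2 = 0.9025, range = c(0.5, 3.0)),
  Protein    = list(channel = "R", scale = "log10", slope = -48.88,
                    intercept = 208.3, r2 = 0.9682, range = c(10, 1000)),
  Nitrites   = list(channel = "G", scale = "log10", slope = -53,
                    intercept = 131, r2 = 0.963, range = c(1, 100))
)

test_that("builtin panel matches the published seven-analyte calibration", {
  panel <- builtin_panel()
  expect_length(panel, 7L)
  expect_named(panel, names(table1))
  for (a in names(table1)) {
    exp <- table1[[a]]
    cv <- panel[[a]]
    expect_identical(cv$channel, exp$channel)
    expect_identical(cv$scale, exp$scale)
    expect_identical(cv$slope, exp$slope)
    expect_identical(cv$intercept, exp$intercept)
    expect_identical(cv$r_squared, exp$r2)
    expect_equal(cv$linearity_range, exp$range)
  }
  expect_identical(panel$Glucose$reference_range, "<20 mg/dL")
})

test_that("noiseless responses from each builtin formula are fit back exactly", {
  for (cv in builtin_panel()) {
    x <- default_levels(cv, 5)
    fit <- fit_curve(x, forward_response(cv, x), scale = cv$scale)
    expect_equal(fit$slope, cv$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, cv$intercept, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1)
    expect_equal(fit$n_points, 5L)
  }
})

test_that("log10-scale fit recovers the ketone formula from two forward points", {
  # forward-evaluated at concentrations 10 and 100 (log10 x = 1, 2)
  fit <- fit_curve(c(10, 100), c(119.18, 49.26), scale = "log10")
  expect_equal(fit$slope, -69.92, tolerance = 1e-9)
  expect_equal(fit$intercept, 189.1, tolerance = 1e-9)
})

test_that("OLS agrees with a normal-equation oracle on random datasets", {
  withr::with_seed(42, {
    for (i in 1:20) {
      n <- sample(3:12, 1)
      x <- runif(n, 1, 50)
      y <- runif(n, 0, 255)
      fit <- fit_curve(x, y, "linear")
      # independent closed form from direct sums
      sl <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
      ic <- mean(y) - sl * mean(x)
      expect_equal(fit$slope, sl, tolerance = 1e-9)
      expect_equal(fit$intercept, ic, tolerance = 1e-9)
    }
  })
})

test_that("OLS agrees with a numerical SSE minimizer", {
  withr::with_seed(7, {
    for (i in 1:5) {
      x <- runif(6, 1, 10)
      y <- 3 * x + 5 + rnorm(6)
      fit <- fit_curve(x, y, "linear")
      sse <- function(p) sum((y - p[1] * x - p[2])^2)
      opt <- optim(c(0, 0), sse, method = "BFGS")
      expect_equal(fit$slope, opt$par[1], tolerance = 1e-3)
      expect_equal(fit$intercept, opt$par[2], tolerance = 1e-3)
    }
  })
})

test_that("degenerate inputs are handled as documented", {
  expect_error(fit_curve(c(2, 2, 2), c(1, 2, 3)), "identical")
  expect_error(fit_curve(c(1), c(1)), "at least 2")
  expect_error(fit_curve(c(1, 2), c(1, 2, 3)), "length")
  expect_error(fit_curve(c(-1, 10), c(1, 2), scale = "log10"), "positive")
  # zero response variance with zero residuals -> r2 = 1
  flat <- fit_curve(c(1, 2, 3), c(7, 7, 7))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 1)
})

test_that("r-squared is invariant under affine rescaling of x; slope scales inversely", {
  withr::with_seed(3, {
    x <- runif(8, 1, 20)
    y <- -2 * x + 100 + rnorm(8, sd = 4)
    f1 <- fit_curve(x, y)
    f2 <- fit_curve(5 * x + 7, y)
    expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
    expect_equal(f2$slope, f1$slope / 5, tolerance = 1e-12)
  })
})

test_that("optimized-channel selection takes max r2 with fixed-order tie-break", {
  mk <- function(r2) structure(list(slope = 1, intercept = 0, r_squared = r2,
                                    n_points = 5), class = "fit_result")
  expect_identical(
    select_optimized_channel(list(R = mk(0.9442), G = mk(0.60), B = mk(0.41))),
    "R")
  expect_identical(select_optimized_channel(list(G = mk(0.9), R = mk(0.9))), "R")
  expect_identical(select_optimized_channel(list(B = mk(0.9104))), "B")
  expect_identical(
    select_optimized_channel(list(S = mk(0.8), V = mk(0.95), H = mk(0.95))),
    "H")
  expect_error(select_optimized_channel(list()), "no channel")
  expect_error(select_optimized_channel(list(Z = mk(0.5))), "named by channels")
})

test_that("screen_linearity fits every requested channel and keys by channel", {
  cv <- builtin_panel()$pH
  series <- dilution_series(cv, noise = noise_model(0, 1, 1))
  fits <- screen_linearity(series, channels = c("R", "G", "B"))
  expect_named(fits, c("R", "G", "B"))
  expect_equal(fits$R$r_squared, 1)          # generating channel is exact
  expect_lt(fits$G$r_squared, 1)             # quadratic ramps are not linear
  expect_identical(select_optimized_channel(fits), "R")

  hv <- screen_linearity(series, channels = c("R", "V"))
  expect_named(hv, c("R", "V"))
  expect_s3_class(hv$V, "fit_result")
})
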