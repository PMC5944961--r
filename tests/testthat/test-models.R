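test_that("the registry holds the seven models with their parameter counts", {
  reg <- sadModels()
  expect_length(reg, 7)
  expect_identical(names(reg), c("GS", "BS", "ON", "LSer", "LN", "LC", "LS"))
  k <- vapply(reg, nParameters, integer(1))
  expect_equal(unname(k), c(1L, 2L, 1L, 2L, 3L, 3L, 3L))
  # lower-case config aliases resolve to the same specs
  expect_identical(modelName(sadModel("lc")), "LC")
  expect_error(sadModel("weibull"), "unknown")
})

test_that("octave-scale forms evaluate to their defining values", {
  expect_equal(evaluateModel("LC", c(S_m = 10, alpha = 1, R_m = 2), 2), 10)
  expect_equal(evaluateModel("LC", c(S_m = 10, alpha = 1, R_m = 2), 3), 5)
  expect_equal(evaluateModel("LN", c(S_m = 8, alpha = 0.5, R_m = 1), 1), 8)
  expect_equal(evaluateModel("LS", c(S_m = 8, alpha = 0.5, R_m = 1), 1), 8)
  expect_equal(evaluateModel("GS", c(S_m = 4), -3:5), rep(4, 9))
  # BS at R=0: S_m exp(-alpha)
  expect_equal(evaluateModel("BS", c(S_m = 2, alpha = 1.5), 0),
               2 * exp(-1.5))
  # LSer: S(0) = S_m * alpha
  expect_equal(evaluateModel("LSer", c(S_m = 5, alpha = 0.4), 0), 2)
  expect_error(evaluateModel("LSer", c(S_m = 5, alpha = 0.4), -1), "R >= 0")
  # ON requires frozen data constants and respects its domain
  on <- evaluateModel("ON", c(S_m = 0.5), 1,
                      dataConstants = c(N_oct = 64, R_max = 5))
  expect_equal(on, 0.5 * (1 - 2 / 64) * 2)
  expect_error(
    evaluateModel("ON", c(S_m = 0.5), 8,
                  dataConstants = c(N_oct = 64, R_max = 5)),
    "N_oct")
})

test_that("LN, LC and LS are symmetric with their peak exactly at R_m", {
  for (name in c("LN", "LC", "LS")) {
    p <- c(S_m = 7, alpha = 0.7, R_m = 2.5)
    d <- seq(0.25, 6, by = 0.25)
    expect_equal(evaluateModel(name, p, p["R_m"] + d),
                 evaluateModel(name, p, p["R_m"] - d))
    expect_true(all(evaluateModel(name, p, p["R_m"] + d) < p[["S_m"]]))
    expect_equal(evaluateModel(name, p, unname(p["R_m"])), p[["S_m"]])
  }
})

test_that("tail weight orders as logCauchy > log-sech > lognormal", {
  p <- c(S_m = 10, alpha = 0.8, R_m = 1)
  for (d in c(4, 6, 10)) {
    lc <- evaluateModel("LC", p, 1 + d)
    ls <- evaluateModel("LS", p, 1 + d)
    ln <- evaluateModel("LN", p, 1 + d)
    expect_true(lc > ls && ls > ln)
  }
})

test_that("sech evaluation is overflow-safe far into the tails", {
  v <- evaluateModel("LS", c(S_m = 1, alpha = 2, R_m = 0), c(-600, 600, 1e4))
  expect_true(all(is.finite(v) & v >= 0))
})

test_that("closed-form S* matches quadrature of the untruncated curve to 0.1%", {
  cases <- list(
    list(name = "BS", p = c(S_m = 3.2, alpha = 0.07)),
    list(name = "LN", p = c(S_m = 12, alpha = 0.55, R_m = 1.4)),
    list(name = "LC", p = c(S_m = 10, alpha = 0.5, R_m = 1)),
    list(name = "LS", p = c(S_m = 25, alpha = 1.3, R_m = 0.2)))
  for (cs in cases) {
    quad <- integrate(function(x) evaluateModel(cs$name, cs$p, x),
                      lower = -Inf, upper = Inf,
                      rel.tol = 1e-10, abs.tol = 0)$value
    expect_equal(totalRichness(cs$name, cs$p), quad,
                 tolerance = 1e-3, label = cs$name)
  }
  # pinned closed-form values
  expect_equal(totalRichness("LC", c(S_m = 10, alpha = 0.5)), 20 * pi)
  expect_equal(totalRichness("BS", c(S_m = log(2), alpha = 1)), 1)
  # ON uses the published S_m/(2 ln 2) form
  expect_equal(totalRichness("ON", c(S_m = 3)), 3 / (2 * log(2)))
})

test_that("GS and LSer refuse richness extrapolation", {
  expect_error(totalRichness("GS", c(S_m = 5)), "cannot extrapolate")
  expect_error(totalRichness("LSer", c(S_m = 5, alpha = 0.5)),
               "cannot extrapolate")
})
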