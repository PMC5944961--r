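test_that("adjusted R^2 follows its definition, including negative values", {
  expect_equal(adjustedRSquared(c(3, 1, 1, 6), c(3, 1, 1, 6), k = 3), 1)
  # hand-computed: 1 - (18/1)/(14/3/2) = -6.714286
  expect_equal(adjustedRSquared(c(4, 2, 1), c(1, 2, 4), k = 2),
               1 - (18 / 1) / ((14 / 3) / 2), tolerance = 1e-12)
  expect_equal(round(adjustedRSquared(c(4, 2, 1), c(1, 2, 4), k = 2), 3),
               -6.714)
  # constant fit at the mean with k = 1 is exactly zero
  obs <- c(9, 4, 2, 1, 1)
  expect_identical(adjustedRSquared(obs, rep(mean(obs), 5), k = 1), 0)
  # plain R^2 differs when requested
  expect_equal(adjustedRSquared(obs, rep(mean(obs), 5), k = 1,
                                adjusted = FALSE), 0)
  expect_error(adjustedRSquared(1:3, 1:3, k = 3), "undefined")
  expect_error(adjustedRSquared(c(2, 2), c(2, 2), k = 1), "zero variance")
})

test_that("chi-square gof reproduces table values and handles pooling", {
  g <- chiSquareGof(c(10, 5), c(8, 7), k = 1)
  expect_equal(g$chi2, 4 / 8 + 4 / 7, tolerance = 1e-12)
  expect_equal(g$df, 1)
  expect_equal(g$P, 0.3006, tolerance = 1e-3)  # chi^2_1 upper tail table

  perfect <- chiSquareGof(c(6, 3, 2), c(6, 3, 2), k = 1)
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$P, 1)

  # classes with expectation < 1 merge with their inner neighbour
  pooled <- chiSquareGof(c(5, 3, 1), c(5.2, 3.1, 0.4), k = 1)
  expect_equal(pooled$nPooled, 2)
  expect_equal(pooled$chi2,
               (5 - 5.2) ^ 2 / 5.2 + (4 - 3.5) ^ 2 / 3.5,
               tolerance = 1e-12)

  # df below one leaves P undefined
  und <- chiSquareGof(c(10, 5), c(8, 7), k = 2)
  expect_true(is.na(und$P))
  expect_error(chiSquareGof(c(1, 1), c(0.2, 0.3), k = 1), "not applicable")
})

test_that("information criteria evaluate exactly with the -Inf sentinel at SS = 0", {
  ic <- informationCriteria(SS = 1, n = 8, k = 3)
  expect_equal(unname(ic["AIC"]), 6 - 8 * log(8), tolerance = 1e-12)
  expect_equal(unname(ic["BIC"]), 3 * log(8) - 8 * log(8), tolerance = 1e-12)
  expect_equal(round(unname(ic), 3), c(-10.636, -10.397))
  expect_identical(unname(informationCriteria(0, 5, 2)), c(-Inf, -Inf))
})

test_that("noiseless model histograms are exact fixed points of the fit", {
  cases <- list(
    list(name = "GS", p = c(S_m = 5)),
    list(name = "BS", p = c(S_m = 30, alpha = 0.12)),
    list(name = "LSer", p = c(S_m = 40, alpha = 0.82)),
    list(name = "LN", p = c(S_m = 15, alpha = 0.6, R_m = 2)),
    list(name = "LC", p = c(S_m = 12, alpha = 0.8, R_m = 1)),
    list(name = "LS", p = c(S_m = 18, alpha = 0.7, R_m = 2)))
  for (cs in cases) {
    h <- expectedHistogram(cs$name, cs$p, 1:8)
    f <- fitModel(cs$name, h)
    expect_lt(f@SS, 1e-10)
    expect_equal(unname(parameters(f)), unname(cs$p), tolerance = 1e-6,
                 label = cs$name)
    expect_true(f@converged)
    if (cs$name != "GS") expect_equal(f@Rd2, 1, tolerance = 1e-9)
  }
})

test_that("the ON fit is an exact fixed point of its self-consistent histogram", {
  # choose counts S(R) = S_m (1 - 2^R/N_oct) 2^R whose own octave total
  # equals N_oct, found by root solving
  Sm <- 0.08
  octs <- 1:6
  f <- function(Noct) Sm * sum((1 - 2 ^ octs / Noct) * 4 ^ octs) - Noct
  Noct <- uniroot(f, c(100, 1e5), tol = 1e-12)$root
  counts <- Sm * (1 - 2 ^ octs / Noct) * 2 ^ octs
  h <- octaveHistogram(octs, counts)
  expect_equal(octaveTotal(h), Noct, tolerance = 1e-8)
  fit <- fitModel("ON", h)
  expect_lt(fit@SS, 1e-16)
  expect_equal(unname(parameters(fit)), Sm, tolerance = 1e-8)
})

test_that("the GS fit is the mean with zero adjusted R^2 and SS = SS_tot", {
  h <- noisyHistogram(1)
  f <- fitModel("GS", h)
  Sobs <- unname(octaveCounts(h))
  expect_equal(unname(parameters(f)), mean(Sobs))
  expect_equal(f@SS, sum((Sobs - mean(Sobs)) ^ 2))
  expect_identical(f@Rd2, 0)
})

test_that("AIC - BIC equals k(2 - ln n) on every fitted model", {
  h <- noisyHistogram(2)
  cmp <- fitAllModels(h)
  for (f in sadFits(cmp)) {
    expect_equal(f@AIC - f@BIC, f@k * (2 - log(f@n)), tolerance = 1e-10,
                 label = modelName(f))
  }
})

test_that("LM never loses to a dense brute-force parameter grid", {
  for (seed in 1:6) {
    h <- noisyHistogram(seed)
    f <- fitModel("LC", h)
    Sobs <- unname(octaveCounts(h))
    grid <- bruteForceSS("LC", h,
                         SmGrid = seq(0.2, 2, length.out = 40) * max(Sobs),
                         alphaGrid = seq(0.05, 4, length.out = 45),
                         RmGrid = seq(-1, 11, length.out = 49))
    expect_lte(f@SS, grid + 1e-6)
  }
})

test_that("the fitted curve is a fixed point of refitting", {
  h <- noisyHistogram(3)
  f <- fitModel("LC", h)
  h2 <- expectedHistogram("LC", parameters(f), octaves(h))
  f2 <- fitModel("LC", h2)
  expect_equal(unname(parameters(f2)), unname(parameters(f)),
               tolerance = 1e-6)
})

test_that("rescaling counts rescales S_m and leaves shape parameters fixed", {
  h <- noisyHistogram(4)
  for (name in c("GS", "LN", "LC", "LS")) {
    f1 <- fitModel(name, h)
    h2 <- octaveHistogram(octaves(h), 3.5 * unname(octaveCounts(h)))
    f2 <- fitModel(name, h2)
    expect_equal(parameters(f2)[["S_m"]], 3.5 * parameters(f1)[["S_m"]],
                 tolerance = 1e-4, label = name)
    if (name != "GS") {
      expect_equal(parameters(f2)[["alpha"]], parameters(f1)[["alpha"]],
                   tolerance = 1e-4)
      expect_equal(parameters(f2)[["R_m"]], parameters(f1)[["R_m"]],
                   tolerance = 1e-4)
    }
  }
})

test_that("too few octaves for the parameter count is an error", {
  h <- octaveHistogram(1:2, c(4, 2))
  expect_error(fitModel("LC", h), "insufficient data")
})

test_that("fractional counts from the halving dialect enter the fit as-is", {
  ds <- toyDataset(c(1, 2, 3, 4, 4, 7, 8, 16, 20))
  h <- binOctaves(ds, dialect = "preston_halving")
  expect_true(any(octaveCounts(h) %% 1 != 0))
  f <- fitModel("LC", h)
  expect_true(is.finite(f@SS))
  expect_equal(f@SS, sum((h@count - fittedValues(f)) ^ 2), tolerance = 1e-10)
})
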