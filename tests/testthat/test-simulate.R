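test_that("geometric-series ranks follow p_j = k(1-k)^(j-1) exactly", {
  ds <- simulateCommunity("GS", S = 4, k = 0.5, N = 160, seed = 1)
  expect_equal(unname(abundances(ds)), c(80, 40, 20, 10))
  # proportions sum to the geometric partial sum 1 - (1-k)^S
  k <- 0.3; S <- 25
  p <- k * (1 - k) ^ (0:(S - 1))
  expect_equal(sum(p), 1 - (1 - 0.3) ^ 25, tolerance = 1e-12)
})

test_that("broken-stick ranks telescope to proportions summing to one", {
  ds <- simulateCommunity("BS", S = 3, N = 18, seed = 1)
  expect_equal(unname(abundances(ds)), c(11, 5, 2))
  for (S in c(3, 10, 57)) {
    p <- rev(cumsum(1 / rev(seq_len(S)))) / S
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(diff(p) < 0))
  }
})

test_that("identical seed and configuration reproduce the dataset exactly", {
  a <- simulateCommunity("LC", S = 50, alpha = 0.8, R_m = 1, seed = 77)
  b <- simulateCommunity("LC", S = 50, alpha = 0.8, R_m = 1, seed = 77)
  expect_identical(abundances(a), abundances(b))
  c1 <- simulateCommunity("LSer", S = 40, alpha = 0.9, seed = 3)
  c2 <- simulateCommunity("LSer", S = 40, alpha = 0.9, seed = 3)
  expect_identical(abundances(c1), abundances(c2))
})

test_that("the overlapping-niche sampler draws from the linear density 2 - 2r", {
  set.seed(42)
  x <- octavesad:::qlinearON(runif(1e5))
  ks <- suppressWarnings(ks.test(x, function(q) 2 * q - q ^ 2))
  expect_gt(ks$p.value, 0.001)
  expect_true(all(x >= 0 & x <= 1))
})

test_that("the hyperbolic-secant inverse CDF agrees with rejection sampling", {
  alpha <- 0.7; Rm <- 1
  set.seed(7)
  inv <- octavesad:::qsech(runif(5000), Rm, alpha)
  # rejection sampler: Laplace proposal, envelope sech(u) <= 2 exp(-|u|)
  rejection <- function(n) {
    out <- numeric(0)
    while (length(out) < n) {
      u <- rexp(2 * n) * sample(c(-1, 1), 2 * n, replace = TRUE)
      keep <- runif(2 * n) < (1 / cosh(u)) * exp(abs(u)) / 2
      out <- c(out, u[keep])
    }
    Rm + out[seq_len(n)] / alpha
  }
  rej <- rejection(5000)
  ks <- suppressWarnings(ks.test(inv, rej))
  expect_gt(ks$p.value, 0.001)
  # analytic CDF cross-check at fixed points
  emp <- ecdf(inv)
  for (x in c(-1, 0, 1, 2, 4)) {
    expect_lt(abs(emp(x) - (2 / pi) * atan(exp(alpha * (x - Rm)))), 0.03)
  }
})

test_that("logseries draws follow the alpha^r / r law", {
  alpha <- 0.9
  ds <- simulateCommunity("LSer", S = 20000, alpha = alpha, seed = 11)
  ab <- unname(abundances(ds))
  E1 <- pracma::expint_E1
  Fc <- function(r) 1 - E1(-r * log(alpha)) / E1(-log(alpha))
  # integer abundance j collects the continuous mass around it
  probs <- diff(sapply(c(1, seq(1.5, 20.5, by = 1)), Fc))
  probs <- c(probs, 1 - Fc(20.5))
  obs <- tabulate(pmin(ab, 21), nbins = 21)
  cs <- suppressWarnings(chisq.test(obs, p = probs / sum(probs)))
  expect_gt(cs$p.value, 0.001)
})

test_that("large symmetric communities peak at the class holding the modal octave", {
  # half-open classes span (R-1, R] on the continuous log2 scale, so a
  # peak at R_m = 3.5 falls squarely in the class labelled 4
  ds <- simulateCommunity("LC", S = 10000, alpha = 0.6, R_m = 3.5,
                          seed = 19, truncateAtOne = FALSE)
  expect_identical(modalOctave(binOctaves(ds)), 4L)
  dsn <- simulateCommunity("LN", S = 10000, alpha = 0.8, R_m = 4.5, seed = 23)
  expect_identical(modalOctave(binOctaves(dsn)), 5L)
  # at the veil line the singleton class {1, 2} captures an R_m = 1 peak
  dst <- simulateCommunity("LC", S = 10000, alpha = 0.6, R_m = 1, seed = 29)
  expect_identical(modalOctave(binOctaves(dst)), 1L)
})

test_that("the veil line resamples sub-unit abundances when requested", {
  ds <- simulateCommunity("LC", S = 400, alpha = 0.6, R_m = 0, seed = 31,
                          truncateAtOne = TRUE)
  expect_equal(totalSpecies(ds), 400)
  expect_true(all(abundances(ds) >= 1))
  dsf <- simulateCommunity("LC", S = 400, alpha = 0.6, R_m = 0, seed = 31,
                           truncateAtOne = FALSE)
  expect_lt(totalSpecies(dsf), 400)
  expect_equal(totalSpecies(dsf) + attr(dsf, "dropped"), 400)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulateCommunity("GS", S = 4, k = 1.2, N = 100, seed = 1),
               "k in \\(0, 1\\)")
  expect_error(simulateCommunity("LSer", S = 10, alpha = 1.2, seed = 1),
               "alpha in \\(0, 1\\)")
  expect_error(simulateCommunity("GS", S = 4, k = 0.99, N = 5, seed = 1),
               "fewer than 3")
  expect_error(simulateCommunity("LC", S = 10, alpha = 0.5, R_m = 1),
               "seed")
})

test_that("multinomial sampling keeps the exact target total", {
  ds <- simulateCommunity("BS", S = 30, N = 500, seed = 8,
                          multinomial = TRUE)
  # dropped species carry zero individuals, so the total is exact
  expect_equal(totalIndividuals(ds), 500)
})

test_that("expected histograms are noiseless model evaluations", {
  h <- expectedHistogram("LC", c(S_m = 12, alpha = 0.8, R_m = 1), 1:8)
  expect_equal(unname(octaveCounts(h))[1], 12)
  expect_equal(length(octaves(h)), 8)
  hg <- expectedHistogram("GS", c(S_m = 5), 2:6)
  expect_equal(unname(octaveCounts(hg)), rep(5, 5))
  # BS octave curve integrates to its closed-form richness
  p <- c(S_m = 11, alpha = 0.23)
  quad <- integrate(function(x) evaluateModel("BS", p, x), -Inf, Inf,
                    rel.tol = 1e-10)$value
  expect_equal(quad, p[["S_m"]] / (p[["alpha"]] * log(2)), tolerance = 1e-6)
})
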