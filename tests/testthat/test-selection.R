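test_that("fitAllModels returns seven rows in the fixed order and never aborts", {
  # only 2 octaves: the 3-parameter models must fail gracefully
  h <- octaveHistogram(1:2, c(6, 2))
  cmp <- fitAllModels(h)
  df <- as.data.frame(cmp)
  expect_equal(nrow(df), 7)
  expect_identical(df$model, c("GS", "BS", "ON", "LSer", "LN", "LC", "LS"))
  expect_false(any(df$converged[df$model %in% c("LN", "LC", "LS")]))
  expect_true(all(is.na(df$SS[df$model %in% c("LN", "LC", "LS")])))
  expect_true(df$converged[df$model == "GS"])
})

test_that("a noiseless generated histogram selects its own model everywhere", {
  hLC <- expectedHistogram("LC", c(S_m = 12, alpha = 0.8, R_m = 1), 1:8)
  cmp <- fitAllModels(hLC)
  expect_lt(sadFits(cmp)$LC@SS, 1e-10)
  expect_identical(selectBest(cmp, "aic"), "LC")
  expect_identical(selectBest(cmp, "bic"), "LC")

  hLN <- expectedHistogram("LN", c(S_m = 15, alpha = 0.6, R_m = 2), 1:8)
  expect_identical(selectBest(fitAllModels(hLN), "aic"), "LN")
})

test_that("adequacy flags encode the P >= 0.05 and R_d^2 >= 0.50 criteria", {
  ds <- simulateCommunity("LC", S = 300, alpha = 0.7, R_m = 1, seed = 9)
  cmp <- fitAllModels(binOctaves(ds))
  fl <- adequacyFlags(cmp)
  expect_identical(names(fl), c("model", "chi2Pass", "r2Pass"))
  # the constant model never reaches the R^2 floor
  expect_false(fl$r2Pass[fl$model == "GS"])
  # flags follow the stored statistics
  for (i in seq_len(7)) {
    f <- sadFits(cmp)[[i]]
    if (!is.na(f@P)) expect_identical(fl$chi2Pass[i], f@P >= 0.05)
    if (!is.na(f@Rd2)) expect_identical(fl$r2Pass[i], f@Rd2 >= 0.50)
  }
  # stricter thresholds flip flags accordingly
  fl2 <- adequacyFlags(cmp, options = fitOptions(r2Threshold = 1.01))
  expect_true(all(!fl2$r2Pass, na.rm = TRUE))
})

test_that("best-model selection is order-invariant and breaks ties by parsimony", {
  ds <- simulateCommunity("LC", S = 400, alpha = 0.6, R_m = 1, seed = 5)
  h <- binOctaves(ds)
  cmp <- fitAllModels(h)
  best <- selectBest(cmp, "aic")
  # reversing the stored row order cannot change the winner
  rev_cmp <- new("SADComparison", label = cmp@label,
                 fits = rev(sadFits(cmp)), options = cmp@options)
  expect_identical(selectBest(rev_cmp, "aic"), best)

  # equal AIC: the model with fewer parameters wins
  mkFit <- function(model, k, aic) {
    new("SADFit", model = model, params = c(S_m = 1), dataConstants = numeric(),
        octave = 1:4, observed = rep(1, 4), fitted = rep(1, 4), SS = 1,
        n = 4L, k = as.integer(k), Rd2 = 0.5, chi2 = 1, df = 1, P = 0.5,
        AIC = aic, BIC = aic, Sstar = NA_real_, converged = TRUE, note = "")
  }
  fits <- list(GS = mkFit("GS", 1, 10), BS = mkFit("BS", 2, 5),
               ON = mkFit("ON", 1, 10), LSer = mkFit("LSer", 2, 10),
               LN = mkFit("LN", 3, 5), LC = mkFit("LC", 3, 10),
               LS = mkFit("LS", 3, 10))
  tie <- new("SADComparison", label = "", fits = fits, options = fitOptions())
  expect_identical(selectBest(tie, "aic"), "BS")  # k=2 beats k=3 at AIC 5
})

test_that("the overall rule restricts to chi-square-adequate models when any pass", {
  ds <- simulateCommunity("LC", S = 400, alpha = 0.6, R_m = 1, seed = 13)
  cmp <- fitAllModels(binOctaves(ds))
  fl <- adequacyFlags(cmp)
  best <- selectBest(cmp, "overall")
  if (any(fl$chi2Pass, na.rm = TRUE))
    expect_true(isTRUE(fl$chi2Pass[fl$model == best]))
})

test_that("the richness table reports S* for the five supported models", {
  ds <- simulateCommunity("LC", S = 400, alpha = 0.6, R_m = 1, seed = 21)
  cmp <- fitAllModels(binOctaves(ds))
  rt <- richnessTable(cmp)
  expect_equal(nrow(rt), 1)
  expect_true(all(c("Sstar_BS", "Sstar_ON", "Sstar_LN", "Sstar_LC",
                    "Sstar_LS") %in% names(rt)))
  expect_false(any(grepl("Sstar_GS|Sstar_LSer", names(rt))))
  for (m in c("BS", "ON", "LN", "LC", "LS")) {
    expect_identical(rt[[paste0("exceeds_", m)]],
                     rt[[paste0("Sstar_", m)]] > rt$S)
  }
})

test_that("fit results serialise to JSON with the selection verdicts", {
  h <- expectedHistogram("LC", c(S_m = 12, alpha = 0.8, R_m = 1), 1:8)
  cmp <- fitAllModels(h)
  js <- jsonlite::fromJSON(fitToJSON(cmp), simplifyVector = FALSE)
  expect_length(js$fits, 7)
  expect_identical(js$best$aic, "LC")
  expect_equal(js$fits$LC$params$S_m, 12, tolerance = 1e-6)
})
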