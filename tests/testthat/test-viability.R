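test_that("full survival reproduces the Mendelian distribution exactly", {
  M <- enumerate_offspring(fixture_cross1())
  G <- adjusted_frequencies(M, model_preset("A"), "E8.5")
  expect_identical(unname(G), M$mendelian_fraction)
})

test_that("adjusted frequencies match closed-form hand calculations", {
  M <- enumerate_offspring(fixture_cross1())
  # lethal double-mutant male only: G5 = (1/8) / (15/16) = 2/15
  G <- adjusted_frequencies(M, model_preset("B"), "E10.5")
  expect_equal(G[["5"]], 2 / 15, tolerance = 1e-15)
  expect_identical(G[["12"]], 0)
  expect_equal(sum(G), 1, tolerance = 1e-12)
})

test_that("adjusted frequencies agree with the Monte-Carlo thinning oracle", {
  set.seed(2471)
  combos <- expand.grid(d10 = c("+/+", "+/-"), d12 = c("+/+", "+/-", "-/-"),
                        s10 = c("+/Y", "-/Y"), s12 = c("+/+", "+/-", "-/-"),
                        stringsAsFactors = FALSE)
  for (i in sample(nrow(combos), 12)) {
    cr <- cross_spec("t", dam = c(Naa10 = combos$d10[i], Naa12 = combos$d12[i]),
                     sire = c(Naa10 = combos$s10[i], Naa12 = combos$s12[i]))
    M <- enumerate_offspring(cr)
    S <- matrix(1, nrow(M), 5,
                dimnames = list(as.character(M$class_number), age_stages()))
    wt <- wildtype_classes(M)
    for (cl in setdiff(M$class_number, wt))
      S[as.character(cl), ] <- sort(stats::runif(5), decreasing = TRUE)
    age <- sample(age_stages(), 1)
    G <- adjusted_frequencies(M, survival_schedule(S, percent = FALSE), age)
    mc <- oracle_thinning(M$mendelian_fraction, S[, age], 2e5)
    se <- sqrt(G * (1 - G) / mc$n_alive)
    expect_true(all(abs(mc$freq - G) <= 3 * se + 1e-9))
  }
})

test_that("normalization and monotone response to a single survival rate", {
  M <- enumerate_offspring(fixture_cross1())
  base <- unclass(model_preset("D4"))
  G0 <- adjusted_frequencies(M, model_preset("D4"), "P3")
  expect_equal(sum(G0), 1, tolerance = 1e-12)

  lower <- base; lower["5", "P3"] <- 0.20
  G1 <- adjusted_frequencies(M, survival_schedule(lower, percent = FALSE), "P3")
  expect_lt(G1[["5"]], G0[["5"]])
  others <- setdiff(names(G0), "5")
  expect_true(all(G1[others] >= G0[others]))
  expect_equal(sum(G1), 1, tolerance = 1e-12)
})

test_that("an all-lethal schedule is rejected", {
  M <- enumerate_offspring(fixture_cross1())
  S <- matrix(0, 12, 5, dimnames = list(as.character(1:12), age_stages()))
  expect_error(
    adjusted_frequencies(M, structure(S, class = c("survival_schedule", "matrix")),
                         "E8.5"),
    "no surviving genotypes")
})

test_that("expected counts scale frequencies by the genotyped total", {
  G <- stats::setNames(rep(0.25, 4), 1:4)
  expect_identical(unname(expected_counts(G, 16)), rep(4, 4))

  M <- enumerate_offspring(fixture_cross1())
  E <- expected_counts(adjusted_frequencies(M, model_preset("A"), "P3"), 160)
  expect_equal(E[["12"]], 10)       # 160 / 16
  expect_equal(sum(E), 160)
  expect_error(expected_counts(G, -1), ">= 0")

  # pooling two crosses keeps per-cross Mendelian fractions
  crs <- fixture_crosses()
  M2 <- enumerate_offspring(crs[[2]])
  E1 <- expected_counts(adjusted_frequencies(M, model_preset("A"), "P3"), 100)
  E2 <- expected_counts(adjusted_frequencies(M2, model_preset("A"), "P3"), 60)
  pooled <- E1 + E2
  expect_equal(pooled[["12"]], 100 / 16 + 60 / 8)
})

test_that("cumulative expectations sum cross-sectional samples", {
  per_age <- list(E10.5 = c(`12` = 7.9), E18.5 = c(`12` = 6.6))
  expect_equal(cumulative_expected(per_age)[["12"]], 14.5)
  expect_equal(cumulative_expected(per_age, up_to = "E10.5")[["12"]], 7.9)

  set.seed(5)
  tabs <- lapply(age_stages(), function(a) stats::setNames(rpois(12, 10), 1:12))
  names(tabs) <- age_stages()
  want <- Reduce(`+`, tabs[1:4])   # brute-force sum up to E18.5
  expect_identical(cumulative_expected(tabs, up_to = "E18.5"), want)
})

test_that("implied litter size inverts the total survival fraction", {
  M <- enumerate_offspring(fixture_cross1())
  # no mortality: conception litter equals the observed litter
  r0 <- implied_litter_size(4.9, M, model_preset("A"), "P3")
  expect_identical(r0$conception_litter, 4.9)
  expect_identical(r0$survival_fraction, 1)

  # final model at the postnatal census: survival fraction 0.640625;
  # projecting the wildtype mean litter of 8.6 predicts 5.51 pups
  r1 <- implied_litter_size(4.9, M, model_preset("D4"), "P3",
                            reference_wt_litter = 8.6)
  expect_equal(r1$survival_fraction, 0.640625, tolerance = 1e-12)
  expect_equal(r1$predicted_litter, 5.509375, tolerance = 1e-12)
  expect_equal(r1$conception_litter, 4.9 / 0.640625, tolerance = 1e-12)

  # halving the survival fraction doubles the implied conception litter
  S <- unclass(model_preset("A")); S["5", ] <- 0.2  # arbitrary single change
  r2 <- implied_litter_size(4.9, M, survival_schedule(S, percent = FALSE), "P3")
  sf <- r2$survival_fraction
  S2 <- matrix(pmin(1, unclass(model_preset("A")) * sf / 2), 12, 5,
               dimnames = dimnames(S))
  expect_error(implied_litter_size(0, M, model_preset("A"), "P3"), "> 0")
  expect_equal(implied_litter_size(4.9, M, survival_schedule(S2, percent = FALSE),
                                   "P3")$conception_litter,
               4.9 / (sf / 2), tolerance = 1e-12)
})
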