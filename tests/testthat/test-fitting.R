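test_that("deltas subtract expected from observed over a matched class set", {
  obs <- stats::setNames(c(3, 5), c("1", "2"))
  expect_identical(deltas(obs, obs), stats::setNames(c(0, 0), c("1", "2")))
  expect_equal(deltas(c(`12` = 0), c(`12` = 7.9))[["12"]], -7.9)
  expect_error(deltas(obs, c(`1` = 3)), "class sets")

  set.seed(8)
  o <- stats::setNames(rpois(12, 5), 1:12)
  e <- stats::setNames(stats::runif(12, 0, 10), 1:12)
  expect_identical(deltas(o, e), o - e)
})

test_that("relative SD is the sample SD of deltas over animals observed", {
  expect_equal(relative_sd(c(2, -2), 16), sqrt(8) / 16)           # 0.1768
  expect_equal(round(relative_sd(c(2, -2), 16), 4), 0.1768)
  expect_identical(relative_sd(rep(3.2, 5), 10), 0)               # no dispersion

  d <- c(1.5, -2, 0.5, 0)
  expect_equal(relative_sd(3 * d, 3 * 12), relative_sd(d, 12))    # scale-free
  expect_equal(relative_sd(sample(d), 12), relative_sd(d, 12))    # order-free
  expect_equal(relative_sd(c(2, -2), 16, type = "population"), 2 / 16)
  expect_error(relative_sd(c(1, -1), 0), "> 0")
  expect_error(relative_sd(1, 10), "two classes")
})

test_that("model evaluation is deterministic and reduces to the single-age metric", {
  study <- fixture_study(model_preset("D4"), litters = 30, seed = 11)
  crs <- fixture_crosses()
  r1 <- evaluate_model("D4", study$counts, crs)
  r2 <- evaluate_model("D4", study$counts, crs)
  expect_identical(r1, r2)

  # deltas sum to zero at every scope (expected totals match observed totals)
  sums <- tapply(r1$table$delta, list(r1$table$age, r1$table$scope), sum)
  expect_true(all(abs(sums) < 1e-9))

  # single age: the overall combined metric equals that age's metric
  one <- study$counts[study$counts$age == "P3", ]
  rp <- evaluate_model("D4", observed_counts(one), crs)
  expect_equal(rp$overall, rp$rel_sd$relative_sd[rp$rel_sd$scope == "age_specific"])

  expect_error(evaluate_model("A", study$counts, crs[1]), "missing cross definition")
})

test_that("the generating model scores better than a mismatched one on large samples", {
  studyA <- fixture_study(model_preset("A"), litters = 150, seed = 21)
  crs <- fixture_crosses()
  expect_lt(evaluate_model("A", studyA$counts, crs)$overall,
            evaluate_model("D4", studyA$counts, crs)$overall)

  studyD <- fixture_study(model_preset("D4"), litters = 150, seed = 22)
  expect_lte(evaluate_model("D4", studyD$counts, crs)$overall,
             evaluate_model("A", studyD$counts, crs)$overall)
})

test_that("classes never observed are fitted as fully lethal", {
  study <- fixture_study(model_preset("B"), litters = 10, seed = 31)
  expect_gte(sum(study$counts$count[!is.na(study$counts$class_number)]), 400)
  fit <- fit_schedule(study$counts, fixture_crosses(), free_classes = 12)
  expect_identical(unname(unclass(fit$schedule)["12", ]), rep(0, 5))
})

test_that("fitted schedules respect bounds and monotonicity and recover truth", {
  study <- fixture_study(model_preset("D4"), litters = 120, seed = 33)
  crs <- fixture_crosses()
  fit <- fit_schedule(study$counts, crs, free_classes = c(12, 11, 6, 10, 5))
  S <- unclass(fit$schedule)
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(t(apply(S, 1, diff)) <= 1e-12))
  expect_true(all(S[as.character(c(1:4, 7:9)), ] == 1))
  # well-identified cells land near the generating values
  expect_lt(abs(S["11", "E8.5"] - 0.40), 0.10)
  expect_lt(abs(S["6", "E10.5"] - 0.33), 0.12)
  expect_identical(unname(S["12", ]), rep(0, 5))

  expect_error(fit_schedule(study$counts, crs, free_classes = 1), "wildtype")
  expect_error(fit_schedule(study$counts, crs, free_classes = 5, grid_step = 0.6),
               "grid_step")
})

test_that("an optimal base schedule is a fixed point of the fitter (up to grid)", {
  study <- fixture_study(model_preset("A"), litters = 200, seed = 35)
  fit <- fit_schedule(study$counts, fixture_crosses(),
                      free_classes = c(5, 6, 10, 11))
  expect_true(all(unclass(fit$schedule) >= 0.90))
})

test_that("the staged sequence reproduces its defining structure", {
  study <- fixture_study(model_preset("D4"), litters = 120, seed = 40)
  crs <- fixture_crosses()
  st <- staged_models(study$counts, crs)
  expect_identical(names(st), c("A", "B", "C", "D3", "D4"))

  # stage A is the plain Mendelian evaluation
  expect_equal(st$A$report$overall, evaluate_model("A", study$counts, crs)$overall)
  expect_true(all(unclass(st$A$schedule) == 1))

  # stage B always assigns the double-mutant male class zero survival
  expect_true(all(unclass(st$B$schedule)["12", ] == 0))

  # stages only ever improve the overall fit on data they can describe
  overall <- vapply(st, function(s) s$report$overall, 0)
  expect_true(all(diff(overall) <= 1e-12))
})
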