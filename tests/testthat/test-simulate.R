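test_that("one seed determines the whole study", {
  cfg <- sim_config(fixture_crosses(), model_preset("D4"),
                    litters_per_age = 20, seed = 123)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_study(sim_config(fixture_crosses(), model_preset("D4"),
                                  litters_per_age = 20, seed = 124))
  expect_false(identical(s1$litters, s3$litters))
})

test_that("with full survival the class frequencies are Mendelian", {
  cr <- fixture_cross1()
  cfg <- sim_config(cr, model_preset("A"),
                    litters_per_age = c(E8.5 = 11700, E10.5 = 0, E12.5 = 0,
                                        E18.5 = 0, P3 = 0), seed = 5)
  study <- simulate_study(cfg)
  expect_gt(nrow(study$litters), 1e5)
  expect_true(all(study$litters$status == "alive"))  # nothing dies under model A
  M <- enumerate_offspring(cr)
  n <- nrow(study$litters)
  freq <- tabulate(study$litters$class_number, 12) / n
  se <- sqrt(M$mendelian_fraction * (1 - M$mendelian_fraction) / n)
  expect_true(all(abs(freq - M$mendelian_fraction) <= 3 * se + 1e-9))
})

test_that("a fully lethal class never appears among survivors", {
  for (seed in 1:3) {
    study <- fixture_study(model_preset("B"), litters = 25, seed = seed)
    alive <- study$litters[study$litters$status == "alive", ]
    expect_false(any(alive$class_number == 12))
    expect_false(any(study$counts$class_number == 12 & study$counts$count > 0,
                     na.rm = TRUE))
  }
})

test_that("simulator marginals converge to the closed-form adjusted frequencies", {
  # the central dual-route check: stage-wise Bernoulli thinning in the
  # simulator vs the renormalization formula
  set.seed(99)
  S <- random_schedule()
  cr <- fixture_cross1()
  cfg <- sim_config(cr, S, litters_per_age = 700, seed = 17)
  study <- simulate_study(cfg)
  M <- enumerate_offspring(cr)
  for (age in c("E8.5", "E18.5", "P3")) {
    alive <- study$litters[study$litters$age == age &
                             study$litters$status == "alive", ]
    G <- adjusted_frequencies(M, S, age)
    freq <- tabulate(alive$class_number, 12) / nrow(alive)
    se <- sqrt(G * (1 - G) / nrow(alive))
    expect_true(all(abs(freq - G) <= 3.5 * se + 1e-9), label = age)
  }
})

test_that("genotyped totals follow litters x mean size x survival fraction", {
  cr <- fixture_cross1()
  M <- enumerate_offspring(cr)
  cfg <- sim_config(cr, model_preset("D4"), litters_per_age = 500, seed = 29)
  study <- simulate_study(cfg)
  gt <- genotyped_totals(study$counts)
  for (age in c("E10.5", "P3")) {
    sf <- sum(M$mendelian_fraction * unclass(model_preset("D4"))[as.character(M$class_number), age])
    want <- 500 * 8.6 * sf
    got <- gt$n_genotyped[gt$age == age]
    expect_lt(abs(got - want) / want, 0.05)
  }
})

test_that("the un-genotyped tally tracks the resorption-recovery rate", {
  base <- function(rate, seed) {
    cfg <- sim_config(fixture_cross1(), model_preset("D4"), litters_per_age = 50,
                      ungenotyped_rate = rate, seed = seed)
    simulate_study(cfg)
  }
  all_lost <- base(1, 3)
  expect_false(any(all_lost$litters$status == "dead_genotyped"))
  expect_gt(sum(all_lost$counts$count[is.na(all_lost$counts$class_number)]), 0)

  none_lost <- base(0, 3)
  expect_false(any(none_lost$litters$status == "dead_ungenotyped"))
  expect_false(any(is.na(none_lost$counts$class_number)))
})

test_that("invalid simulation configurations are rejected", {
  crs <- fixture_crosses()
  expect_error(sim_config(crs, model_preset("A"),
                          litter_size_model = list(family = "poisson", mean = 0)),
               "> 0")
  expect_error(sim_config(crs, model_preset("A"),
                          litter_size_model = list(family = "gamma", mean = 5)),
               "poisson")
  expect_error(sim_config(crs, model_preset("A"), ungenotyped_rate = 1.5),
               "\\[0, 1\\]")
  expect_error(sim_config(crs, model_preset("A"), litters_per_age = -1),
               "nonnegative")
})

test_that("recovery experiments aggregate seeded replicate fits", {
  cfg <- sim_config(fixture_crosses(), model_preset("A"), litters_per_age = 60,
                    seed = 1)
  rec <- recovery_experiment(model_preset("D4"), cfg, n_replicates = 2,
                             seed = 101, method = "direct", grid_step = 0.05)
  expect_identical(rec$seeds, c(101L, 102L))
  expect_identical(dim(rec$estimates), c(nrow(rec$summary), 2L))
  expect_true(all(c("truth", "bias", "rmse", "coverage") %in% names(rec$summary)))
  # the fully lethal class is recovered exactly in every replicate
  expect_true(all(rec$estimates[rec$summary$class_number == 12, ] == 0))
})
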