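# Independent oracles and shared fixtures. Each oracle is a deliberately
# naive implementation kept separate from the package code paths it checks.

# The two modeled matings (compound-het dam x Naa12-het / Naa12-null sire).
fixture_crosses <- function() modeled_crosses()

fixture_cross1 <- function() fixture_crosses()[[1]]

# Brute-force Mendelian oracle: enumerate every (egg, sperm) gamete
# combination with equal weight. Eggs carry one X allele and one autosomal
# allele from the dam; sperm carry either the sire's X or a Y, plus one
# autosomal allele. Returns probabilities keyed "sex|naa10|naa12".
oracle_mendelian <- function(dam10, dam12, sire10, sire12) {
  d10 <- strsplit(dam10, "/")[[1]]
  d12 <- strsplit(dam12, "/")[[1]]
  s10 <- strsplit(sire10, "/")[[1]][1]   # single X allele; other is Y
  s12 <- strsplit(sire12, "/")[[1]]
  tally <- list()
  for (egg_x in d10) for (egg_a in d12)
    for (sperm_sex in c("X", "Y")) for (sperm_a in s12) {
      ord <- function(p) p[order(match(p, c("+", "-")))]  # "+" first
      if (sperm_sex == "X") {
        sex <- "female"
        g10 <- paste(ord(c(egg_x, s10)), collapse = "/")
      } else {
        sex <- "male"
        g10 <- paste0(egg_x, "/Y")
      }
      g12 <- paste(ord(c(egg_a, sperm_a)), collapse = "/")
      key <- paste(sex, g10, g12, sep = "|")
      tally[[key]] <- (tally[[key]] %||% 0) + 1
    }
  unlist(tally) / 16
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-tailed Fisher oracle: exhaustive enumeration of all tables with the
# observed margins; p = sum of point hypergeometric probabilities <= that of
# the observed table. Probabilities via log-binomial coefficients.
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; N <- r1 + r2
  pt <- function(x) exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1))
  xs <- max(0, c1 - r2):min(r1, c1)
  ps <- vapply(xs, pt, 0)
  sum(ps[ps <= pt(a) * (1 + 1e-7)])
}

# Monte-Carlo thinning oracle: draw genotypes from M, survive each with
# probability S, return the genotype frequencies among survivors.
oracle_thinning <- function(M, S, n) {
  counts <- stats::rmultinom(1, n, M)[, 1]
  alive <- stats::rbinom(length(M), counts, S)
  list(freq = alive / sum(alive), n_alive = sum(alive))
}

# Random monotone survival schedule over the 12-class design: wildtype rows
# at 1, every other row a sorted non-increasing uniform draw.
random_schedule <- function(classes = 1:12, wt = c(1, 7)) {
  S <- matrix(1, length(classes), 5,
              dimnames = list(as.character(classes), age_stages()))
  for (cl in setdiff(classes, wt))
    S[as.character(cl), ] <- sort(stats::runif(5), decreasing = TRUE)
  survival_schedule(S, percent = FALSE)
}

# Small simulated study under a given schedule (both modeled crosses).
fixture_study <- function(schedule, litters = 50, seed = 7,
                          ungenotyped_rate = 0.5) {
  cfg <- sim_config(fixture_crosses(), schedule, litters_per_age = litters,
                    ungenotyped_rate = ungenotyped_rate, seed = seed)
  simulate_study(cfg)
}
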