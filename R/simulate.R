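#' Configure a synthetic breeding study
#'
#' Defines the sampling design the simulator emulates: litters conceived
#' under each cross, harvested cross-sectionally at the embryonic stages and
#' censused once postnatally. Conceptus genotypes are multinomial draws from
#' the cross's Mendelian fractions; presence at the harvest age is a single
#' Bernoulli draw per conceptus with the cumulative survival of its genotype
#' class (equivalent, by construction, to stage-wise conditional thinning).
#'
#' @param crosses a [cross_spec()] or list of them.
#' @param schedule the true [survival_schedule()].
#' @param litters_per_age number of litters harvested at each age stage, per
#'   cross; either a single number or a named vector over [age_stages()].
#' @param litter_size_model list with `family` (`"poisson"` or `"normal"`)
#'   and `mean` (plus `sd` for normal): the litter size distribution at
#'   conception, truncated at >= 1. Default Poisson with mean 8.6, the
#'   wildtype-cross mean litter size.
#' @param ungenotyped_rate fraction of non-surviving conceptuses whose
#'   genotype cannot be recovered (resorbed/degraded); the rest are recorded
#'   as dead but genotyped.
#' @param seed integer seed; one seed determines the whole study.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(crosses, schedule, litters_per_age = 200L,
                       litter_size_model = list(family = "poisson", mean = 8.6),
                       ungenotyped_rate = 0.5, seed = 1L) {
  if (inherits(crosses, "cross_spec")) crosses <- list(crosses)
  if (is.null(names(crosses)))
    names(crosses) <- vapply(crosses, `[[`, "", "cross_id")
  if (length(litters_per_age) == 1L)
    litters_per_age <- stats::setNames(rep(as.integer(litters_per_age),
                                           length(age_stages())), age_stages())
  litters_per_age <- litters_per_age[age_stages()]
  if (any(is.na(litters_per_age)) || any(litters_per_age < 0))
    sv_stop("litters_per_age must be a nonnegative count per age stage")
  if (!litter_size_model$family %in% c("poisson", "normal"))
    sv_stop("litter_size_model$family must be 'poisson' or 'normal'")
  if (litter_size_model$mean <= 0) sv_stop("litter size mean must be > 0")
  if (identical(litter_size_model$family, "normal") &&
      (is.null(litter_size_model$sd) || litter_size_model$sd < 0))
    sv_stop("normal litter size model needs a nonnegative sd")
  if (ungenotyped_rate < 0 || ungenotyped_rate > 1)
    sv_stop("ungenotyped_rate must lie in [0, 1]")
  validate_schedule(unclass(schedule))
  structure(list(crosses = crosses, schedule = schedule,
                 litters_per_age = litters_per_age,
                 litter_size_model = litter_size_model,
                 ungenotyped_rate = ungenotyped_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

draw_litter_sizes <- function(n, model) {
  if (n == 0L) return(integer(0))
  draw <- function(m) {
    if (m$family == "poisson") stats::rpois(n, m$mean)
    else as.integer(round(stats::rnorm(n, m$mean, m$sd)))
  }
  x <- draw(model)
  while (any(x < 1L)) x[x < 1L] <- draw(model)[x < 1L]  # truncate at >= 1
  x
}

#' Simulate a breeding study
#'
#' Runs the generative model of [sim_config()]: per litter, a litter size at
#' conception, multinomial genotype draws, and binomial survival thinning to
#' the harvest age. Offspring present at harvest (live, or at least intact)
#' are genotyped and counted; non-survivors are resorptions/losses, of which
#' a fraction `1 - ungenotyped_rate` still yield a genotype (status
#' `dead_genotyped`, kept in the records but not in the default counts) and
#' the rest are tallied as un-genotyped. Fully reproducible from the config
#' seed.
#'
#' @param config a [sim_config()].
#' @return List of class `"sim_study"` with `litters` (per-offspring long
#'   table: `litter_id`, `cross_id`, `age`, `class_number`, `status`),
#'   `counts` (the derived [observed_counts()] table) and `truth` (the
#'   generating schedule).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- unclass(config$schedule)
  recs <- list(); ri <- 0L
  for (cid in names(config$crosses)) {
    M <- enumerate_offspring(config$crosses[[cid]])
    cls <- M$class_number
    surv <- S[as.character(cls), , drop = FALSE]
    for (age in age_stages()) {
      nlit <- config$litters_per_age[[age]]
      if (nlit == 0L) next
      sizes <- draw_litter_sizes(nlit, config$litter_size_model)
      tot <- sum(sizes)
      geno <- sample(cls, tot, replace = TRUE, prob = M$mendelian_fraction)
      alive <- stats::runif(tot) < surv[match(geno, cls), age]
      genotypeable <- alive | (stats::runif(tot) >= config$ungenotyped_rate)
      status <- ifelse(alive, "alive",
                       ifelse(genotypeable, "dead_genotyped", "dead_ungenotyped"))
      ri <- ri + 1L
      recs[[ri]] <- data.frame(
        litter_id = paste(cid, age, rep(seq_len(nlit), sizes), sep = "_"),
        cross_id = cid, age = age, class_number = geno, status = status,
        stringsAsFactors = FALSE)
    }
  }
  litters <- do.call(rbind, recs)
  rownames(litters) <- NULL
  structure(list(litters = litters, counts = study_counts(litters),
                 truth = config$schedule, config = config),
            class = "sim_study")
}

#' Derive the observed-counts table from per-offspring records
#'
#' Counting rule: genotyped counts include exactly the offspring present at
#' harvest (`status == "alive"`, i.e. live or at least intact); the
#' un-genotyped tally per (cross, age) counts the `dead_ungenotyped`
#' conceptuses. Dead-but-genotyped records are available for sensitivity
#' analyses but excluded here, so that observed frequencies estimate the
#' survival-adjusted distribution.
#'
#' @param litters per-offspring records as in [simulate_study()].
#' @return An [observed_counts()] table.
#' @export
study_counts <- function(litters) {
  a <- litters[litters$status == "alive", ]
  cnt <- stats::aggregate(list(count = a$status),
                          by = list(cross_id = a$cross_id, age = a$age,
                                    class_number = a$class_number),
                          FUN = length)
  u <- litters[litters$status == "dead_ungenotyped", ]
  if (nrow(u)) {
    ucnt <- stats::aggregate(list(count = u$status),
                             by = list(cross_id = u$cross_id, age = u$age),
                             FUN = length)
    ucnt$class_number <- NA_integer_
    cnt <- rbind(cnt, ucnt[, names(cnt)])
  }
  observed_counts(cnt)
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d conceptuses, %d genotyped survivors, %d crosses\n",
              nrow(x$litters), sum(x$litters$status == "alive"),
              length(unique(x$litters$cross_id))))
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Simulates replicate studies under a known (true) survival schedule, fits
#' each with the staged procedure (or a direct [fit_schedule()]), and
#' aggregates recovery error per fitted cell: bias, RMSE and coverage of the
#' +/- `band` accuracy band.
#'
#' @param truth the generating [survival_schedule()].
#' @param config a [sim_config()] (its schedule is replaced by `truth`).
#' @param n_replicates number of simulated studies.
#' @param seed base seed; replicate r runs with seed `seed + r - 1`.
#' @param cells data.frame of `class_number`, `age` cells to score (default:
#'   every non-wildtype cell with true survival < 1, plus the fully lethal
#'   class at all ages).
#' @param method `"staged"` ([staged_models()], final-stage schedule) or
#'   `"direct"` ([fit_schedule()] on all free cells).
#' @param grid_step grid resolution passed to the fitter.
#' @param band half-width of the recovery accuracy band.
#' @return List with `estimates` (cells x replicates matrix), `summary`
#'   (per-cell truth, mean, bias, RMSE, coverage) and `seeds`.
#' @export
recovery_experiment <- function(truth, config, n_replicates = 50L, seed = 1L,
                                cells = NULL, method = c("staged", "direct"),
                                grid_step = 0.01, band = 0.10) {
  method <- match.arg(method)
  Tm <- unclass(truth)
  if (is.null(cells)) {
    idx <- which(Tm < 1, arr.ind = TRUE)
    cells <- data.frame(class_number = as.integer(rownames(Tm)[idx[, 1]]),
                        age = colnames(Tm)[idx[, 2]], stringsAsFactors = FALSE)
  }
  free <- sort(unique(cells$class_number))
  seeds <- as.integer(seed + seq_len(n_replicates) - 1L)
  est <- matrix(NA_real_, nrow(cells), n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$schedule <- truth
    cfg$seed <- seeds[r]
    study <- simulate_study(cfg)
    fitted <- if (method == "staged") {
      st <- staged_models(study$counts, cfg$crosses, grid_step = grid_step)
      unclass(st$D4$schedule)
    } else {
      unclass(fit_schedule(study$counts, cfg$crosses, free_classes = free,
                           grid_step = grid_step)$schedule)
    }
    est[, r] <- fitted[cbind(as.character(cells$class_number), cells$age)]
  }
  tru <- Tm[cbind(as.character(cells$class_number), cells$age)]
  err <- est - tru
  summary <- data.frame(cells, truth = tru,
                        mean = rowMeans(est),
                        bias = rowMeans(err),
                        rmse = sqrt(rowMeans(err^2)),
                        coverage = rowMeans(abs(err) <= band + 1e-12))
  list(estimates = est, summary = summary, seeds = seeds, band = band,
       method = method)
}
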