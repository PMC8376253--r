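#' Observed-minus-expected deltas
#'
#' @param observed named numeric vector of observed counts per class.
#' @param expected named numeric vector of expected counts over the same
#'   class set.
#' @return Named vector `observed - expected`.
#' @export
deltas <- function(observed, expected) {
  if (!setequal(names(observed), names(expected)))
    sv_stop("observed and expected cover different class sets")
  observed - expected[names(observed)]
}

#' Relative standard deviation of deltas
#'
#' The model-fit criterion: the standard deviation of the per-class deltas
#' (observed minus expected counts) divided by the number of animals observed
#' at the evaluated scope. Dimensionless; 0 means the model allocates the
#' observed total across genotype classes exactly.
#'
#' @param d numeric vector of per-class deltas (>= 2 classes).
#' @param n_observed total genotyped animals at the scope (> 0).
#' @param type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return The relative SD (scalar).
#' @export
#' @examples
#' relative_sd(c(2, -2), 16)   # 0.1768
relative_sd <- function(d, n_observed, type = c("sample", "population")) {
  type <- match.arg(type)
  if (length(d) < 2L) sv_stop("need deltas for at least two classes")
  if (n_observed <= 0) sv_stop("n_observed must be > 0")
  s <- stats::sd(d)
  if (type == "population") s <- s * sqrt((length(d) - 1) / length(d))
  s / n_observed
}

# Precompute everything the objective needs: per-cross Mendelian fractions,
# pooled observed counts and per-(cross, age) genotyped totals.
fit_context <- function(obs, crosses) {
  if (inherits(crosses, "cross_spec")) crosses <- list(crosses)
  if (is.null(names(crosses)))
    names(crosses) <- vapply(crosses, `[[`, "", "cross_id")
  dists <- lapply(crosses, enumerate_offspring)
  cls <- dists[[1]]$class_number
  for (d in dists) if (!identical(d$class_number, cls))
    sv_stop("crosses do not share a class set")
  gobs <- obs[!is.na(obs$class_number), , drop = FALSE]
  unknown <- setdiff(unique(gobs$cross_id), names(crosses))
  if (length(unknown))
    sv_stop(paste("missing cross definition for:", paste(unknown, collapse = ", ")))
  if (length(setdiff(unique(gobs$class_number), cls)))
    sv_stop("observed counts contain class numbers outside the cross design")
  gt <- genotyped_totals(obs)
  ages <- age_stages()[age_stages() %in% gt$age[gt$n_genotyped > 0]]
  if (!length(ages)) sv_stop("no genotyped observations")
  K <- length(cls); A <- length(ages); C <- length(crosses)
  M <- vapply(dists, function(d) d$mendelian_fraction, numeric(K))
  M <- matrix(M, nrow = K, dimnames = list(as.character(cls), names(crosses)))
  n <- matrix(0, A, C, dimnames = list(ages, names(crosses)))
  i <- cbind(match(gt$age, ages), match(gt$cross_id, names(crosses)))
  ok <- !is.na(i[, 1]) & !is.na(i[, 2])
  n[i[ok, , drop = FALSE]] <- gt$n_genotyped[ok]
  obs_pooled <- matrix(0, K, A, dimnames = list(as.character(cls), ages))
  j <- cbind(match(gobs$class_number, cls), match(gobs$age, ages))
  ok <- !is.na(j[, 2])
  for (r in which(ok))
    obs_pooled[j[r, 1], j[r, 2]] <- obs_pooled[j[r, 1], j[r, 2]] + gobs$count[r]
  list(classes = cls, ages = ages, crosses = crosses, M = M, n = n,
       n_age = rowSums(n), obs_pooled = obs_pooled,
       wildtype = wildtype_classes(dists[[1]]), K = K, A = A, C = C)
}

# Pooled expected counts (classes x ages) for a schedule, using each cross's
# own Mendelian fractions weighted by its per-age genotyped totals.
expected_pooled <- function(ctx, S) {
  Sd <- unclass(S)[rownames(ctx$M), ctx$ages, drop = FALSE]
  E <- matrix(0, ctx$K, ctx$A, dimnames = dimnames(ctx$obs_pooled))
  for (c in seq_len(ctx$C)) {
    W <- ctx$M[, c] * Sd
    cs <- colSums(W)
    if (any(cs <= 0)) return(NULL)   # all-lethal at some age: invalid model
    E <- E + t(t(W) / cs * ctx$n[, c])
  }
  E
}

# Age-specific and cumulative relative SDs plus the scalar objective.
fit_metrics <- function(ctx, S, objective = "combined") {
  E <- expected_pooled(ctx, S)
  if (is.null(E)) return(NULL)
  D <- ctx$obs_pooled - E
  cm <- colMeans(D)
  sd_age <- sqrt(pmax(colSums(D * D) - ctx$K * cm * cm, 0) / (ctx$K - 1))
  rel_age <- sd_age / ctx$n_age
  Dcum <- apply(D, 1L, cumsum)
  if (ctx$A == 1L) Dcum <- matrix(Dcum, nrow = 1L)
  n_cum <- cumsum(ctx$n_age)
  rel_cum <- apply(Dcum, 1L, stats::sd) / n_cum
  overall <- switch(objective,
                    combined     = mean(c(rel_age, rel_cum[ctx$A])),
                    age_specific = mean(rel_age),
                    cumulative   = rel_cum[ctx$A],
                    sv_stop("unknown objective mode"))
  list(expected = E, deltas = D, rel_age = rel_age, rel_cum = rel_cum,
       cum_deltas = t(Dcum), n_cum = n_cum, overall = overall)
}

fit_objective <- function(ctx, S, objective) {
  m <- fit_metrics(ctx, S, objective)
  if (is.null(m)) Inf else m$overall
}

#' Score a survival model against observed counts
#'
#' Computes, at every age stage with data and for the cumulative tallies up
#' to each stage, the expected genotype counts under the model, the
#' observed-minus-expected deltas across all genotype classes, and the
#' relative SD fit criterion ([relative_sd()]). Expected counts pool crosses
#' using each cross's own Mendelian fractions weighted by its per-age
#' genotyped totals. Deterministic: identical inputs give identical reports.
#'
#' @param model a [survival_schedule()], or a preset id (`"A"` ... `"D4"`).
#' @param obs an [observed_counts()] table.
#' @param crosses a [cross_spec()] or (named) list of them, covering every
#'   `cross_id` in `obs`.
#' @param objective how the overall metric combines scopes: `"combined"`
#'   (unweighted mean of the per-age age-specific relative SDs and the final
#'   cumulative relative SD), `"age_specific"`, or `"cumulative"`.
#' @param model_id label stored in the report.
#' @return A `fit_report`: list with the per-scope count table (`table`),
#'   relative SDs (`rel_sd`), the scalar `overall` objective and metadata.
#' @export
evaluate_model <- function(model, obs, crosses, objective = "combined",
                           model_id = NULL) {
  if (is.character(model) && length(model) == 1L) {
    if (is.null(model_id)) model_id <- model
    model <- model_preset(model)
  }
  ctx <- fit_context(obs, crosses)
  validate_schedule(unclass(model), wildtype_classes = ctx$wildtype)
  m <- fit_metrics(ctx, model, objective)
  if (is.null(m)) sv_stop("no surviving genotypes at some age under this model")
  long <- function(mat, obs_mat, scope) {
    data.frame(age = rep(ctx$ages, each = ctx$K), scope = scope,
               class_number = rep(ctx$classes, ctx$A),
               observed = as.vector(obs_mat), expected = as.vector(mat),
               delta = as.vector(obs_mat - mat), stringsAsFactors = FALSE)
  }
  obs_cum <- t(apply(ctx$obs_pooled, 1L, cumsum))
  if (ctx$K == 1L) obs_cum <- matrix(obs_cum, nrow = 1L)
  exp_cum <- t(apply(m$expected, 1L, cumsum))
  tab <- rbind(long(m$expected, ctx$obs_pooled, "age_specific"),
               long(exp_cum, obs_cum, "cumulative"))
  rel <- data.frame(age = rep(ctx$ages, 2L),
                    scope = rep(c("age_specific", "cumulative"), each = ctx$A),
                    relative_sd = c(m$rel_age, m$rel_cum),
                    n_observed = c(ctx$n_age, m$n_cum),
                    stringsAsFactors = FALSE)
  structure(list(model_id = if (is.null(model_id)) "custom" else model_id,
                 schedule = model, table = tab, rel_sd = rel,
                 overall = m$overall, objective = objective,
                 ages = ctx$ages, n_total = sum(ctx$n_age)),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> model %s | %d genotyped | objective (%s) = %.5g\n",
              x$model_id, x$n_total, x$objective, x$overall))
  print(x$rel_sd, row.names = FALSE)
  invisible(x)
}

#' Fit a constrained survival schedule by staged grid search
#'
#' Coordinate-wise search over the survival grid \{0, step, 2 step, ..., 1\}
#' for every (free class, age stage) cell, minimizing the overall relative-SD
#' objective while enforcing the schedule rules (values in \[0, 1\],
#' non-increasing with age, wildtype fixed at 1). Classes are processed in
#' the order given in `free_classes`; within a class, stages are visited from
#' the latest to the earliest so that a cell can fall below the all-survival
#' starting point without violating the monotone bound against not-yet-fitted
#' later stages. Ties are broken toward the higher survival value (lethality
#' is only assumed when the data demand it). Sweeps repeat until no cell
#' changes; the objective never increases, so termination is guaranteed on
#' the finite grid.
#'
#' Never-observed rule: a free class with zero genotyped observations at
#' every age is assigned survival 0 at all ages and excluded from the grid
#' search. This mirrors the study's inference for the double-mutant male
#' (absent from all obtained genotypes, hence 0% survival at all ages) and
#' avoids the one pathology of the SD-of-deltas criterion, which can buy a
#' small negative delta in a never-observed class to recenter sampling noise
#' in the others.
#'
#' @inheritParams evaluate_model
#' @param free_classes integer class numbers whose survival is fitted; must
#'   exclude wildtype classes. Order = processing order.
#' @param grid_step grid resolution in (0, 0.5]; default 0.01.
#' @param base starting [survival_schedule()] (default: all 1); non-free
#'   classes keep their base values.
#' @param max_sweeps safety cap on full sweeps.
#' @return List with the fitted `schedule` and its `report`
#'   (see [evaluate_model()]).
#' @export
fit_schedule <- function(obs, crosses, free_classes, grid_step = 0.01,
                         base = NULL, objective = "combined",
                         max_sweeps = 100L) {
  if (grid_step <= 0 || grid_step > 0.5)
    sv_stop("grid_step must lie in (0, 0.5]")
  ctx <- fit_context(obs, crosses)
  if (any(free_classes %in% ctx$wildtype))
    sv_stop("free_classes must exclude wildtype classes")
  if (length(setdiff(free_classes, ctx$classes)))
    sv_stop("free_classes outside the cross design")
  if (is.null(base)) {
    base <- matrix(1, ctx$K, length(age_stages()),
                   dimnames = list(as.character(ctx$classes), age_stages()))
  }
  S <- unclass(base)[as.character(ctx$classes), age_stages(), drop = FALSE]
  validate_schedule(S, ctx$wildtype)
  never_seen <- rownames(ctx$obs_pooled)[rowSums(ctx$obs_pooled) == 0]
  pinned <- intersect(as.character(free_classes), never_seen)
  if (length(pinned)) {
    S[pinned, ] <- 0
    free_classes <- setdiff(as.character(free_classes), pinned)
  }
  grid <- sort(unique(c(seq(0, 1, by = grid_step), 1)))
  all_ages <- age_stages()
  fit_cols <- match(ctx$ages, all_ages)
  best <- fit_objective(ctx, S, objective)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (cl in as.character(free_classes)) {
      for (a in rev(fit_cols)) {
        hi <- if (a > 1L) min(S[cl, seq_len(a - 1L)]) else 1
        lo <- if (a < ncol(S)) max(S[cl, seq(a + 1L, ncol(S))]) else 0
        cand <- unique(c(grid[grid >= lo - 1e-12 & grid <= hi + 1e-12], S[cl, a]))
        cur <- S[cl, a]
        obj <- vapply(cand, function(v) {
          S[cl, a] <<- v
          fit_objective(ctx, S, objective)
        }, 0)
        S[cl, a] <- cur
        keep <- obj <= min(obj) * (1 + 1e-12) + 1e-15
        v_best <- max(cand[keep])
        if (v_best != cur && min(obj) <= best + 1e-15) {
          S[cl, a] <- v_best
          best <- fit_objective(ctx, S, objective)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  validate_schedule(S, ctx$wildtype)
  sched <- structure(S, class = c("survival_schedule", class(matrix())))
  list(schedule = sched,
       report = evaluate_model(sched, obs, crosses, objective = objective,
                               model_id = "fitted"))
}

#' Run the staged model sequence A through D4
#'
#' Reproduces the staged model-building procedure on a counts table:
#' \enumerate{
#'   \item Model A: full Mendelian survival (null model).
#'   \item Model B: the double-mutant male class (default 12) set fully
#'     lethal at every age.
#'   \item Model C: B plus fitted survival schedules for the mid/late
#'     gestation lethal classes (default 11 then 6).
#'   \item Model D3: C plus a fitted schedule for the compound-het female
#'     class (default 5).
#'   \item Model D4: D3 plus a fitted schedule for the late-lethal male
#'     class (default 10), then one global refinement sweep over all
#'     adjusted classes in the order 12, 11, 6, 10, 5.
#' }
#'
#' @inheritParams fit_schedule
#' @param lethal_class class set to 0 survival at stage B.
#' @param stage_c_classes,stage_d3_class,stage_d4_class classes fitted at the
#'   later stages, in processing order.
#' @return Named list (`A`, `B`, `C`, `D3`, `D4`) of lists with `model_id`,
#'   `schedule` and `report`.
#' @export
staged_models <- function(obs, crosses, grid_step = 0.01,
                          objective = "combined", lethal_class = 12L,
                          stage_c_classes = c(11L, 6L),
                          stage_d3_class = 5L, stage_d4_class = 10L) {
  ctx <- fit_context(obs, crosses)
  cls <- as.character(ctx$classes)
  ages <- age_stages()
  ones <- matrix(1, ctx$K, length(ages), dimnames = list(cls, ages))
  stage <- function(id, S)
    list(model_id = id,
         schedule = structure(S, class = c("survival_schedule", class(matrix()))),
         report = evaluate_model(
           structure(S, class = c("survival_schedule", class(matrix()))),
           obs, crosses, objective = objective, model_id = id))
  out <- list()
  out$A <- stage("A", ones)
  SB <- ones; SB[as.character(lethal_class), ] <- 0
  out$B <- stage("B", SB)
  fitC <- fit_schedule(obs, crosses, free_classes = stage_c_classes,
                       grid_step = grid_step, base = SB, objective = objective)
  out$C <- stage("C", unclass(fitC$schedule))
  fitD3 <- fit_schedule(obs, crosses, free_classes = stage_d3_class,
                        grid_step = grid_step, base = fitC$schedule,
                        objective = objective)
  out$D3 <- stage("D3", unclass(fitD3$schedule))
  fitD4 <- fit_schedule(obs, crosses, free_classes = stage_d4_class,
                        grid_step = grid_step, base = fitD3$schedule,
                        objective = objective)
  refine <- fit_schedule(obs, crosses,
                         free_classes = c(lethal_class, stage_c_classes,
                                          stage_d4_class, stage_d3_class),
                         grid_step = grid_step, base = fitD4$schedule,
                         objective = objective, max_sweeps = 1L)
  out$D4 <- stage("D4", unclass(refine$schedule))
  out
}
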