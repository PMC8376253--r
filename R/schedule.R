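#' Genotype-by-age survival schedule
#'
#' A survival schedule gives, for each genotype class, the cumulative
#' fraction Sx of the Mendelian expectation still present (live, or at least
#' intact) at each age stage, relative to wildtype survival. Rules enforced:
#' every Sx lies in \[0, 1\]; Sx cannot increase with age; wildtype classes
#' (all-wildtype genotypes) have Sx = 1 at every age, because the model
#' predicts offspring numbers relative to wildtype.
#'
#' @param x numeric matrix of survival fractions with one row per genotype
#'   class (rownames = class numbers) and one column per age stage (colnames
#'   from [age_stages()]), or a data.frame with a `class_number` column plus
#'   one column per stage. Values may be fractions (0-1) or percentages
#'   (0-100, auto-detected when any value exceeds 1).
#' @param classes full set of class numbers the schedule covers; classes
#'   absent from `x` get survival 1 at every age.
#' @param wildtype_classes class numbers that must have survival 1 (checked);
#'   `NULL` skips the check.
#' @param percent `"auto"`, `TRUE` or `FALSE`: whether `x` is in percent.
#' @return Numeric matrix of class `"survival_schedule"` (classes x stages,
#'   fractional).
#' @export
#' @examples
#' d4 <- model_preset("D4")
#' d4["11", ]   # 0.40 0.35 0.10 0.10 0.00
survival_schedule <- function(x, classes = NULL, wildtype_classes = NULL,
                              percent = "auto") {
  if (is.data.frame(x)) {
    if (!"class_number" %in% names(x))
      sv_stop("schedule data.frame needs a class_number column")
    stage_cols <- intersect(c(age_stages(), "Postnatal", "postnatal"), names(x))
    m <- as.matrix(x[, stage_cols, drop = FALSE])
    colnames(m) <- normalize_age(stage_cols)
    rownames(m) <- as.character(x$class_number)
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) sv_stop("schedule must be a numeric matrix")
  colnames(x) <- normalize_age(colnames(x))
  miss <- setdiff(age_stages(), colnames(x))
  if (length(miss))
    sv_stop(paste("schedule is missing age stage(s):", paste(miss, collapse = ", ")))
  x <- x[, age_stages(), drop = FALSE]
  if (identical(percent, "auto")) percent <- any(x > 1)
  if (isTRUE(percent)) x <- x / 100
  if (!is.null(classes)) {
    classes <- as.character(sort(as.integer(classes)))
    full <- matrix(1, nrow = length(classes), ncol = length(age_stages()),
                   dimnames = list(classes, age_stages()))
    known <- intersect(rownames(x), classes)
    if (length(setdiff(rownames(x), classes)))
      sv_stop("schedule lists class numbers outside `classes`")
    full[known, ] <- x[known, ]
    x <- full
  }
  validate_schedule(x, wildtype_classes)
  structure(x, class = c("survival_schedule", class(matrix())))
}

#' @rdname survival_schedule
#' @param s schedule matrix to validate.
#' @export
validate_schedule <- function(s, wildtype_classes = NULL) {
  if (any(s < 0 | s > 1))
    sv_stop("survival rates must lie in [0, 1]")
  inc <- t(apply(s, 1L, diff)) > 1e-12
  if (any(inc)) {
    bad <- rownames(s)[apply(inc, 1L, any)]
    sv_stop(paste("survival cannot increase with age (class",
                  paste(bad, collapse = ", "), ")"))
  }
  if (!is.null(wildtype_classes)) {
    wt <- intersect(as.character(wildtype_classes), rownames(s))
    if (length(wt) && any(s[wt, , drop = FALSE] != 1))
      sv_stop("wildtype classes must have survival 1 at all ages")
  }
  invisible(s)
}

#' Class numbers of fully wildtype genotypes
#'
#' @param dist a `mendelian_distribution`.
#' @return Integer class numbers whose genotype carries no null allele
#'   (e.g. female +/+ ; +/+ and male +/Y ; +/+).
#' @export
wildtype_classes <- function(dist) {
  cols <- setdiff(names(dist), c("class_number", "sex", "num", "den",
                                 "mendelian_fraction"))
  n_null <- rowSums(sapply(dist[cols], function(s)
    vapply(strsplit(s, "/", fixed = TRUE), function(p) sum(p == "-"), 0L)))
  dist$class_number[n_null == 0L]
}

#' Packaged survival-schedule presets
#'
#' Five staged model presets over the 12 classes of the two-locus design:
#' \describe{
#'   \item{A}{full Mendelian survival (all 1) -- the null model.}
#'   \item{B}{double-mutant male (class 12) fully lethal at every age.}
#'   \item{C}{B plus mid/late-gestation lethality of the -/Y ; +/- male
#'     (class 11) and the +/- ; -/- female (class 6).}
#'   \item{D3}{C plus reduced postnatal survival of the compound-het female
#'     (class 5).}
#'   \item{D4}{D3 plus reduced late survival of the -/Y ; +/+ male
#'     (class 10); the study's final fitted schedule.}
#' }
#' Presets are shipped as tab-separated percent tables under
#' `inst/extdata/models/` and converted to fractions on load.
#'
#' @param model_id one of `"A"`, `"B"`, `"C"`, `"D3"`, `"D4"`.
#' @param classes class-number set of the schedule (default 1-12).
#' @return A [survival_schedule()].
#' @export
model_preset <- function(model_id = c("A", "B", "C", "D3", "D4"),
                         classes = 1:12) {
  model_id <- match.arg(model_id)
  path <- system.file("extdata", "models",
                      paste0("model_", model_id, ".tsv"),
                      package = "segviab", mustWork = TRUE)
  read_schedule(path, classes = classes)
}

#' Read / write survival schedules as tab-separated text
#'
#' The file layout mirrors the study's survival table: columns
#' `class_number`, `genotype_label`, then one column per age stage
#' (`E8.5` ... `E18.5`, `Postnatal`), values in percent (0-100) or fractions
#' (auto-detected; any value > 1 implies percent). Classes not listed get
#' survival 1.
#'
#' @param path file path.
#' @param classes full class-number set (see [survival_schedule()]).
#' @param percent `"auto"`, `TRUE` or `FALSE`.
#' @return [read_schedule()] returns a `survival_schedule`.
#' @export
read_schedule <- function(path, classes = 1:12, percent = "auto") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  df$genotype_label <- NULL
  survival_schedule(df, classes = classes, percent = percent)
}

#' @rdname read_schedule
#' @param s a `survival_schedule`.
#' @param labels optional character vector of genotype labels per row.
#' @export
write_schedule <- function(s, path, labels = NULL) {
  df <- data.frame(class_number = rownames(s),
                   genotype_label = if (is.null(labels)) "" else labels,
                   round(unclass(s) * 100, 6), check.names = FALSE)
  names(df)[-(1:2)] <- sub("^P3$", "Postnatal", colnames(s))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-stage conditional survival implied by a cumulative schedule
#'
#' The schedule stores cumulative survival S(age) relative to the Mendelian
#' expectation. The conditional survival across stage k is
#' p_k = S(age_k) / S(age_(k-1)), with S = 1 before the first stage and
#' p_k defined as 0 whenever both terms are 0 (a class already extinct stays
#' extinct). Under the monotonicity rule every p_k lies in \[0, 1\] and their
#' running product reconstructs the cumulative schedule.
#'
#' @param s a `survival_schedule`.
#' @return Matrix of the same shape with per-stage conditional survival.
#' @export
#' @examples
#' conditional_survival(model_preset("D4"))["11", ]
conditional_survival <- function(s) {
  validate_schedule(s)
  prev <- cbind(1, unclass(s)[, -ncol(s), drop = FALSE])
  p <- ifelse(prev == 0, 0, unclass(s) / prev)
  dimnames(p) <- dimnames(s)
  p
}
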