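#' Ordered developmental age stages
#'
#' The study design harvests litters cross-sectionally at four embryonic days
#' and performs one postnatal census at P3. Every survival schedule, count
#' table and model in the package is indexed by these five ordered stages.
#'
#' @return Character vector of canonical stage labels, in developmental order:
#'   `"E8.5" < "E10.5" < "E12.5" < "E18.5" < "P3"`.
#' @export
#' @examples
#' age_stages()
age_stages <- function() {
  c("E8.5", "E10.5", "E12.5", "E18.5", "P3")
}

#' Normalize age-stage labels
#'
#' Accepts common spellings ("P3", "postnatal", "Postnatal (%)", "e10.5") and
#' returns the canonical labels used throughout the package.
#'
#' @param x character vector of stage labels.
#' @return Character vector of canonical labels.
#' @export
normalize_age <- function(x) {
  x0 <- trimws(sub("\\s*\\(%\\)\\s*$", "", as.character(x)))
  lab <- toupper(x0)
  lab[grepl("^POSTNATAL$|^P3$|^P 3$", lab)] <- "P3"
  ok <- lab %in% toupper(age_stages())
  if (any(!ok)) {
    stop("unknown age label(s): ", paste(unique(x0[!ok]), collapse = ", "),
         " (expected one of ", paste(age_stages(), collapse = ", "),
         " or 'postnatal')", call. = FALSE)
  }
  age_stages()[match(lab, toupper(age_stages()))]
}

#' @rdname normalize_age
#' @return `age_rank()` returns the integer position of each stage in the
#'   developmental order.
#' @export
age_rank <- function(x) {
  match(normalize_age(x), age_stages())
}

#' @rdname normalize_age
#' @return `age_kind()` returns `"embryonic_cross_sectional"` or
#'   `"postnatal"` for each stage.
#' @export
age_kind <- function(x) {
  ifelse(normalize_age(x) == "P3", "postnatal", "embryonic_cross_sectional")
}
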