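#' Read observed genotype counts
#'
#' Counts tables are plain tab-separated UTF-8 text with a single header line
#' and columns `cross_id`, `age`, `class_number`, `count`. Rows with
#' `class_number` `NA` (or empty) carry the un-genotyped tally for that
#' (cross, age): embryos already in resorption or degraded/cannibalized pups
#' that could not be genotyped. Malformed rows are reported with their line
#' number.
#'
#' @param path tab-separated counts file.
#' @return A `data.frame` of class `"observed_counts"` with integer counts;
#'   un-genotyped rows keep `class_number = NA`.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("cross_id", "age", "class_number", "count")
  if (!all(need %in% names(df)))
    sv_stop(paste("counts file must have columns:", paste(need, collapse = ", ")))
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_age <- tryCatch({ normalize_age(df$age); integer(0) },
                      error = function(e) which(!toupper(trimws(sub("\\s*\\(%\\)\\s*$", "", df$age))) %in%
                                                  c(toupper(age_stages()), "POSTNATAL")))
  if (length(bad_age))
    sv_stop(paste0("unknown age label at line(s) ", paste(line[bad_age], collapse = ", ")))
  df$age <- normalize_age(df$age)
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad))
    sv_stop(paste0("count must be a nonnegative integer: line(s) ",
                   paste(line[bad], collapse = ", ")))
  df$count <- as.integer(cnt)
  df$class_number <- suppressWarnings(as.integer(df$class_number))
  key <- paste(df$cross_id, df$age, df$class_number)
  if (anyDuplicated(key))
    sv_stop(paste0("duplicate (cross, age, class) key at line(s) ",
                   paste(line[duplicated(key)], collapse = ", ")))
  observed_counts(df)
}

#' Construct an observed-counts table
#'
#' @param df data.frame with columns `cross_id`, `age`, `class_number`
#'   (`NA` for un-genotyped tallies) and `count`.
#' @return The validated `observed_counts` object.
#' @export
observed_counts <- function(df) {
  df <- as.data.frame(df)[, c("cross_id", "age", "class_number", "count")]
  df$age <- normalize_age(df$age)
  if (any(df$count < 0 | df$count != floor(df$count)))
    sv_stop("counts must be nonnegative integers")
  df$count <- as.integer(df$count)
  df <- df[order(df$cross_id, age_rank(df$age), df$class_number), ]
  rownames(df) <- NULL
  structure(df, class = c("observed_counts", "data.frame"))
}

#' @rdname read_counts
#' @param obs an `observed_counts` table.
#' @export
write_counts <- function(obs, path) {
  utils::write.table(as.data.frame(obs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-(cross, age) genotyped totals
#'
#' @param obs an `observed_counts` table.
#' @return data.frame with `cross_id`, `age`, `n_genotyped` and
#'   `n_ungenotyped` (the `NA`-class tallies).
#' @export
genotyped_totals <- function(obs) {
  g <- stats::aggregate(count ~ cross_id + age, data = obs[!is.na(obs$class_number), ],
                        FUN = sum)
  names(g)[3] <- "n_genotyped"
  u <- obs[is.na(obs$class_number), c("cross_id", "age", "count")]
  g$n_ungenotyped <- 0L
  if (nrow(u)) {
    i <- match(paste(u$cross_id, u$age), paste(g$cross_id, g$age))
    miss <- is.na(i)
    g$n_ungenotyped[i[!miss]] <- u$count[!miss]
    if (any(miss)) {
      extra <- u[miss, ]
      extra <- data.frame(cross_id = extra$cross_id, age = extra$age,
                          n_genotyped = 0L, n_ungenotyped = extra$count)
      g <- rbind(g, extra)
    }
  }
  g[order(g$cross_id, age_rank(g$age)), ]
}

#' Read cross definitions from a YAML/JSON config
#'
#' The config lists the loci (`name`, `linkage`) and one or more crosses with
#' `cross_id`, `dam` and `sire` per-locus allele states (`"+/-"`, `"+/Y"`,
#' ...). JSON is accepted as well (YAML is a superset).
#'
#' @param path config file; the packaged default describes the two modeled
#'   matings (`system.file("extdata/crosses/modeled_crosses.yaml",
#'   package = "segviab")`).
#' @return Named list of [cross_spec()] objects.
#' @export
read_cross_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$loci) || is.null(cfg$crosses))
    sv_stop("cross config needs `loci:` and `crosses:` entries")
  loci <- lapply(cfg$loci, function(l) locus(l$name, l$linkage))
  crosses <- lapply(cfg$crosses, function(cr) {
    cross_spec(cr$cross_id, dam = unlist(cr$dam), sire = unlist(cr$sire),
               loci = loci)
  })
  names(crosses) <- vapply(crosses, `[[`, "", "cross_id")
  crosses
}

#' The two modeled matings
#'
#' Convenience accessor for the packaged cross config: compound-heterozygous
#' (*Naa10* +/- ; *Naa12* +/-) dams crossed to *Naa10* +/Y sires that are
#' either *Naa12* +/- or *Naa12* -/-.
#'
#' @return Named list of two [cross_spec()] objects.
#' @export
modeled_crosses <- function() {
  read_cross_config(system.file("extdata", "crosses", "modeled_crosses.yaml",
                                package = "segviab", mustWork = TRUE))
}

#' Postnatal mortality fractions from breeding-record tallies
#'
#' Recomputes descriptive death rates (percent) from dead/total tallies. The
#' packaged table carries the study's headline postnatal tallies: 29/38
#' *Naa10*-null males dead before P3, and the maternal-effect mating's 37/127
#' (first day) and 46/127 (first three days) death counts.
#'
#' @param path tab-separated file with columns `label`, `dead`, `total`;
#'   default is the packaged table.
#' @return data.frame with `label`, `dead`, `total` and `percent_dead`.
#' @export
#' @examples
#' mortality_fractions()
mortality_fractions <- function(path = system.file("extdata", "observed",
                                                   "mortality_tallies.tsv",
                                                   package = "segviab")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (any(df$dead > df$total) || any(df$dead < 0))
    sv_stop("dead tallies must lie in [0, total]")
  df$percent_dead <- 100 * df$dead / df$total
  df
}
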