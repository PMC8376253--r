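#' @keywords internal
sv_stop <- function(msg, class = "segviab_error", ...) {
  stop(errorCondition(msg, ..., class = c(class, "segviab_error", "error", "condition")))
}

#' Define a locus
#'
#' A bi-allelic locus with a wildtype ("+") and a null ("-") allele, either
#' autosomal or X-linked. The study design carries one X-linked locus
#' (*Naa10*) and optionally one autosomal locus (*Naa12*).
#'
#' @param name locus identifier (e.g. `"Naa10"`).
#' @param linkage `"autosomal"` or `"x_linked"`.
#' @param alleles ordered pair of allele labels; first is wildtype.
#' @return An object of class `"locus"`.
#' @export
#' @examples
#' locus("Naa10", "x_linked")
locus <- function(name, linkage = c("autosomal", "x_linked"),
                  alleles = c("+", "-")) {
  linkage <- match.arg(linkage)
  if (length(alleles) != 2L || anyDuplicated(alleles))
    sv_stop("a locus needs two distinct allele labels")
  structure(list(name = as.character(name), linkage = linkage,
                 alleles = as.character(alleles)),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("<locus> %s (%s), alleles %s/%s\n",
              x$name, x$linkage, x$alleles[1], x$alleles[2]))
  invisible(x)
}

#' The Naa10/Naa12 locus pair
#'
#' @return List of the X-linked *Naa10* locus and the autosomal *Naa12* locus.
#' @export
naa_loci <- function() {
  list(locus("Naa10", "x_linked"), locus("Naa12", "autosomal"))
}

# Normalize a diploid state string to canonical order: "+" alleles first.
# Returns e.g. "+/-" for input "-/+".
normalize_diploid <- function(a, b, alleles) {
  pair <- c(a, b)[order(match(c(a, b), alleles))]
  paste(pair, collapse = "/")
}

# Parse a per-locus parental state string, validating against linkage and sex.
# Returns list(alleles = character vector of transmissible gamete alleles for
# the relevant chromosome, state = canonical state string).
parse_parent_state <- function(state, loc, parent = c("dam", "sire")) {
  parent <- match.arg(parent)
  parts <- strsplit(trimws(state), "/", fixed = TRUE)[[1]]
  bad <- function(why) {
    sv_stop(sprintf("invalid %s state '%s' at locus %s: %s",
                    parent, state, loc$name, why),
            class = "segviab_parent_error")
  }
  if (length(parts) != 2L) bad("expected two '/'-separated entries")
  if (loc$linkage == "x_linked" && parent == "sire") {
    if (parts[2] != "Y") bad("a sire is hemizygous: expected '<allele>/Y'")
    if (!parts[1] %in% loc$alleles) bad("unknown X allele")
    list(alleles = parts[1], state = paste0(parts[1], "/Y"))
  } else {
    if (any(parts == "Y")) bad("'Y' is only valid for a sire at an X-linked locus")
    if (!all(parts %in% loc$alleles)) bad("unknown allele")
    list(alleles = parts,
         state = normalize_diploid(parts[1], parts[2], loc$alleles))
  }
}

#' Specify a mating
#'
#' A cross between one dam and one sire over the loci in `loci` (default: the
#' X-linked *Naa10* locus plus the autosomal *Naa12* locus). Parental states
#' are written as in breeding records: `"+/-"` for a heterozygous dam,
#' `"+/Y"` for a hemizygous wildtype sire, etc. A single-locus cross (e.g.
#' *Naa10* only) is specified by passing only that locus.
#'
#' @param cross_id identifier for the mating.
#' @param dam,sire named character vectors of per-locus states; names must
#'   match the locus names.
#' @param loci list of [locus()] objects: exactly one X-linked locus and at
#'   most one autosomal locus.
#' @return An object of class `"cross_spec"`.
#' @export
#' @examples
#' # compound-het dam x Naa12-het sire, the primary modeled mating
#' cross_spec("cross1", dam = c(Naa10 = "+/-", Naa12 = "+/-"),
#'            sire = c(Naa10 = "+/Y", Naa12 = "+/-"))
cross_spec <- function(cross_id, dam, sire, loci = naa_loci()) {
  linkages <- vapply(loci, `[[`, "", "linkage")
  if (sum(linkages == "x_linked") != 1L || sum(linkages == "autosomal") > 1L)
    sv_stop("a cross needs exactly one X-linked locus and at most one autosomal locus")
  names(loci) <- vapply(loci, `[[`, "", "name")
  for (p in c("dam", "sire")) {
    states <- if (p == "dam") dam else sire
    if (!setequal(names(states), names(loci)))
      sv_stop(sprintf("%s of cross '%s' must give one state per locus (%s)",
                      p, cross_id, paste(names(loci), collapse = ", ")))
  }
  parsed <- list(
    dam  = lapply(names(loci), function(nm)
      parse_parent_state(dam[[nm]],  loci[[nm]], "dam")),
    sire = lapply(names(loci), function(nm)
      parse_parent_state(sire[[nm]], loci[[nm]], "sire"))
  )
  names(parsed$dam) <- names(parsed$sire) <- names(loci)
  structure(list(cross_id = as.character(cross_id), loci = loci,
                 dam = parsed$dam, sire = parsed$sire),
            class = "cross_spec")
}

#' @export
print.cross_spec <- function(x, ...) {
  fmt <- function(p) paste(vapply(x[[p]], `[[`, "", "state"), collapse = "; ")
  cat(sprintf("<cross_spec> %s: dam (%s) x sire (%s)\n",
              x$cross_id, fmt("dam"), fmt("sire")))
  invisible(x)
}

# Ranking of genotype states: fewer null alleles first.
state_rank <- function(states) {
  vapply(strsplit(states, "/", fixed = TRUE),
         function(p) sum(p == "-"), 0L) + ifelse(grepl("Y", states), 0, 0)
}

# Producible offspring states at one locus, by sex, with exact transmission
# probabilities as integer numerators over a common denominator.
offspring_states <- function(cross, loc_name, sex) {
  loc <- cross$loci[[loc_name]]
  dam_al <- cross$dam[[loc_name]]$alleles
  sire_al <- cross$sire[[loc_name]]$alleles
  if (loc$linkage == "x_linked") {
    if (sex == "female") {
      states <- vapply(dam_al, function(a)
        normalize_diploid(a, sire_al[1], loc$alleles), "")
      den <- 2L
    } else {
      states <- paste0(dam_al, "/Y")
      den <- 2L
    }
    num <- as.integer(table(factor(states, levels = unique(states))))
    states <- unique(states)
  } else {
    grid <- expand.grid(d = dam_al, s = sire_al, stringsAsFactors = FALSE)
    states0 <- mapply(normalize_diploid, grid$d, grid$s,
                      MoreArgs = list(alleles = loc$alleles))
    den <- 4L
    num <- as.integer(table(factor(states0, levels = unique(states0))))
    states <- unique(states0)
  }
  ord <- order(state_rank(states))
  data.frame(state = states[ord], num = num[ord], den = den,
             stringsAsFactors = FALSE)
}

# Full ordered class grid for the cross under the default ("supp1")
# numbering: females first then males, within sex ordered by X-locus state
# (fewest nulls first) then autosomal state (+/+, +/-, -/-). The autosomal
# dimension always spans all three states so class numbers stay stable
# across crosses that differ only in the sire's autosomal genotype;
# unproducible cells are carried with probability zero.
class_grid <- function(cross) {
  x_name <- names(cross$loci)[vapply(cross$loci, `[[`, "", "linkage") == "x_linked"]
  a_name <- setdiff(names(cross$loci), x_name)
  rows <- list()
  for (sex in c("female", "male")) {
    xs <- offspring_states(cross, x_name, sex)
    if (length(a_name)) {
      loc_a <- cross$loci[[a_name]]
      a_states <- c(paste0(loc_a$alleles[1], "/", loc_a$alleles[1]),
                    paste0(loc_a$alleles[1], "/", loc_a$alleles[2]),
                    paste0(loc_a$alleles[2], "/", loc_a$alleles[2]))
      as_prod <- offspring_states(cross, a_name, sex)
      num_a <- as_prod$num[match(a_states, as_prod$state)]
      num_a[is.na(num_a)] <- 0L
      g <- expand.grid(a_state = a_states, x_state = xs$state,
                       stringsAsFactors = FALSE)
      rows[[sex]] <- data.frame(
        sex = sex, x_state = g$x_state, a_state = g$a_state,
        num = xs$num[match(g$x_state, xs$state)] * num_a[match(g$a_state, a_states)],
        den = xs$den[1] * as_prod$den[1] * 2L,  # x 2 for the 1:1 sex ratio
        stringsAsFactors = FALSE)
    } else {
      rows[[sex]] <- data.frame(
        sex = sex, x_state = xs$state, a_state = NA_character_,
        num = xs$num, den = xs$den * 2L, stringsAsFactors = FALSE)
    }
  }
  out <- rbind(rows$female, rows$male)
  out$class_number <- seq_len(nrow(out))
  attr(out, "x_locus") <- x_name
  attr(out, "a_locus") <- if (length(a_name)) a_name else NA_character_
  out
}

#' Enumerate offspring genotype classes with exact Mendelian fractions
#'
#' Computes the Mendelian fraction Mx of every offspring genotype class of a
#' cross as the exact product of per-locus transmission probabilities and a
#' 1:1 sex ratio. Fractions are kept as integer ratios internally and exported
#' as floats, so they sum to 1 exactly. For the compound-het dam x *Naa12*-het
#' sire mating this yields the 12 classes of the study's numbering, with the
#' double-mutant male (class 12) at 1/16.
#'
#' @param cross a [cross_spec()].
#' @param drop_zero drop classes with Mendelian fraction 0 instead of carrying
#'   them (default keeps them, so class numbers are stable across crosses).
#' @param convention class-numbering convention; only `"supp1"` (females 1-6,
#'   males 7-12, X-locus-major ordering) is defined.
#' @return A `data.frame` of class `"mendelian_distribution"` with columns
#'   `class_number`, `sex`, one genotype column per locus (lower-case locus
#'   name), `num`, `den` (exact ratio) and `mendelian_fraction`.
#' @export
#' @examples
#' cr <- cross_spec("cross1", dam = c(Naa10 = "+/-", Naa12 = "+/-"),
#'                  sire = c(Naa10 = "+/Y", Naa12 = "+/-"))
#' enumerate_offspring(cr)
enumerate_offspring <- function(cross, drop_zero = FALSE, convention = "supp1") {
  if (!inherits(cross, "cross_spec")) sv_stop("`cross` must be a cross_spec")
  grid <- class_map(cross, convention)
  g <- gcd_vec(grid$num, grid$den)
  out <- data.frame(class_number = grid$class_number, sex = grid$sex,
                    stringsAsFactors = FALSE)
  out[[tolower(attr(grid, "x_locus"))]] <- grid$x_state
  if (!is.na(attr(grid, "a_locus")))
    out[[tolower(attr(grid, "a_locus"))]] <- grid$a_state
  out$num <- grid$num %/% g
  out$den <- grid$den %/% g
  out$mendelian_fraction <- grid$num / grid$den
  if (drop_zero) out <- out[out$num > 0L, , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(abs(sum(out$mendelian_fraction) - 1) < 1e-12)
  structure(out, class = c("mendelian_distribution", "data.frame"),
            cross_id = cross$cross_id)
}

gcd_vec <- function(a, b) {
  mapply(function(x, y) {
    if (x == 0L) return(y)
    while (y != 0L) { t <- x %% y; x <- y; y <- t }
    x
  }, as.integer(a), as.integer(b))
}

#' Class-numbering map for a cross
#'
#' Deterministic assignment of class numbers to offspring genotype classes.
#' The default `"supp1"` convention numbers females first (1-6 in the
#' two-locus design) then males (7-12), each sex block ordered by X-locus
#' state (wildtype allele first) and, within it, by autosomal state
#' (+/+, +/-, -/-). This reproduces the anchored identities of the study:
#' class 5 = female +/- ; +/-, class 6 = female +/- ; -/-,
#' classes 10-12 = -/Y males with +/+, +/-, -/- at the autosomal locus.
#'
#' @param cross a [cross_spec()].
#' @param convention numbering convention identifier.
#' @return `data.frame` mapping `class_number` to sex and per-locus states,
#'   with exact transmission numerators (internal columns `num`, `den`).
#' @export
class_map <- function(cross, convention = "supp1") {
  if (!identical(convention, "supp1"))
    sv_stop(sprintf("unknown numbering convention '%s'; available: supp1",
                    convention))
  class_grid(cross)
}

#' Look up the genotype label of a class number
#'
#' @param dist a `mendelian_distribution`.
#' @param classes integer class numbers (default all).
#' @return character labels like `"female Naa10 +/- ; Naa12 -/-"`.
#' @export
class_labels <- function(dist, classes = dist$class_number) {
  i <- match(classes, dist$class_number)
  cols <- setdiff(names(dist), c("class_number", "sex", "num", "den",
                                 "mendelian_fraction"))
  lab <- apply(dist[i, cols, drop = FALSE], 1L, function(r)
    paste(paste0(toupper(substring(cols, 1, 1)), substring(cols, 2), " ", r),
          collapse = " ; "))
  paste(dist$sex[i], lab)
}

#' @export
print.mendelian_distribution <- function(x, ...) {
  cat(sprintf("<mendelian_distribution> cross '%s', %d classes\n",
              attr(x, "cross_id"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write / read a Mendelian distribution as tab-separated text
#'
#' @param dist a `mendelian_distribution`.
#' @param path output file path.
#' @export
write_distribution <- function(dist, path) {
  out <- dist[, setdiff(names(dist), c("num", "den")), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
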