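# Elemental-formula arithmetic and monoisotopic masses.
#
# Atomic masses are pinned in source so that every theoretical m/z the package
# reports is reproducible independent of external mass tables. Cation masses
# are electron-corrected (proton = 1.00727645 Da), which is required to
# reproduce vendor-style "theoretical m/z" values at 3 decimals.

#' Pinned monoisotopic atomic masses (Da)
#'
#' The supported element set and the monoisotopic mass of each element's
#' principal isotope. All mass arithmetic in the package uses this table.
#'
#' @format Named numeric vector (element symbol -> Da).
#' @export
ATOMIC_MASSES <- c(
  C  = 12.000000000,
  H  = 1.00782503,
  N  = 14.00307401,
  O  = 15.99491462,
  Na = 22.98976928
)

#' Electron rest mass (Da)
#' @export
ELECTRON_MASS <- 0.00054858

# Hill-order element sequence for formatting: C, H, then alphabetical.
.hill_order <- c("C", "H", "N", "Na", "O")

#' Parse a Hill-notation elemental formula
#'
#' Parses strings such as `"C86H172O6"` into a named integer vector of element
#' counts. Counts default to 1 when omitted (`"H2O"` -> H 2, O 1). Only the
#' elements in [ATOMIC_MASSES] are accepted.
#'
#' @param text Single formula string in Hill notation.
#' @return Named integer vector of element counts (only elements present).
#' @examples
#' parse_formula("C86H172O6")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (text == "") {
    return(stats::setNames(integer(0), character(0)))
  }
  tokens <- stringr::str_match_all(text, "([A-Z][a-z]?)([0-9]*)")[[1]]
  tokens <- tokens[tokens[, 1] != "", , drop = FALSE]
  if (paste(tokens[, 1], collapse = "") != text) {
    stop("malformed formula string: ", text, call. = FALSE)
  }
  elems <- tokens[, 2]
  unknown <- setdiff(elems, names(ATOMIC_MASSES))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- ifelse(tokens[, 3] == "", 1L, as.integer(tokens[, 3]))
  # collapse repeated symbols ("CH3CH3" style input)
  out <- vapply(split(counts, elems), sum, integer(1))
  out[intersect(.hill_order, names(out))]
}

# Accept either a formula string or a named count vector; return counts.
.as_counts <- function(f) {
  if (is.character(f)) {
    return(parse_formula(f))
  }
  stopifnot(is.numeric(f))
  f <- f[f != 0]
  unknown <- setdiff(names(f), names(ATOMIC_MASSES))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(f < 0)) stop("negative element count", call. = FALSE)
  out <- as.integer(f)
  names(out) <- names(f)
  out[intersect(.hill_order, names(out))]
}

#' Format element counts as a Hill-notation string
#'
#' Inverse of [parse_formula()]: carbon first, hydrogen second, remaining
#' elements alphabetical; a count of 1 is omitted.
#'
#' @param counts Named integer vector of element counts (or a formula string,
#'   which is canonicalised).
#' @return Single Hill-notation string ("" for the empty formula).
#' @export
format_formula <- function(counts) {
  counts <- .as_counts(counts)
  counts <- counts[counts > 0]
  if (length(counts) == 0) return("")
  ord <- intersect(.hill_order, names(counts))
  paste0(ord, ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}

#' Add or subtract elemental formulas
#'
#' Element-wise formula arithmetic. Subtraction that would drive any element
#' count negative is an error (the requested fragment/loss is not a
#' sub-formula).
#'
#' @param a,b Formula strings or named count vectors.
#' @return Named integer count vector.
#' @export
formula_add <- function(a, b) {
  a <- .as_counts(a); b <- .as_counts(b)
  elems <- union(names(a), names(b))
  out <- stats::setNames(integer(length(elems)), elems)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  .as_counts(out)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  a <- .as_counts(a); b <- .as_counts(b)
  elems <- union(names(a), names(b))
  out <- stats::setNames(integer(length(elems)), elems)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0)) {
    stop("subtraction would produce a negative element count", call. = FALSE)
  }
  .as_counts(out)
}

#' Monoisotopic mass of a formula
#'
#' Sum of count x pinned atomic monoisotopic mass over all elements. Additive:
#' `monoisotopic_mass(formula_add(a, b)) == monoisotopic_mass(a) +
#' monoisotopic_mass(b)` to machine precision. Vectorised over a character
#' vector of formulas.
#'
#' @param f Formula string(s) or a named count vector.
#' @return Mass in Da (numeric, same length as `f` for character input).
#' @examples
#' monoisotopic_mass("C20H40")   # phytane neutral loss
#' monoisotopic_mass("C6H10O5")  # hexose head-group increment
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f) && length(f) > 1L) {
    return(vapply(f, monoisotopic_mass, numeric(1), USE.NAMES = FALSE))
  }
  counts <- .as_counts(f)
  if (length(counts) == 0) return(0)
  sum(counts * ATOMIC_MASSES[names(counts)])
}

#' Supported positive adducts
#'
#' The three singly charged adducts modelled ([M+H]+, [M+NH4]+, [M+Na]+), with
#' electron-corrected cation masses derived from the pinned atomic masses.
#'
#' @return Tibble with columns `adduct`, `cation_formula`, `cation_mass`,
#'   `charge`.
#' @export
adducts <- function() {
  tibble::tibble(
    adduct = c("+H", "+NH4", "+Na"),
    cation_formula = c("H", "NH4", "Na"),
    cation_mass = vapply(
      c("H", "NH4", "Na"),
      function(f) monoisotopic_mass(f) - ELECTRON_MASS,
      numeric(1), USE.NAMES = FALSE
    ),
    charge = 1L
  )
}

.cation_mass <- function(adduct) {
  tab <- adducts()
  i <- match(adduct, tab$adduct)
  if (anyNA(i)) {
    stop("unsupported adduct: ", paste(adduct[is.na(i)], collapse = ", "),
         "; supported: ", paste(tab$adduct, collapse = ", "), call. = FALSE)
  }
  tab$cation_mass[i]
}

#' Theoretical m/z of an adduct ion
#'
#' m/z of the singly charged `[M + X]+` ion: neutral monoisotopic mass plus
#' the electron-corrected cation mass. Computed at full double precision;
#' round with [round_mz()] for reporting.
#'
#' @param neutral Neutral formula (string or counts), or a precomputed neutral
#'   mass in Da.
#' @param adduct One of `"+H"`, `"+NH4"`, `"+Na"` (vectorised).
#' @return m/z (numeric).
#' @examples
#' round_mz(adduct_mz("C86H172O6", "+H"))    # 1302.323
#' round_mz(adduct_mz("C97H194O11", "+NH4")) # 1553.496
#' @export
adduct_mz <- function(neutral, adduct = "+H") {
  m <- if (is.numeric(neutral) && is.null(names(neutral))) {
    neutral
  } else {
    monoisotopic_mass(neutral)
  }
  m + .cation_mass(adduct)
}

#' Round an m/z for reporting
#'
#' Round-half-even to 3 decimals, the convention used for all reported
#' theoretical m/z values. (R's `round()` implements IEC 60559 half-even.)
#'
#' @param mz Numeric m/z value(s).
#' @param digits Decimals (default 3).
#' @export
round_mz <- function(mz, digits = 3) round(mz, digits)

#' Relative mass error in parts per million
#'
#' `1e6 * (observed - theoretical) / theoretical`.
#'
#' @param observed,theoretical m/z values; `theoretical` must be > 0.
#' @return Signed ppm error (vectorised).
#' @examples
#' ppm_error(1302.326, 1302.323) # ~ +2.3 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) {
    stop("theoretical mass must be positive", call. = FALSE)
  }
  1e6 * (observed - theoretical) / theoretical
}
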