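# Injection-standard semi-quantification with class-specific response
# factors. Amounts are computed relative to a co-injected standard (default
# 2 ng per injection) and corrected for ionisation-efficiency differences via
# response factors fitted from calibration curves of structurally similar
# standards. All outputs are semi-quantitative: per-species standards are not
# available, so a class standard stands in for each lipid class.

#' Default response-factor table
#'
#' One calibration standard per lipid class: diglycosidic archaeol for intact
#' glycosidic archaeols, archaeol for core archaeols, monoglycosidic iGDGT-0
#' for intact glycosidic tetraethers, and the GTGT-C46 injection standard for
#' core tetraethers. Response factors default to 1 (uncalibrated); fit real
#' values with [fit_response_factor()] from a user calibration file.
#'
#' @return Tibble with columns `class`, `standard`, `rf`.
#' @export
default_response_factors <- function() {
  tibble::tibble(
    class = c("glycosidic AR", "core AR",
              "glycosidic tetraether", "core tetraether"),
    standard = c("2G-AR", "AR", "1G-iGDGT-0", "GTGT-C46"),
    rf = 1
  )
}

#' Fit response factors from calibration curves
#'
#' Fits a through-origin least-squares line (area ~ 0 + amount) per standard
#' and normalises each slope by the injection standard's slope. Through-origin
#' is the appropriate model here: zero analyte must give zero area, and the
#' ratio-based semi-quantification presumes proportionality.
#'
#' @param calibration Tibble/data frame with columns `standard`, `amount_ng`,
#'   `area`; at least 2 points with distinct amounts per standard.
#' @param injection_standard Name of the standard whose slope defines rf = 1.
#' @return Object of class `rf_fit`: list with `rf` (tibble `standard`,
#'   `slope`, `rf`) and `fits` (named list of `lm` objects). Use
#'   [generics::tidy()] / [generics::glance()] for summaries.
#' @examples
#' cal <- tibble::tibble(
#'   standard = rep(c("GTGT-C46", "AR"), each = 3),
#'   amount_ng = rep(c(1, 2, 4), 2),
#'   area = c(100, 200, 400, 50, 100, 200)
#' )
#' fit_response_factor(cal, "GTGT-C46")
#' @export
fit_response_factor <- function(calibration, injection_standard = "GTGT-C46") {
  calibration <- tibble::as_tibble(calibration)
  stopifnot(all(c("standard", "amount_ng", "area") %in% names(calibration)))
  fits <- calibration |>
    dplyr::group_by(.data$standard) |>
    dplyr::group_map(function(df, key) {
      if (nrow(df) < 2 || dplyr::n_distinct(df$amount_ng) < 2) {
        stop("need >= 2 calibration points with distinct amounts for ",
             key$standard, call. = FALSE)
      }
      stats::lm(area ~ 0 + amount_ng, data = df)
    }, .keep = TRUE)
  names(fits) <- sort(unique(calibration$standard))
  slopes <- vapply(fits, function(m) unname(stats::coef(m)[1]), numeric(1))
  if (any(slopes <= 0)) {
    stop("non-positive calibration slope", call. = FALSE)
  }
  if (!injection_standard %in% names(slopes)) {
    stop("injection standard '", injection_standard,
         "' not present in calibration data", call. = FALSE)
  }
  structure(
    list(
      rf = tibble::tibble(
        standard = names(slopes),
        slope = unname(slopes),
        rf = unname(slopes) / slopes[[injection_standard]]
      ),
      fits = fits,
      injection_standard = injection_standard
    ),
    class = "rf_fit"
  )
}

#' @export
print.rf_fit <- function(x, ...) {
  cat("<rf_fit> response factors relative to", x$injection_standard, "\n")
  print(x$rf)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rf_fit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(m, std) {
    co <- summary(m)$coefficients
    tibble::tibble(
      standard = std,
      slope = co[1, 1],
      std.error = co[1, 2],
      rf = x$rf$rf[x$rf$standard == std]
    )
  })
}

#' @export
glance.rf_fit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(m, std) {
    s <- summary(m)
    tibble::tibble(standard = std, r.squared = s$r.squared,
                   sigma = s$sigma, nobs = stats::nobs(m))
  })
}

#' Semi-quantify annotated lipids against an injection standard
#'
#' Converts peak areas to amounts via
#' `amount = (area / std_area) * std_amount / rf(class)` and reports each
#' lipid's relative abundance as a percentage of the total pool. Percentages
#' are computed on ng amounts (not areas) and sum to 100.
#'
#' @param areas Tibble/data frame with columns `name` (systematic lipid name)
#'   and `area`.
#' @param std_area Peak area of the injection standard (> 0).
#' @param std_amount Injected standard amount in ng (default 2 ng).
#' @param rf Response-factor table (`class`, `rf`), e.g.
#'   [default_response_factors()] or `fit_response_factor(...)$rf` joined to
#'   classes.
#' @param library Library used to resolve each lipid's class (default
#'   [default_library()]).
#' @return Tibble with columns `name`, `class`, `area`, `amount_ng`,
#'   `rel_abundance` (percent, sums to 100).
#' @export
quantify <- function(areas, std_area, std_amount = 2,
                     rf = default_response_factors(),
                     library = default_library()) {
  if (length(std_area) != 1 || !is.finite(std_area) || std_area <= 0) {
    stop("standard area must be a single positive number", call. = FALSE)
  }
  areas <- tibble::as_tibble(areas)
  stopifnot(all(c("name", "area") %in% names(areas)))
  out <- areas |>
    dplyr::left_join(dplyr::select(library, "name", "class"), by = "name") |>
    dplyr::left_join(dplyr::select(rf, "class", "rf"), by = "class")
  if (anyNA(out$class) || anyNA(out$rf)) {
    bad <- unique(out$name[is.na(out$class) | is.na(out$rf)])
    stop("no response-factor class for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out |>
    dplyr::mutate(
      amount_ng = (.data$area / std_area) * std_amount / .data$rf,
      rel_abundance = 100 * .data$amount_ng / sum(.data$amount_ng)
    ) |>
    dplyr::select("name", "class", "area", "amount_ng", "rel_abundance")
}

#' Grouped relative-abundance report
#'
#' Renormalises amounts within a requested grouping: `"total"` (all lipids),
#' `"extended_fraction"` (lipids carrying at least one extra isoprenoid unit)
#' or `"tetraether_fraction"` (non-AR cores). Percentages within the group
#' sum to 100.
#'
#' @param records Output of [quantify()].
#' @param grouping One of `"total"`, `"extended_fraction"`,
#'   `"tetraether_fraction"`.
#' @param library Library used for the descriptor predicates.
#' @return Tibble `name`, `amount_ng`, `pct` (within-group percentage).
#' @export
abundance_report <- function(records,
                             grouping = c("total", "extended_fraction",
                                          "tetraether_fraction"),
                             library = default_library()) {
  grouping <- match.arg(grouping)
  if (is.null(records) || nrow(records) == 0) {
    stop("no quantification records", call. = FALSE)
  }
  info <- dplyr::select(library, "name", "extensions", "core")
  grp <- records |>
    dplyr::left_join(info, by = "name") |>
    dplyr::filter(
      switch(grouping,
             total = TRUE,
             extended_fraction = .data$extensions > 0,
             tetraether_fraction = .data$core != "AR")
    )
  if (nrow(grp) == 0) {
    stop("grouping '", grouping, "' selects no lipids", call. = FALSE)
  }
  grp |>
    dplyr::mutate(pct = 100 * .data$amount_ng / sum(.data$amount_ng)) |>
    dplyr::select("name", "amount_ng", "pct")
}
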