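# MS1 feature annotation and homolog-series (mass-ladder) detection.
#
# The series detector looks for chains of features whose consecutive m/z
# differences equal one isoprenoid repeat unit (C5H10 within a tetraether
# series; C5H12 across the GDGT->GTGT step) and whose retention times follow
# the chromatographic mode's elution direction: extension homologs elute
# later in reversed phase, earlier in normal phase.

#' Annotate MS1 features against a lipid library
#'
#' Every feature within tolerance of any library adduct m/z yields a hit;
#' a feature may collect several candidates, ranked by absolute ppm error and,
#' on ties, by fewer structural modifications (extensions + rings + hexoses).
#'
#' @param features Tibble/data frame with columns `feature_id`, `mz`, and
#'   optionally `rt_min`, `intensity`.
#' @param library Library tibble from [enumerate_library()] /
#'   [default_library()].
#' @param tol_ppm MS1 match tolerance in ppm (default 5).
#' @param adducts_used Adduct columns to search (default all three).
#' @return Tibble with one row per (feature, candidate) pair: feature columns
#'   plus `name`, `adduct`, `theo_mz`, `ppm`, `rank`.
#' @examples
#' lib <- default_library()
#' feats <- tibble::tibble(feature_id = "F1", mz = 1302.326)
#' annotate_features(feats, lib, tol_ppm = 5)
#' @export
annotate_features <- function(features, library, tol_ppm = 5,
                              adducts_used = c("+H", "+NH4", "+Na")) {
  if (is.null(library) || nrow(library) == 0) {
    stop("library must be non-empty", call. = FALSE)
  }
  features <- tibble::as_tibble(features)
  stopifnot(all(c("feature_id", "mz") %in% names(features)),
            !anyDuplicated(features$feature_id))

  targets <- library |>
    dplyr::select("name", "extensions", "rings", "hexoses",
                  dplyr::all_of(paste0("mz_M", adducts_used))) |>
    tidyr::pivot_longer(dplyr::starts_with("mz_M"),
                        names_to = "adduct", values_to = "theo_mz") |>
    dplyr::mutate(adduct = sub("^mz_M", "", .data$adduct),
                  n_mod = .data$extensions + .data$rings + .data$hexoses)

  hits <- tidyr::crossing(
    dplyr::select(features, "feature_id", obs_mz = "mz"),
    targets
  ) |>
    dplyr::mutate(ppm = ppm_error(.data$obs_mz, .data$theo_mz)) |>
    dplyr::filter(abs(.data$ppm) <= tol_ppm) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::arrange(abs(.data$ppm), .data$n_mod, .data$name,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()

  features |>
    dplyr::inner_join(hits, by = "feature_id") |>
    dplyr::select(-"obs_mz", -"n_mod") |>
    dplyr::arrange(.data$feature_id, .data$rank)
}

# repeat-unit masses are derived from formulas, never hard-coded
.repeat_unit_mass <- function(unit) {
  unit <- match.arg(unit, c("C5H10", "C5H12"))
  monoisotopic_mass(unit)
}

#' Detect homolog series in a feature table
#'
#' Finds maximal chains of features whose consecutive m/z differences equal
#' the repeat-unit mass within `tol_ppm` (evaluated relative to the heavier
#' member's m/z; the default 15 ppm is looser than the MS1 tolerance because
#' the errors of two features compound) and whose retention times are strictly
#' monotone in `rt_direction`. Chains are maximal -- not extendable at either
#' end -- and each is reported once; overlapping chains are all reported
#' (discovery recall over precision). Series of three or more members are
#' flagged `strong`.
#'
#' @param features Tibble with `feature_id`, `mz`, `rt_min`.
#' @param unit Repeat unit, `"C5H10"` (isoprenoid) or `"C5H12"`.
#' @param tol_ppm Tolerance on each consecutive mass difference, in ppm of the
#'   heavier member's m/z.
#' @param rt_direction `"increasing"` (reversed phase) or `"decreasing"`
#'   (normal phase).
#' @return Tibble with one row per series: `series_id`, `members`
#'   (list-column of feature ids, ordered by m/z), `n`, `repeat_unit`,
#'   `mean_ppm` (mean signed deviation of the steps), `rt_direction`,
#'   `strong`.
#' @export
detect_series <- function(features, unit = "C5H10", tol_ppm = 15,
                          rt_direction = c("increasing", "decreasing")) {
  rt_direction <- match.arg(rt_direction)
  features <- tibble::as_tibble(features)
  if (nrow(features) < 2) {
    return(.empty_series(unit, rt_direction))
  }
  stopifnot(all(c("feature_id", "mz", "rt_min") %in% names(features)))
  umass <- .repeat_unit_mass(unit)

  f <- dplyr::arrange(features, .data$mz)
  n <- nrow(f)
  # adjacency: j follows i if mz_j - mz_i matches the unit and rt is ordered
  succ <- vector("list", n)
  has_pred <- logical(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dmz <- f$mz[j] - f$mz[i]
      if (abs(dmz - umass) <= tol_ppm * 1e-6 * f$mz[j] &&
          ((rt_direction == "increasing" && f$rt_min[j] > f$rt_min[i]) ||
           (rt_direction == "decreasing" && f$rt_min[j] < f$rt_min[i]))) {
        succ[[i]] <- c(succ[[i]], j)
        has_pred[j] <- TRUE
      }
    }
  }

  chains <- list()
  walk <- function(path) {
    nxt <- succ[[path[length(path)]]]
    if (length(nxt) == 0) {
      if (length(path) >= 2) chains[[length(chains) + 1L]] <<- path
      return(invisible())
    }
    for (j in nxt) walk(c(path, j))
  }
  for (i in which(!has_pred)) walk(i)
  if (length(chains) == 0) {
    return(.empty_series(unit, rt_direction))
  }

  purrr::imap_dfr(chains, function(idx, sid) {
    steps <- diff(f$mz[idx])
    tibble::tibble(
      series_id = sid,
      members = list(f$feature_id[idx]),
      n = length(idx),
      repeat_unit = unit,
      mean_ppm = mean(1e6 * (steps - umass) / f$mz[idx][-1]),
      rt_direction = rt_direction,
      strong = length(idx) >= 3
    )
  })
}

.empty_series <- function(unit, rt_direction) {
  tibble::tibble(series_id = integer(0), members = list(), n = integer(0),
                 repeat_unit = character(0), mean_ppm = numeric(0),
                 rt_direction = character(0), strong = logical(0))
}

#' Classify the core hypothesis for a detected series
#'
#' A tetraether extension series rooted at a GTGT is 2 H (2.016 Da) heavier
#' than the corresponding GDGT. If the feature table contains a co-occurring
#' feature one H2 below the series root (within tolerance), the root is
#' labelled `"GTGT-series"`; a partner one H2 above labels it
#' `"GDGT-series"`; otherwise `"unknown"`.
#'
#' @param series One row of the [detect_series()] output (tibble slice).
#' @param features The feature table the series was detected in.
#' @param tol_ppm Tolerance for recognising the H2 offset (default mirrors the
#'   MS1 tolerance, 5 ppm).
#' @return `"GTGT-series"`, `"GDGT-series"` or `"unknown"`.
#' @export
series_class_hypothesis <- function(series, features, tol_ppm = 5) {
  stopifnot(nrow(series) == 1)
  features <- tibble::as_tibble(features)
  ids <- series$members[[1]]
  member_mz <- features$mz[match(ids, features$feature_id)]
  root <- min(member_mz)
  h2 <- monoisotopic_mass("H2")
  others <- features$mz[!features$feature_id %in% ids]
  tol <- tol_ppm * 1e-6 * root
  if (any(abs(others - (root - h2)) <= tol)) return("GTGT-series")
  if (any(abs(others - (root + h2)) <= tol)) return("GDGT-series")
  "unknown"
}
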