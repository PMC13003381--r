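# In-silico MS2 fragmentation of archaeal ether lipids.
#
# Product-ion chemistry follows the diagnostic scheme observed for these
# lipids in positive mode: pendant chains leave as alkenes CnH2n (phytane /
# sesterterpane analogues), bridging chains as dienes CnH(2n-2), glycerol as
# C3H8O3, hexose head groups as C6H10O5, plus water losses and the
# glycerol-monoalkyl counter-ions (e.g. C23H48O3, C28H58O3). All product ions
# are modelled as protonated, including those from [M+NH4]+ precursors.

.kind_priority <- c("precursor", "chain_glycerol_ion", "chain_loss",
                    "headgroup_loss", "combined_loss", "glycerol_loss",
                    "water_loss")

.proton_mass <- function() monoisotopic_mass("H") - ELECTRON_MASS

#' Predict theoretical MS2 fragments for a lipid
#'
#' Enumerates the diagnostic product ions for a descriptor and precursor
#' adduct: the precursor itself; per pendant chain, the neutral loss CnH2n and
#' the complementary glycerol-monoalkyl ion C(n+3)H(2n+8)O3; per bridging
#' chain, the neutral loss CnH(2n-2) (whose complement is the
#' glycerol-chain-glycerol ion); loss of one glycerol, alone and combined with
#' each chain loss; one and two water losses; and per hexose the C6H10O5
#' head-group loss (ammoniated precursors yield protonated fragments). The
#' list is deduplicated by fragment formula (symmetric lipids collapse their
#' equivalent chain losses).
#'
#' @param d A [lipid_descriptor()].
#' @param adduct Precursor adduct, `"+H"` or `"+NH4"` (`"+Na"` fragmentation
#'   is not modelled).
#' @return Tibble with columns `kind`, `annotation`, `frag_formula` (neutral
#'   part of the detected cation), `loss_formula` (complement w.r.t. the
#'   precursor neutral), `mz`.
#' @examples
#' d <- lipid_descriptor("GTGT", bridges = 40, pendants = c(20, 25))
#' predict_fragments(d)
#' @export
predict_fragments <- function(d, adduct = "+H") {
  stopifnot(inherits(d, "lipid_descriptor"))
  if (!adduct %in% c("+H", "+NH4")) {
    stop("fragmentation modelled for +H and +NH4 precursors only",
         call. = FALSE)
  }
  M <- build_formula(d)
  proton <- .proton_mass()
  rows <- list()
  add <- function(kind, frag, loss, annotation) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      kind = kind,
      annotation = annotation,
      frag_formula = format_formula(frag),
      loss_formula = format_formula(loss),
      mz = monoisotopic_mass(frag) +
        if (kind == "precursor") .cation_mass(adduct) else proton
    )
  }
  ion <- function(loss_formula) {
    paste0("[M-", loss_formula, "+H]+")
  }

  add("precursor", M, "", paste0("[M", adduct, "]+"))

  chain_losses <- list()
  for (n in d$pendants) {
    loss <- c(C = n, H = 2L * n)                       # alkene, e.g. C20H40
    chain_losses <- c(chain_losses, list(loss))
    add("chain_loss", formula_subtract(M, loss), loss, ion(format_formula(loss)))
    gro_ion <- c(C = n + 3L, H = 2L * n + 8L, O = 3L)  # glycerol-monoalkyl
    add("chain_glycerol_ion", gro_ion, formula_subtract(M, gro_ion),
        paste0("[", format_formula(gro_ion), "+H]+"))
  }
  for (n in d$bridges) {
    loss <- c(C = n, H = 2L * n - 2L)                  # diene, e.g. C40H78
    chain_losses <- c(chain_losses, list(loss))
    add("chain_loss", formula_subtract(M, loss), loss, ion(format_formula(loss)))
  }

  add("glycerol_loss", formula_subtract(M, GLYCEROL), parse_formula(GLYCEROL),
      ion(GLYCEROL))
  for (loss in chain_losses) {
    comb <- formula_add(loss, GLYCEROL)
    add("combined_loss", formula_subtract(M, comb), comb,
        ion(format_formula(comb)))
  }

  add("water_loss", formula_subtract(M, "H2O"), parse_formula("H2O"),
      ion("H2O"))
  add("water_loss", formula_subtract(M, "H4O2"), parse_formula("H4O2"),
      ion("2H2O"))

  if (d$hexoses > 0L) {
    for (k in seq_len(d$hexoses)) {
      loss <- c(C = 6L * k, H = 10L * k, O = 5L * k)
      add("headgroup_loss", formula_subtract(M, loss), loss,
          ion(paste0(if (k > 1L) k else "", HEXOSE_INCREMENT)))
    }
  }

  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(kind = factor(.data$kind, levels = .kind_priority)) |>
    dplyr::arrange(.data$kind, .data$annotation) |>
    dplyr::distinct(.data$frag_formula, .keep_all = TRUE) |>
    dplyr::mutate(kind = as.character(.data$kind)) |>
    dplyr::arrange(dplyr::desc(.data$mz))
  out
}

#' Match an observed MS2 spectrum against theoretical fragments
#'
#' Each theoretical fragment is assigned its nearest peak; the assignment
#' stands if the absolute deviation is within the tolerance (the larger of
#' `tol_ppm` and `tol_da` at that m/z, reflecting that printed observed
#' fragment masses deviate from theory by a few mDa). One peak may satisfy
#' several mass-identical annotations. Ties (a fragment equidistant between
#' two peaks) resolve to the lower-m/z peak; output order follows `frags`,
#' so the result is deterministic.
#'
#' @param spectrum Tibble/data frame with columns `mz` and `intensity`.
#' @param frags Fragment table from [predict_fragments()].
#' @param tol_ppm,tol_da Match tolerance; effective window is
#'   `max(tol_ppm * 1e-6 * mz, tol_da)`.
#' @return Tibble of matched fragments with `peak_mz`, `peak_intensity`,
#'   `ppm` columns appended; zero rows if nothing (or an empty spectrum)
#'   matches.
#' @export
match_spectrum <- function(spectrum, frags, tol_ppm = 10, tol_da = 0.005) {
  stopifnot(is.data.frame(frags))
  if (is.null(spectrum) || nrow(spectrum) == 0) {
    return(dplyr::mutate(frags[0, ], peak_mz = numeric(0),
                         peak_intensity = numeric(0), ppm = numeric(0)))
  }
  peaks <- dplyr::arrange(tibble::as_tibble(spectrum), .data$mz)
  hit <- purrr::map_dfr(seq_len(nrow(frags)), function(i) {
    theo <- frags$mz[i]
    dev <- abs(peaks$mz - theo)
    j <- which(dev == min(dev))[1]               # lower-m/z peak on ties
    tol <- max(tol_ppm * 1e-6 * theo, tol_da)
    if (dev[j] > tol) return(NULL)
    dplyr::mutate(frags[i, ],
                  peak_mz = peaks$mz[j],
                  peak_intensity = peaks$intensity[j],
                  ppm = ppm_error(peaks$mz[j], theo))
  })
  if (nrow(hit) == 0) {
    return(dplyr::mutate(frags[0, ], peak_mz = numeric(0),
                         peak_intensity = numeric(0), ppm = numeric(0)))
  }
  hit
}

#' Score how well a spectrum supports a predicted fragment list
#'
#' Weighted fraction of predicted fragments that found a peak: the diagnostic
#' `chain_glycerol_ion` and `chain_loss` kinds carry weight 2, all other kinds
#' weight 1. Equals 1 iff every predicted fragment matched, 0 if none did.
#'
#' @param matches Output of [match_spectrum()].
#' @param frags The fragment table the matches were computed from.
#' @return Score in `[0, 1]`.
#' @export
fragment_score <- function(matches, frags) {
  if (is.null(frags) || nrow(frags) == 0) {
    stop("fragment list is empty", call. = FALSE)
  }
  w <- ifelse(frags$kind %in% c("chain_glycerol_ion", "chain_loss"), 2, 1)
  matched <- frags$annotation %in% matches$annotation
  sum(w[matched]) / sum(w)
}
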