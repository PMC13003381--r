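# Synthetic feature tables, MS2 spectra and calibration files with the
# statistical structure the analysis assumes: singly charged +H/+NH4/+Na
# ions, ppm-scale Gaussian mass error (high-resolution instruments calibrate
# to better than 1 ppm), mode-dependent retention-time ordering of extension
# homologs, and MS2 peak lists that follow the predicted fragmentation
# scheme. All randomness is driven by one explicit seed per call.

# relative ionisation yield of the three adducts (ammoniated ions dominate
# for these lipids in positive ESI)
.adduct_weights <- c("+H" = 0.3, "+NH4" = 0.6, "+Na" = 0.1)

#' Mixture approximating the geyser lipidome composition
#'
#' Named mixture used throughout tests and examples: dominated by glycosidic
#' archaeols (2G-AR 35%, 1G-AR 15%), ~34% regular tetraethers, ~10% extended
#' lipids (glycosidic extended archaeols over half of that fraction, extended
#' tetraethers the rest), remainder core AR and 3G-AR. Percentages sum to 100.
#'
#' @return Tibble with columns `name`, `pct`.
#' @export
mixture_fig1 <- function() {
  tibble::tibble(
    name = c("2G-AR", "1G-AR", "AR", "3G-AR",
             "iGDGT-0", "1G-iGDGT-0",
             "1G-ext-AR", "2G-ext-AR", "ext-AR",
             "ext-iGTGT-0", "di-ext-iGTGT-0",
             "ext-iGDGT-0", "di-ext-iGDGT-0"),
    pct = c(35, 15, 4, 2,
            24, 10,
            3, 3, 1.3,
            1.8, 0.8,
            0.05, 0.05)
  )
}

#' Generate a synthetic MS1 feature table for a lipid mixture
#'
#' One feature per lipid per adduct. Observed m/z is the library theoretical
#' m/z perturbed by multiplicative Gaussian error of `mass_sigma_ppm` ppm.
#' Retention time follows a simple monotone model of core type, extension
#' count and hexose count: in reversed phase (RP) each extension adds 1 min
#' (anchored at iGDGT-0 = 24.4 min) and each hexose elutes 1.2 min earlier;
#' in normal phase (NP) extensions elute 1 min earlier and hexoses 3 min
#' later. Peak area is proportional to amount x class response factor x
#' adduct weight, with lognormal area noise of coefficient of variation
#' `intensity_cv`. The injected-standard area consistent with the same
#' proportionality is attached as attribute `std_area` (for `std_amount` ng),
#' and the true composition as attribute `truth`.
#'
#' @param mixture Tibble with `name`, `pct` (percent, summing to 100), e.g.
#'   [mixture_fig1()].
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param mode Chromatography mode, `"RP"` or `"NP"`.
#' @param mass_sigma_ppm Gaussian m/z error (ppm), default 1.
#' @param rt_sigma_min Gaussian retention-time jitter (min).
#' @param intensity_cv Lognormal area noise (coefficient of variation).
#' @param total_ng Total lipid amount represented by the mixture (ng).
#' @param std_amount Injection-standard amount (ng).
#' @param rf Response-factor table used to scale areas by class.
#' @param library Library supplying theoretical masses and descriptors.
#' @return Feature tibble: `feature_id`, `mz`, `rt_min`, `intensity`,
#'   `true_name`, `true_adduct`; attributes `std_area`, `std_amount`,
#'   `truth`.
#' @export
generate_features <- function(mixture, seed = 1, mode = c("RP", "NP"),
                              mass_sigma_ppm = 1, rt_sigma_min = 0.05,
                              intensity_cv = 0.02, total_ng = 100,
                              std_amount = 2,
                              rf = default_response_factors(),
                              library = default_library()) {
  mode <- match.arg(mode)
  mixture <- tibble::as_tibble(mixture)
  stopifnot(all(c("name", "pct") %in% names(mixture)))
  if (abs(sum(mixture$pct) - 100) > 1e-6) {
    stop("mixture percentages must sum to 100", call. = FALSE)
  }
  if (mass_sigma_ppm < 0 || rt_sigma_min < 0 || intensity_cv < 0) {
    stop("noise levels must be non-negative", call. = FALSE)
  }
  missing <- setdiff(mixture$name, library$name)
  if (length(missing) > 0) {
    stop("mixture lipids not in library: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  area_per_ng <- 1e4  # arbitrary-unit proportionality of the instrument

  base <- mixture |>
    dplyr::left_join(library, by = "name") |>
    dplyr::left_join(dplyr::select(rf, "class", "rf"), by = "class") |>
    tidyr::pivot_longer(dplyr::starts_with("mz_M"),
                        names_to = "adduct", values_to = "theo_mz") |>
    dplyr::mutate(
      adduct = sub("^mz_M", "", .data$adduct),
      amount_ng = total_ng * .data$pct / 100,
      rt_base = .rt_model(.data$core, .data$extensions, .data$hexoses, mode),
      area0 = .data$amount_ng * .data$rf *
        .adduct_weights[.data$adduct] * area_per_ng
    )

  withr::with_seed(seed, {
    out <- base |>
      dplyr::mutate(
        feature_id = sprintf("F%03d", dplyr::row_number()),
        mz = .data$theo_mz *
          (1 + stats::rnorm(dplyr::n(), 0, mass_sigma_ppm * 1e-6)),
        rt_min = .data$rt_base + stats::rnorm(dplyr::n(), 0, rt_sigma_min),
        intensity = .data$area0 *
          stats::rlnorm(dplyr::n(),
                        -0.5 * log(1 + intensity_cv^2),
                        sqrt(log(1 + intensity_cv^2)))
      ) |>
      dplyr::select("feature_id", "mz", "rt_min", "intensity",
                    true_name = "name", true_adduct = "adduct")
  })
  attr(out, "std_area") <- std_amount * area_per_ng
  attr(out, "std_amount") <- std_amount
  attr(out, "truth") <- mixture
  out
}

# monotone retention-time model; annotation only relies on the ordering
.rt_model <- function(core, extensions, hexoses, mode) {
  base <- ifelse(core == "AR", 15, 24.4)
  if (mode == "RP") {
    base + 1.0 * extensions - 1.2 * hexoses
  } else {
    (ifelse(core == "AR", 20, 40)) - 1.0 * extensions + 3.0 * hexoses
  }
}

#' Generate a synthetic MS2 spectrum for a lipid
#'
#' Places one peak per predicted fragment, with multiplicative Gaussian mass
#' error. Intensities follow a fixed per-kind profile in which the
#' glycerol-monoalkyl ions are highest and scale with chain length (so the
#' glycerol-C25 ion is the base peak of extended lipids). Optional decoy peaks
#' are drawn uniformly over the spectrum's m/z range and flagged in the
#' `is_decoy` column so tests can separate true from false matches.
#'
#' @param d A [lipid_descriptor()].
#' @param adduct Precursor adduct (`"+H"` or `"+NH4"`).
#' @param mass_sigma_ppm Gaussian peak m/z error (ppm).
#' @param seed Integer seed.
#' @param n_decoys Number of decoy peaks to add.
#' @return Tibble `mz`, `intensity`, `is_decoy`; attributes `title`
#'   (systematic name + adduct) and `pepmass` (precursor m/z).
#' @export
generate_ms2 <- function(d, adduct = "+H", mass_sigma_ppm = 0, seed = 1,
                         n_decoys = 0) {
  frags <- predict_fragments(d, adduct)
  kind_base <- c(precursor = 50, chain_loss = 60, chain_glycerol_ion = 100,
                 headgroup_loss = 80, combined_loss = 40, glycerol_loss = 30,
                 water_loss = 20)
  inten <- kind_base[frags$kind]
  gly <- frags$kind == "chain_glycerol_ion"
  if (any(gly)) {
    # scale by pendant chain length: C(n+3)H(2n+8)O3 -> n carbons in chain
    n_chain <- vapply(frags$frag_formula[gly],
                      function(f) parse_formula(f)[["C"]] - 3L, integer(1))
    inten[gly] <- 100 * n_chain / 20
  }
  precursor_mz <- frags$mz[frags$kind == "precursor"][1]
  withr::with_seed(seed, {
    mz <- frags$mz * (1 + stats::rnorm(nrow(frags), 0, mass_sigma_ppm * 1e-6))
    spec <- tibble::tibble(mz = mz, intensity = unname(inten),
                           is_decoy = FALSE)
    if (n_decoys > 0) {
      spec <- dplyr::bind_rows(spec, tibble::tibble(
        mz = stats::runif(n_decoys, 100, precursor_mz),
        intensity = stats::runif(n_decoys, 1, 20),
        is_decoy = TRUE
      ))
    }
  })
  spec <- dplyr::arrange(spec, .data$mz)
  attr(spec, "title") <- paste(systematic_name(d), adduct)
  attr(spec, "pepmass") <- precursor_mz
  spec
}

#' Generate a synthetic calibration file
#'
#' Proportional calibration points (area = slope x amount) for the four class
#' standards, with optional lognormal area noise -- the input
#' [fit_response_factor()] expects.
#'
#' @param slopes Named numeric vector of area-per-ng slopes per standard.
#' @param amounts_ng Calibration levels (ng).
#' @param noise_cv Lognormal area noise.
#' @param seed Integer seed.
#' @return Tibble `standard`, `amount_ng`, `area`.
#' @export
generate_calibration <- function(slopes = c("GTGT-C46" = 1e4, "AR" = 8e3,
                                            "2G-AR" = 1.2e4,
                                            "1G-iGDGT-0" = 9e3),
                                 amounts_ng = c(0.5, 1, 2, 4),
                                 noise_cv = 0, seed = 1) {
  grid <- tidyr::expand_grid(standard = names(slopes),
                             amount_ng = amounts_ng)
  withr::with_seed(seed, {
    grid |>
      dplyr::mutate(
        area = slopes[.data$standard] * .data$amount_ng *
          (if (noise_cv > 0) {
            stats::rlnorm(dplyr::n(), -0.5 * log(1 + noise_cv^2),
                          sqrt(log(1 + noise_cv^2)))
          } else 1)
      )
  })
}
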