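# Constructive structural model of archaeal ether lipids.
#
# A lipid is described by its core type, its isoprenoid chains, cyclopentane
# ring count and hexose head-group count; the elemental formula is derived by
# ether condensation: glycerol(s) + chains as saturated alcohols/diols, minus
# one H2O per ether bond, minus H2 per ring (and per GMGT C-C bridge), plus
# C6H10O5 per hexose.

GLYCEROL <- "C3H8O3"
HEXOSE_INCREMENT <- "C6H10O5" # dehydrated glucose unit

.core_tokens <- c(AR = "AR", GDGT = "iGDGT", GTGT = "iGTGT", GMGT = "iGMGT")

#' Describe an archaeal ether lipid
#'
#' Builds a validated structural descriptor from which the elemental formula
#' and systematic name are derived. Chain roles follow the core architecture:
#' archaeol (AR) carries two pendant chains on one glycerol; GDGT (and its
#' C-C-bridged GMGT variant) two glycerols bridged by two chains; GTGT one
#' bridging chain plus two pendant chains.
#'
#' @param core One of `"AR"`, `"GDGT"`, `"GTGT"`, `"GMGT"`.
#' @param bridges Integer carbon numbers of bridging chains (each 40, 45 or
#'   50). Two for GDGT/GMGT, one for GTGT, none for AR.
#' @param pendants Integer carbon numbers of pendant chains (each 20 or 25).
#'   Two for AR and GTGT, none for GDGT/GMGT.
#' @param rings Total cyclopentane ring count (0-8); rings sit on bridging
#'   chains, so AR must have 0.
#' @param hexoses Hexose (glucose) head-group count, 0-3.
#' @return Object of class `lipid_descriptor`.
#' @examples
#' lipid_descriptor("GDGT", bridges = c(40, 40))            # iGDGT-0
#' lipid_descriptor("GTGT", bridges = 40, pendants = c(20, 25)) # ext-iGTGT-0
#' @export
lipid_descriptor <- function(core, bridges = integer(), pendants = integer(),
                             rings = 0L, hexoses = 0L) {
  core <- match.arg(core, names(.core_tokens))
  bridges <- sort(as.integer(bridges))
  pendants <- sort(as.integer(pendants))
  rings <- as.integer(rings)
  hexoses <- as.integer(hexoses)

  n_bridges <- switch(core, AR = 0L, GTGT = 1L, GDGT = 2L, GMGT = 2L)
  n_pendants <- switch(core, AR = 2L, GTGT = 2L, GDGT = 0L, GMGT = 0L)
  if (length(bridges) != n_bridges || length(pendants) != n_pendants) {
    stop(core, " requires ", n_bridges, " bridging and ", n_pendants,
         " pendant chain(s)", call. = FALSE)
  }
  if (!all(bridges %in% c(40L, 45L, 50L))) {
    stop("bridging chains must have 40, 45 or 50 carbons", call. = FALSE)
  }
  if (!all(pendants %in% c(20L, 25L))) {
    stop("pendant chains must have 20 or 25 carbons", call. = FALSE)
  }
  if (rings < 0L || rings > 8L) stop("rings must be in 0..8", call. = FALSE)
  if (rings > 0L && n_bridges == 0L) {
    stop("cyclopentane rings sit on bridging chains; AR cannot carry rings",
         call. = FALSE)
  }
  if (hexoses < 0L || hexoses > 3L) {
    stop("hexoses must be in 0..3", call. = FALSE)
  }
  structure(
    list(core = core, bridges = bridges, pendants = pendants,
         rings = rings, hexoses = hexoses),
    class = "lipid_descriptor"
  )
}

#' @export
print.lipid_descriptor <- function(x, ...) {
  cat("<lipid_descriptor> ", systematic_name(x), "  [",
      format_formula(build_formula(x)), "]\n", sep = "")
  invisible(x)
}

#' Number of extra C5 isoprenoid units carried by a descriptor
#'
#' Pendant chains count (n-20)/5 units, bridging chains (n-40)/5; the paper's
#' "extended" lipids carry 1, "di-extended" 2.
#'
#' @param d A `lipid_descriptor`.
#' @return Integer extension count.
#' @export
extension_count <- function(d) {
  stopifnot(inherits(d, "lipid_descriptor"))
  as.integer(sum((d$pendants - 20L) / 5L) + sum((d$bridges - 40L) / 5L))
}

#' Derive the elemental formula of a lipid
#'
#' Condensation arithmetic: one glycerol (AR) or two glycerols (tetraethers),
#' plus each pendant chain as a saturated alcohol CnH(2n+2)O and each bridging
#' chain as a diol CnH(2n+2)O2, minus one H2O per ether bond (2 for AR, 4 for
#' tetraethers), minus H2 per cyclopentane ring, minus H2 for the GMGT C-C
#' bridge, plus C6H10O5 per hexose head group.
#'
#' @param d A `lipid_descriptor`.
#' @return Named integer element-count vector (see [format_formula()]).
#' @examples
#' format_formula(build_formula(lipid_descriptor("GDGT", bridges = c(40, 40))))
#' @export
build_formula <- function(d) {
  stopifnot(inherits(d, "lipid_descriptor"))
  n_glycerol <- if (d$core == "AR") 1L else 2L
  n_ether <- if (d$core == "AR") 2L else 4L

  f <- stats::setNames(integer(0), character(0))
  for (i in seq_len(n_glycerol)) f <- formula_add(f, GLYCEROL)
  for (n in d$pendants) {
    f <- formula_add(f, c(C = n, H = 2L * n + 2L, O = 1L))
  }
  for (n in d$bridges) {
    f <- formula_add(f, c(C = n, H = 2L * n + 2L, O = 2L))
  }
  f <- formula_subtract(f, c(H = 2L * n_ether, O = n_ether))
  if (d$rings > 0L) f <- formula_subtract(f, c(H = 2L * d$rings))
  if (d$core == "GMGT") f <- formula_subtract(f, c(H = 2L))
  for (i in seq_len(d$hexoses)) f <- formula_add(f, HEXOSE_INCREMENT)
  f
}

#' Systematic name of a lipid descriptor
#'
#' Deterministic field-style name: optional `nG-` hexose prefix, `ext-` /
#' `di-ext-` by total extension count, core token (`AR`, `iGDGT`, `iGTGT`,
#' `iGMGT`), and for tetraethers a `-r` total ring-count suffix.
#'
#' @param d A `lipid_descriptor`.
#' @return Name string, e.g. `"1G-ext-iGTGT-0"`, `"2G-AR"`.
#' @export
systematic_name <- function(d) {
  stopifnot(inherits(d, "lipid_descriptor"))
  ext <- extension_count(d)
  paste0(
    if (d$hexoses > 0L) paste0(d$hexoses, "G-") else "",
    c("", "ext-", "di-ext-")[ext + 1L],
    .core_tokens[[d$core]],
    if (d$core != "AR") paste0("-", d$rings) else ""
  )
}

#' Lipid class used for response-factor mapping
#'
#' Classes follow the calibration-standard scheme: intact glycosidic archaeols,
#' core archaeols, intact glycosidic tetraethers, core tetraethers.
#'
#' @param core Core type string(s).
#' @param hexoses Hexose count(s).
#' @return Character class label(s).
#' @export
lipid_class <- function(core, hexoses) {
  dplyr::case_when(
    core == "AR" & hexoses > 0 ~ "glycosidic AR",
    core == "AR"               ~ "core AR",
    hexoses > 0                ~ "glycosidic tetraether",
    TRUE                       ~ "core tetraether"
  )
}

# chain assignment for a given core and extension count (0, 1 or 2 extra
# C5 units); the di-extended GDGT is modelled as C40 + C50 (one conserved
# biphytanyl chain), not C45 + C45 -- the mass-identical isomer.
.chains_for <- function(core, ext) {
  pend <- list(c(20L, 20L), c(20L, 25L), c(25L, 25L))[[ext + 1L]]
  brid <- list(c(40L, 40L), c(40L, 45L), c(40L, 50L))[[ext + 1L]]
  switch(core,
    AR   = list(bridges = integer(), pendants = pend),
    GTGT = list(bridges = 40L, pendants = pend),
    GDGT = list(bridges = brid, pendants = integer()),
    GMGT = list(bridges = brid, pendants = integer())
  )
}

#' Enumerate a candidate lipid library
#'
#' Exhaustively enumerates descriptors over the requested core types,
#' extension counts, ring counts and hexose counts, derives each formula and
#' adduct m/z set, and returns a duplicate-free table sorted by neutral mass.
#' Ring-bearing entries are only generated for non-extended tetraethers (the
#' default library does not place rings on extended chains), and AR never
#' carries rings.
#'
#' @param cores Core types to include.
#' @param extensions Extra-isoprenoid-unit counts (subset of 0:2).
#' @param rings Ring counts (subset of 0:8).
#' @param hexoses Hexose counts (subset of 0:3).
#' @return Tibble with columns `name`, `core`, `chains`, `rings`, `hexoses`,
#'   `extensions`, `class`, `formula`, `neutral_mass`, `mz_M+H`, `mz_M+NH4`,
#'   `mz_M+Na`, and a `descriptor` list-column.
#' @examples
#' enumerate_library(cores = "GTGT", extensions = 0:2, rings = 0, hexoses = 0)
#' @export
enumerate_library <- function(cores = c("AR", "GDGT", "GTGT"),
                              extensions = 0:2,
                              rings = 0L,
                              hexoses = 0:3) {
  if (length(cores) == 0 || length(extensions) == 0 ||
      length(rings) == 0 || length(hexoses) == 0) {
    stop("library configuration must be non-empty", call. = FALSE)
  }
  stopifnot(all(cores %in% names(.core_tokens)),
            all(extensions %in% 0:2),
            all(rings %in% 0:8),
            all(hexoses %in% 0:3))

  grid <- tidyr::expand_grid(
    core = cores, ext = as.integer(extensions),
    rings = as.integer(rings), hexoses = as.integer(hexoses)
  ) |>
    dplyr::filter(!(core == "AR" & rings > 0L),
                  !(ext > 0L & rings > 0L)) |>
    dplyr::distinct()

  entries <- purrr::pmap(grid, function(core, ext, rings, hexoses) {
    ch <- .chains_for(core, ext)
    d <- lipid_descriptor(core, bridges = ch$bridges, pendants = ch$pendants,
                          rings = rings, hexoses = hexoses)
    f <- build_formula(d)
    m <- monoisotopic_mass(f)
    tibble::tibble(
      name = systematic_name(d),
      core = core,
      chains = paste0("C", c(ch$bridges, ch$pendants), collapse = "/"),
      rings = rings,
      hexoses = hexoses,
      extensions = ext,
      class = lipid_class(core, hexoses),
      formula = format_formula(f),
      neutral_mass = m,
      `mz_M+H` = adduct_mz(m, "+H"),
      `mz_M+NH4` = adduct_mz(m, "+NH4"),
      `mz_M+Na` = adduct_mz(m, "+Na"),
      descriptor = list(d)
    )
  })
  dplyr::bind_rows(entries) |>
    dplyr::distinct(.data$name, .keep_all = TRUE) |>
    dplyr::arrange(.data$neutral_mass, .data$name)
}

#' Default lipid library
#'
#' Archaeols and tetraethers (GDGT, GTGT, plus acyclic GMGT) with 0-2
#' isoprenoid extensions and 0-3 hexose head groups, no rings. This spans the
#' inventory the annotation stage targets by default.
#'
#' @return Library tibble (see [enumerate_library()]).
#' @export
default_library <- function() {
  enumerate_library(cores = c("AR", "GDGT", "GTGT", "GMGT"),
                    extensions = 0:2, rings = 0L, hexoses = 0:3)
}

#' Look up one library entry's descriptor by name
#' @param library Library tibble.
#' @param name Systematic name.
#' @return `lipid_descriptor`.
#' @export
library_descriptor <- function(library, name) {
  i <- match(name, library$name)
  if (is.na(i)) stop("lipid not in library: ", name, call. = FALSE)
  library$descriptor[[i]]
}
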