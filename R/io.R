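# Plain-text I/O: feature tables and calibration files as CSV/TSV, lipid
# libraries as CSV, MS2 spectra as MGF. MGF is a trivial line-oriented text
# format (BEGIN IONS / TITLE / PEPMASS / peak list / END IONS), parsed here
# directly.

#' Read / write an MS1 feature table
#'
#' CSV or TSV (delimiter inferred from the extension) with columns
#' `feature_id`, `mz`, `rt_min`, `intensity` and optionally `inv_mobility`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_features <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  out <- reader(path, show_col_types = FALSE)
  stopifnot(all(c("feature_id", "mz") %in% names(out)))
  out
}

#' @rdname read_features
#' @param features Feature tibble.
#' @export
write_features <- function(features, path) {
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(features, path)
  invisible(path)
}

#' Write / read a lipid library as CSV
#'
#' Columns: `name`, `core`, `chains`, `rings`, `hexoses`, `formula` (Hill),
#' `neutral_mass`, `mz_M+H`, `mz_M+NH4`, `mz_M+Na`. The descriptor
#' list-column is rebuilt on read from the structural columns.
#'
#' @param library Library tibble from [enumerate_library()].
#' @param path File path.
#' @export
write_library <- function(library, path) {
  library |>
    dplyr::select("name", "core", "chains", "rings", "hexoses", "formula",
                  "neutral_mass", "mz_M+H", "mz_M+NH4", "mz_M+Na") |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  raw |>
    dplyr::mutate(
      descriptor = purrr::pmap(
        list(.data$core, .data$chains, .data$rings, .data$hexoses),
        function(core, chains, rings, hexoses) {
          carbons <- as.integer(sub("^C", "", strsplit(chains, "/")[[1]]))
          lipid_descriptor(core,
                           bridges = carbons[carbons >= 40],
                           pendants = carbons[carbons < 40],
                           rings = rings, hexoses = hexoses)
        }
      ),
      extensions = purrr::map_int(.data$descriptor, extension_count),
      class = lipid_class(.data$core, .data$hexoses)
    )
}

#' Write MS2 spectra to an MGF file
#'
#' @param spectra A single spectrum tibble (`mz`, `intensity`, attributes
#'   `title`/`pepmass`, as from [generate_ms2()]) or a list of them.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  if (is.data.frame(spectra)) spectra <- list(spectra)
  lines <- unlist(lapply(spectra, function(s) {
    c("BEGIN IONS",
      paste0("TITLE=", attr(s, "title") %||% "spectrum"),
      paste0("PEPMASS=", format(attr(s, "pepmass") %||% max(s$mz),
                                nsmall = 4, trim = TRUE)),
      "CHARGE=1+",
      sprintf("%.5f %.4f", s$mz, s$intensity),
      "END IONS", "")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read MS2 spectra from an MGF file
#'
#' @param path MGF file path.
#' @return List of spectrum tibbles (`mz`, `intensity`) with `title` and
#'   `pepmass` attributes.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) {
    stop("malformed MGF: unbalanced BEGIN/END IONS", call. = FALSE)
  }
  purrr::map2(begins, ends, function(b, e) {
    block <- lines[(b + 1):(e - 1)]
    keyed <- grepl("=", block, fixed = TRUE)
    meta <- block[keyed]
    peaks <- block[!keyed & nzchar(trimws(block))]
    get <- function(key) {
      hit <- meta[startsWith(meta, paste0(key, "="))]
      if (length(hit) == 0) return(NA_character_)
      sub(paste0("^", key, "="), "", hit[1])
    }
    vals <- do.call(rbind, lapply(strsplit(trimws(peaks), "[ \t]+"),
                                  function(x) as.numeric(x[1:2])))
    spec <- tibble::tibble(
      mz = if (length(peaks)) vals[, 1] else numeric(0),
      intensity = if (length(peaks)) vals[, 2] else numeric(0)
    )
    attr(spec, "title") <- get("TITLE")
    attr(spec, "pepmass") <- as.numeric(strsplit(get("PEPMASS"), " ")[[1]][1])
    spec
  })
}

#' Read a calibration file
#'
#' CSV with columns `standard`, `amount_ng`, `area`.
#'
#' @param path File path.
#' @return Tibble suitable for [fit_response_factor()].
#' @export
read_calibration <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("standard", "amount_ng", "area") %in% names(out)))
  out
}
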