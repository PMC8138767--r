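#' Read an anisotropy titration CSV
#'
#' Loads the titration CSV dialect: columns `titrant_conc`, `conc_unit`,
#' `anisotropy`, `replicate` with a header row. Concentrations are
#' converted to molar via the explicit per-row unit -- units are never
#' guessed. Malformed rows are reported with their line numbers.
#'
#' @param path Path to the CSV file.
#' @return A tibble with `titrant_conc` (molar), `conc_unit` (`"M"`),
#'   `anisotropy`, `replicate`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_titration(gen_competition_titration(1e-4, seed = 1), f)
#' read_titration(f)
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("cannot read ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(tab) == 0) stop("empty titration file: ", path, call. = FALSE)
  need <- c("titrant_conc", "conc_unit", "anisotropy", "replicate")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("titration CSV missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(suppressWarnings(as.numeric(tab$titrant_conc))) |
                 is.na(suppressWarnings(as.numeric(tab$anisotropy))))
  if (length(bad)) {
    stop("non-numeric titrant_conc/anisotropy at data line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    titrant_conc = conc_to_molar(as.numeric(tab$titrant_conc),
                                 tab$conc_unit),
    conc_unit = "M",
    anisotropy = as.numeric(tab$anisotropy),
    replicate = as.character(tab$replicate)
  )
}

#' @rdname read_titration
#' @param data Titration tibble (e.g. from a generator) with columns
#'   `titrant_conc` (molar), `anisotropy`, `replicate`.
#' @export
write_titration <- function(data, path) {
  stopifnot(all(c("titrant_conc", "anisotropy", "replicate") %in%
                  names(data)))
  out <- tibble::tibble(
    titrant_conc = data$titrant_conc,
    conc_unit = if ("conc_unit" %in% names(data)) data$conc_unit else "M",
    anisotropy = data$anisotropy,
    replicate = data$replicate
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a per-residue profile CSV
#'
#' Serializes a (binned) residue profile to the
#' `residue,percent_change,bin,missing_reason` CSV dialect.
#'
#' @param profile A profile from [intensity_change()], optionally after
#'   [bin_changes()].
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  out <- tibble::tibble(
    residue = profile$residue,
    percent_change = profile$percent_change,
    bin = if ("bin" %in% names(profile)) profile$bin else NA_character_,
    missing_reason = profile$missing_reason
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}
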