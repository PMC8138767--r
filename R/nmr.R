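#' Read an NMR peak list
#'
#' Parses per-residue peak intensities from either a Sparky-style list
#' (whitespace-delimited: assignment, one or more chemical-shift columns,
#' intensity/volume in the last numeric column; e.g. `"G220N-H"`) or a
#' generic CSV with columns `residue,intensity`. Assignment strings are
#' reduced to residue numbers in the native full-length protein frame.
#' Rows whose assignment cannot be parsed (e.g. `"?-?"` placeholders from
#' unassigned peaks) are skipped with a message; duplicate residue numbers
#' are an error because the downstream profile is keyed by residue.
#'
#' @param path Path to the peak list file.
#' @param dialect `"sparky_list"` or `"generic_csv"`; `NULL` auto-detects
#'   (CSV header `residue,intensity` wins, otherwise Sparky).
#' @return A tibble with columns `residue` (integer) and `intensity`.
#' @examples
#' f <- tempfile(fileext = ".list")
#' writeLines(c("Assignment w1 w2 Height",
#'              "G220N-H 109.1 8.2 5400",
#'              "V229N-H 121.4 8.0 3100"), f)
#' read_peak_list(f)
#' @export
read_peak_list <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(dialect)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    dialect <- if (grepl("residue", first, ignore.case = TRUE) &&
                   grepl(",", first)) "generic_csv" else "sparky_list"
  }
  dialect <- match.arg(dialect, c("sparky_list", "generic_csv"))
  tab <- switch(dialect,
                generic_csv = read_peaks_csv(path),
                sparky_list = read_peaks_sparky(path))
  if (nrow(tab) == 0) {
    stop("no parseable rows in peak list: ", path,
         " (dialect ", dialect, "); try an explicit dialect", call. = FALSE)
  }
  dup <- tab$residue[duplicated(tab$residue)]
  if (length(dup)) {
    stop("duplicate assignment for residue(s): ",
         paste(sort(unique(dup)), collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(tab, .data$residue)
}

read_peaks_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("residue", "intensity") %in% names(tab))) {
    stop("generic_csv peak list needs columns residue,intensity",
         call. = FALSE)
  }
  tibble::tibble(residue = as.integer(tab$residue),
                 intensity = as.numeric(tab$intensity))
}

read_peaks_sparky <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  # drop header rows (e.g. "Assignment w1 w2 Height")
  lines <- lines[!grepl("^Assignment\\b", lines, ignore.case = TRUE)]
  skipped <- 0L
  rows <- purrr::map(lines, function(ln) {
    tok <- strsplit(ln, "\\s+")[[1]]
    m <- stringr::str_match(tok[1], "^[A-Za-z]{1,3}(\\d+)")
    num <- suppressWarnings(as.numeric(tok[-1]))
    if (is.na(m[1, 2]) || !any(!is.na(num))) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    tibble::tibble(residue = as.integer(m[1, 2]),
                   intensity = num[max(which(!is.na(num)))])
  })
  if (skipped > 0) {
    message("read_peak_list: skipped ", skipped, " unparseable row(s)")
  }
  dplyr::bind_rows(rows)
}

#' Per-residue intensity change between apo and ligand-bound spectra
#'
#' Computes the intensity attenuation statistic `1 - I_bound/I_unbound` for
#' each residue after normalizing the apo and bound peak lists within each
#' dataset, so that overall spectrometer/sample scale differences between
#' the two experiments cancel. A change near 1 marks strong attenuation
#' (binding in intermediate exchange); near 0 no perturbation; negative
#' values (intensity gain) are retained.
#'
#' Normalization statistics:
#' \describe{
#'   \item{`least_changed` (default)}{Each dataset is scaled so that the
#'     median intensity over the 20 percent of shared residues with the smallest
#'     provisional change is 1. Using the least-perturbed residues as the
#'     reference keeps the binding signal itself from biasing the scale.}
#'   \item{`total`}{Scale by the summed intensity of shared residues.}
#'   \item{`max`}{Scale by the maximum intensity of shared residues.}
#' }
#'
#' @param apo,bound Tibbles with columns `residue`, `intensity` (from
#'   [read_peak_list()]). At least 10 residues must be common to both.
#' @param normalization One of `"least_changed"`, `"total"`, `"max"`.
#' @param window Integer vector of residues the profile should cover
#'   (native protein numbering, e.g. `204:283`); defaults to the span of
#'   observed residues. Residues in the window absent from either table are
#'   flagged missing with reason `"omitted"` and carry no change value.
#' @return A tibble (class `residue_profile`) with columns `residue`,
#'   `intensity_unbound`, `intensity_bound` (normalized), `percent_change`
#'   (fraction, 0-1 scale), `missing`, `missing_reason`.
#' @examples
#' sim <- gen_nmr_titration(seed = 1)
#' prof <- intensity_change(sim$apo, sim$bound, window = 204:283)
#' head(prof)
#' @export
intensity_change <- function(apo, bound,
                             normalization = c("least_changed", "total",
                                               "max"),
                             window = NULL) {
  normalization <- match.arg(normalization)
  for (tab in list(apo, bound)) {
    if (!all(c("residue", "intensity") %in% names(tab))) {
      stop("peak tables need columns residue, intensity", call. = FALSE)
    }
    if (any(tab$intensity < 0)) {
      stop("peak intensities must be non-negative", call. = FALSE)
    }
  }
  shared <- intersect(apo$residue, bound$residue)
  if (length(shared) < 10) {
    stop("need at least 10 residues common to apo and bound tables (got ",
         length(shared), ")", call. = FALSE)
  }
  ia <- apo$intensity[match(shared, apo$residue)]
  ib <- bound$intensity[match(shared, bound$residue)]

  scales <- switch(normalization,
    total = c(sum(ia), sum(ib)),
    max = c(max(ia), max(ib)),
    least_changed = {
      # provisional total-scaled ratio picks the reference residues
      ratio0 <- (ib / sum(ib)) / (ia / sum(ia))
      k <- max(2L, ceiling(0.2 * length(shared)))
      ref <- order(abs(1 - ratio0))[seq_len(k)]
      c(stats::median(ia[ref]), stats::median(ib[ref]))
    })
  if (any(scales == 0)) {
    stop("normalization statistic is zero; cannot scale dataset",
         call. = FALSE)
  }

  if (is.null(window)) {
    window <- seq(min(apo$residue, bound$residue),
                  max(apo$residue, bound$residue))
  }
  window <- sort(unique(as.integer(window)))

  prof <- tibble::tibble(residue = window) |>
    dplyr::left_join(
      tibble::tibble(residue = shared,
                     intensity_unbound = ia / scales[1],
                     intensity_bound = ib / scales[2]),
      by = "residue") |>
    dplyr::mutate(
      percent_change = 1 - .data$intensity_bound / .data$intensity_unbound,
      missing = is.na(.data$percent_change),
      missing_reason = dplyr::if_else(.data$missing, "omitted",
                                      NA_character_)
    )
  class(prof) <- c("residue_profile", class(prof))
  prof
}

#' Threshold binning schemes for intensity changes
#'
#' A bin scheme is an ordered partition of the percent-change scale
#' (0-100) into lower-exclusive/upper-inclusive intervals, each with a
#' label and a color rank (rank 1 = lightest = greatest change, following
#' the convention that the strongest attenuation is drawn lightest on a
#' dark structure surface). The lowest bin is a catch-all down to -Inf.
#'
#' Two schemes are built in:
#' \describe{
#'   \item{`sbm1_4bin`}{Four bins: >90 (lightest), 80 to 90, 70 to 80,
#'     <70 (darkest).}
#'   \item{`sbm2_3bin`}{Three bins: >70 (lightest), 40 to 70, <40
#'     (darkest), suited to a weaker-binding titration with smaller
#'     attenuations.}
#' }
#'
#' @param name Name of a built-in scheme, or `"custom"` with explicit
#'   `breaks`.
#' @param breaks For a custom scheme: ascending numeric vector of interior
#'   bin boundaries on the percent (0-100) scale.
#' @return A tibble (class `bin_scheme`) with columns `lower`, `upper`,
#'   `label`, `rank` ordered darkest to lightest by rank descending.
#' @examples
#' bin_scheme("sbm1_4bin")
#' bin_scheme("custom", breaks = c(50, 75))
#' @export
bin_scheme <- function(name = c("sbm1_4bin", "sbm2_3bin", "custom"),
                       breaks = NULL) {
  name <- match.arg(name)
  if (name != "custom") {
    breaks <- switch(name, sbm1_4bin = c(70, 80, 90), sbm2_3bin = c(40, 70))
  } else if (is.null(breaks) || is.unsorted(breaks, strictly = TRUE)) {
    stop("custom scheme needs strictly ascending breaks", call. = FALSE)
  }
  lower <- c(-Inf, breaks)
  upper <- c(breaks, Inf)
  k <- length(lower)
  label <- character(k)
  label[1] <- paste0("<", breaks[1])
  label[k] <- paste0(">", breaks[length(breaks)])
  if (k > 2) {
    label[2:(k - 1)] <- paste(breaks[-length(breaks)], "to", breaks[-1])
  }
  out <- tibble::tibble(lower = lower, upper = upper, label = label,
                        rank = rev(seq_len(k)))  # rank 1 = lightest bin
  structure(out, class = c("bin_scheme", class(out)), scheme_name = name)
}

#' @rdname bin_scheme
#' @export
bin_schemes <- function() c("sbm1_4bin", "sbm2_3bin")

#' Bin per-residue intensity changes
#'
#' Assigns every residue of a profile to exactly one bin of a threshold
#' scheme (intervals are lower-exclusive/upper-inclusive on the percent
#' scale). Residues with missing data (peak overlap, unassigned, omitted)
#' are placed in the darkest catch-all bin, the same convention used when
#' coloring structure surfaces: absence of evidence is drawn as absence of
#' perturbation.
#'
#' @param profile A `residue_profile` from [intensity_change()].
#' @param scheme A `bin_scheme` or the name of a built-in scheme.
#' @return The profile with added columns `bin` (label) and `bin_rank`.
#' @examples
#' sim <- gen_nmr_titration(seed = 1)
#' prof <- intensity_change(sim$apo, sim$bound, window = 204:283)
#' binned <- bin_changes(prof, "sbm1_4bin")
#' table(binned$bin)
#' @export
bin_changes <- function(profile, scheme = "sbm1_4bin") {
  if (is.character(scheme)) scheme <- bin_scheme(scheme)
  stopifnot(inherits(scheme, "bin_scheme"))
  pct <- profile$percent_change * 100
  idx <- vapply(pct, function(p) {
    if (is.na(p)) return(NA_integer_)
    which(p > scheme$lower & p <= scheme$upper)[1]
  }, integer(1))
  darkest <- which.max(scheme$rank)
  idx[is.na(idx)] <- darkest
  profile$bin <- scheme$label[idx]
  profile$bin_rank <- scheme$rank[idx]
  attr(profile, "bin_scheme") <- attr(scheme, "scheme_name")
  profile
}

#' Detect contiguous binding regions in an intensity-change profile
#'
#' Finds maximal runs of residues whose intensity change meets a threshold,
#' the footprint of a short linear binding motif in a disordered region.
#' Runs may contain up to `max_gap` consecutive interior residues that are
#' below threshold or missing (peak overlap routinely punches single-residue
#' holes in real profiles) and must span at least `min_run` residues.
#' Region boundaries are always above-threshold residues.
#'
#' @param profile A `residue_profile` from [intensity_change()].
#' @param change_threshold Minimum percent change (fraction scale, 0-1) for
#'   a residue to count as perturbed.
#' @param min_run Minimum region span (residues, inclusive of gaps).
#' @param max_gap Maximum number of consecutive interior below-threshold or
#'   missing residues tolerated inside a region.
#' @return A tibble with columns `start_residue`, `end_residue` (inclusive),
#'   `n_scored` (above-threshold residues in the region), and
#'   `mean_percent_change` (over non-missing residues in the span), sorted
#'   by start. Zero rows when nothing qualifies.
#' @examples
#' sim <- gen_nmr_titration(seed = 1)
#' prof <- intensity_change(sim$apo, sim$bound, window = 204:283)
#' detect_binding_regions(prof)
#' @export
detect_binding_regions <- function(profile, change_threshold = 0.5,
                                   min_run = 4L, max_gap = 1L) {
  stopifnot(nrow(profile) > 0, min_run >= 1, max_gap >= 0)
  qual <- profile$residue[!profile$missing &
                            !is.na(profile$percent_change) &
                            profile$percent_change >= change_threshold]
  if (length(qual) == 0) {
    return(tibble::tibble(start_residue = integer(), end_residue = integer(),
                          n_scored = integer(),
                          mean_percent_change = numeric()))
  }
  qual <- sort(qual)
  new_region <- c(TRUE, diff(qual) > max_gap + 1L)
  grp <- cumsum(new_region)
  out <- tibble::tibble(residue = qual, grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(start_residue = min(.data$residue),
                     end_residue = max(.data$residue),
                     n_scored = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$end_residue - .data$start_residue + 1L >= min_run) |>
    dplyr::select(-"grp")
  out$mean_percent_change <- purrr::map2_dbl(
    out$start_residue, out$end_residue,
    function(s, e) {
      v <- profile$percent_change[profile$residue >= s &
                                    profile$residue <= e]
      mean(v, na.rm = TRUE)
    })
  dplyr::arrange(out, .data$start_residue)
}

#' Export structure-coloring attributes
#'
#' Writes a deterministic tab-separated attribute file mapping residue
#' numbers (native protein frame) to bin ranks, with the bin legend in
#' comment lines, for coloring molecular surfaces in a structure viewer.
#' Byte-identical output for identical input.
#'
#' @param binned A binned profile from [bin_changes()].
#' @param path Output file path.
#' @param chain_id Chain identifier recorded in the header.
#' @return `path`, invisibly.
#' @seealso [read_attributes()] for the exact inverse.
#' @export
export_attributes <- function(binned, path, chain_id = "A") {
  stopifnot(all(c("residue", "bin", "bin_rank") %in% names(binned)))
  legend <- binned |>
    dplyr::distinct(.data$bin_rank, .data$bin) |>
    dplyr::arrange(.data$bin_rank)
  lines <- c(
    "# per-residue intensity-change bins (rank 1 = lightest = largest change)",
    paste0("# chain\t", chain_id),
    sprintf("# rank %d\t%s", legend$bin_rank, legend$bin),
    "residue\tbin_rank\tbin"
  )
  if (nrow(binned) == 0) {
    warning("no binned residues; writing header-only attribute file",
            call. = FALSE)
  }
  dat <- dplyr::arrange(binned, .data$residue)
  lines <- c(lines,
             sprintf("%d\t%d\t%s", dat$residue, dat$bin_rank, dat$bin))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_attributes
#' @return `read_attributes()` returns a tibble with columns `residue`,
#'   `bin_rank`, `bin`.
#' @export
read_attributes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0 || lines[1] != "residue\tbin_rank\tbin") {
    stop("not an attribute file: ", path, call. = FALSE)
  }
  lines <- lines[-1]
  if (length(lines) == 0) {
    return(tibble::tibble(residue = integer(), bin_rank = integer(),
                          bin = character()))
  }
  parts <- stringr::str_split_fixed(lines, "\t", 3)
  tibble::tibble(residue = as.integer(parts[, 1]),
                 bin_rank = as.integer(parts[, 2]),
                 bin = parts[, 3])
}
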