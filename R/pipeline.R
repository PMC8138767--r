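#' Pipeline entry points: file in, report files out
#'
#' The `run_*` functions bind the analysis stages into a reproducible
#' file-based pipeline: each reads the documented CSV dialects, runs the
#' corresponding analysis, writes a JSON report plus human-readable text
#' (and stage-specific tables), and emits a run manifest recording the
#' configuration snapshot, input file digests, seed (where randomness is
#' involved), and package version, so a run can be reproduced exactly.
#' Reports contain no timestamps: identical inputs give byte-identical
#' outputs. A thin command-line dispatcher over these functions ships in
#' `inst/cli/spopbind.R`
#' (`Rscript spopbind.R simulate|fit-direct|fit-compete|nmr-map|cells ...`).
#'
#' @param csv_path Input titration CSV (see [read_titration()]).
#' @param out_prefix Path prefix for output files; `<prefix>.json`,
#'   `<prefix>.txt` and `<prefix>_manifest.json` are written.
#' @param probe_total Total probe concentration, molar.
#' @param g,fit_g Intensity-ratio handling, as in [fit_direct()].
#' @return The fitted `affinity_fit`, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_fit_direct <- function(csv_path, out_prefix, probe_total = 4e-8,
                           g = 1, fit_g = FALSE) {
  data <- read_titration(csv_path)
  fit <- fit_direct(data, probe_total = probe_total, g = g, fit_g = fit_g)
  write_fit_report(fit, out_prefix)
  write_manifest(out_prefix,
                 stage = "fit-direct",
                 config = list(probe_total = probe_total, g = g,
                               fit_g = fit_g),
                 inputs = csv_path,
                 outputs = paste0(out_prefix, c(".json", ".txt")))
  invisible(fit)
}

#' @rdname pipeline
#' @param probe_kd Probe dissociation constant, molar; must be positive.
#' @param receptor_total Total receptor concentration, molar.
#' @export
run_fit_compete <- function(csv_path, out_prefix, probe_kd = 2.6e-6,
                            probe_total = 4e-8, receptor_total = 6e-6,
                            g = 1, fit_g = FALSE) {
  if (probe_kd <= 0) stop("probe_kd must be positive", call. = FALSE)
  message(sprintf(
    "fit-compete: probe_total = %.3g M, receptor_total = %.3g M, probe_kd = %.3g M",
    probe_total, receptor_total, probe_kd))
  data <- read_titration(csv_path)
  fit <- fit_competition(data, probe_kd = probe_kd,
                         probe_total = probe_total,
                         receptor_total = receptor_total,
                         g = g, fit_g = fit_g)
  write_fit_report(fit, out_prefix)
  write_manifest(out_prefix,
                 stage = "fit-compete",
                 config = list(probe_kd = probe_kd,
                               probe_total = probe_total,
                               receptor_total = receptor_total,
                               g = g, fit_g = fit_g),
                 inputs = csv_path,
                 outputs = paste0(out_prefix, c(".json", ".txt")))
  invisible(fit)
}

#' @rdname pipeline
#' @param apo_path,bound_path Peak-list files (see [read_peak_list()]).
#' @param scheme Name of a built-in bin scheme; see [bin_schemes()].
#' @param dialect Peak-list dialect, or `NULL` to auto-detect.
#' @param window Residue window for the profile; `NULL` uses the observed
#'   span.
#' @param change_threshold,min_run,max_gap Region-detection parameters,
#'   as in [detect_binding_regions()].
#' @export
run_nmr_map <- function(apo_path, bound_path, out_prefix,
                        scheme = "sbm1_4bin", dialect = NULL,
                        window = NULL, change_threshold = 0.5,
                        min_run = 4L, max_gap = 1L) {
  if (!scheme %in% bin_schemes()) {
    stop("unknown bin scheme '", scheme, "'; available: ",
         paste(bin_schemes(), collapse = ", "), call. = FALSE)
  }
  apo <- read_peak_list(apo_path, dialect)
  bound <- read_peak_list(bound_path, dialect)
  prof <- intensity_change(apo, bound, window = window)
  binned <- bin_changes(prof, scheme)
  regions <- detect_binding_regions(prof,
                                    change_threshold = change_threshold,
                                    min_run = min_run, max_gap = max_gap)
  write_profile(binned, paste0(out_prefix, "_profile.csv"))
  export_attributes(binned, paste0(out_prefix, "_attributes.tsv"))
  readr::write_csv(regions, paste0(out_prefix, "_regions.csv"))
  if (nrow(regions)) {
    message("binding regions (inclusive): ",
            paste(sprintf("%d-%d", regions$start_residue,
                          regions$end_residue), collapse = ", "))
  } else {
    message("no binding regions detected")
  }
  write_manifest(out_prefix,
                 stage = "nmr-map",
                 config = list(scheme = scheme, window = window,
                               change_threshold = change_threshold,
                               min_run = min_run, max_gap = max_gap),
                 inputs = c(apo_path, bound_path),
                 outputs = paste0(out_prefix,
                                  c("_profile.csv", "_attributes.tsv",
                                    "_regions.csv")))
  invisible(list(profile = binned, regions = regions))
}

#' @rdname pipeline
#' @param variant Variant label to analyze; must exist in the table.
#' @export
run_cells <- function(csv_path, out_prefix, variant = NULL) {
  records <- read_cell_table(csv_path)
  if (!is.null(variant) && !variant %in% records$variant) {
    stop("unknown variant '", variant, "'; table has: ",
         paste(unique(records$variant), collapse = ", "), call. = FALSE)
  }
  summary <- summarize_by_class(records, variant)
  cmp <- compare_classes(records, variant)
  report <- list(
    variant = variant,
    n_per_class = stats::setNames(as.list(summary$n), summary$spop_class),
    class_summary = dplyr::select(summary, -"replicate_counts"),
    replicate_counts = stats::setNames(
      purrr::map(summary$replicate_counts, ~ as.list(
        stats::setNames(.x$n, .x$replicate))),
      summary$spop_class),
    comparison = unclass_comparison(cmp)
  )
  jsonlite::write_json(report, paste0(out_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, na = "null")
  readr::write_csv(dplyr::select(summary, -"replicate_counts"),
                   paste0(out_prefix, "_violin.csv"))
  write_manifest(out_prefix,
                 stage = "cells",
                 config = list(variant = variant),
                 inputs = csv_path,
                 outputs = paste0(out_prefix, c(".json", "_violin.csv")))
  invisible(cmp)
}

#' @rdname pipeline
#' @param kind Which generator to run: `"direct"`, `"competition"`,
#'   `"nmr"`, or `"cells"`.
#' @param out_dir Directory to write the simulated input files into.
#' @param seed Integer random seed (required).
#' @param ... Passed to the corresponding generator.
#' @export
run_simulate <- function(kind = c("competition", "direct", "nmr", "cells"),
                         out_dir, seed, ...) {
  kind <- match.arg(kind)
  check_seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- switch(kind,
    direct = {
      sim <- gen_direct_titration(seed = seed, ...)
      write_titration(sim, file.path(out_dir, "direct_titration.csv"))
    },
    competition = {
      sim <- gen_competition_titration(seed = seed, ...)
      write_titration(sim, file.path(out_dir, "competition_titration.csv"))
    },
    nmr = {
      sim <- gen_nmr_titration(seed = seed, ...)
      a <- file.path(out_dir, "apo_peaks.csv")
      b <- file.path(out_dir, "bound_peaks.csv")
      readr::write_csv(sim$apo, a)
      readr::write_csv(sim$bound, b)
      c(a, b)
    },
    cells = {
      sim <- gen_cell_table(seed = seed, ...)
      write_cell_table(sim, file.path(out_dir, "cells.csv"))
    })
  write_manifest(file.path(out_dir, paste0("simulate_", kind)),
                 stage = paste0("simulate-", kind),
                 config = list(kind = kind, args = list(...)),
                 inputs = character(0), outputs = outputs, seed = seed)
  invisible(outputs)
}

# JSON + text fit report; lower-bound results render as "K_D > value"
write_fit_report <- function(fit, out_prefix) {
  report <- list(
    mode = fit$mode,
    kd_mean = fit$kd_mean,
    kd_sem = fit$kd_sem,
    kd_display = format_kd(fit),
    status = fit$status,
    per_replicate = fit$per_replicate,
    endpoints = fit$endpoints,
    fixed = fit$fixed,
    residual_rms = fit$residual_rms,
    converged = fit$converged,
    note = paste("uncertainty in any fixed probe K_D is not propagated",
                 "into the competitor K_D")
  )
  jsonlite::write_json(report, paste0(out_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, na = "null")
  txt <- c(
    sprintf("Anisotropy titration fit (%s mode)", fit$mode),
    format_kd(fit),
    sprintf("status: %s", fit$status),
    sprintf("replicates converged: %d/%d",
            sum(fit$per_replicate$converged), nrow(fit$per_replicate)),
    sprintf("per-replicate K_D (M): %s",
            paste(sprintf("%.6g", fit$per_replicate$kd), collapse = ", ")),
    sprintf("endpoints: r_free = %.6g, r_bound = %.6g, g = %.6g",
            fit$endpoints$r_free, fit$endpoints$r_bound, fit$endpoints$g),
    sprintf("residual RMS: %.6g", fit$residual_rms)
  )
  writeLines(txt, paste0(out_prefix, ".txt"))
  invisible(out_prefix)
}

unclass_comparison <- function(cmp) {
  cmp <- unclass(cmp)
  cmp[!purrr::map_lgl(cmp, is.function)]
}

# run manifest: config snapshot, input digests, seed, package version.
# deliberately timestamp-free so reruns are byte-identical.
write_manifest <- function(out_prefix, stage, config, inputs, outputs,
                           seed = NULL) {
  manifest <- list(
    stage = stage,
    package = "spopbind",
    version = as.character(utils::packageVersion("spopbind")),
    seed = seed,
    config = config,
    input_digests = if (length(inputs)) {
      as.list(stats::setNames(unname(tools::md5sum(inputs)),
                              basename(inputs)))
    } else list(),
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, paste0(out_prefix, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_prefix)
}
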