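#' Read and validate a per-cell measurement table
#'
#' Loads the per-cell CSV dialect: one row per analyzed cell with the mean
#' nuclear GFP intensity (grayscale units averaged over the DAPI-designated
#' nuclear area) and the binary SPOP localization class. Cells showing both
#' diffuse and punctate signal are conventionally binned as `"speckled"`
#' upstream, so the class here is strictly binary.
#'
#' @param path CSV with columns
#'   `cell_id,replicate,variant,mean_gfp_intensity,spop_class`.
#' @return A validated tibble.
#' @export
read_cell_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  validate_cell_table(tab)
}

#' @rdname read_cell_table
#' @param records A per-cell data frame to write.
#' @export
write_cell_table <- function(records, path) {
  readr::write_csv(validate_cell_table(records), path)
  invisible(path)
}

validate_cell_table <- function(tab) {
  need <- c("cell_id", "replicate", "variant", "mean_gfp_intensity",
            "spop_class")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("cell table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(tab$spop_class), c("diffuse", "speckled"))
  if (length(bad)) {
    stop("spop_class must be 'diffuse' or 'speckled'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(tab$mean_gfp_intensity < 0)) {
    stop("mean_gfp_intensity must be non-negative", call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' Summarize per-cell intensities by localization class
#'
#' Violin-ready distribution summary of per-cell substrate expression split
#' by SPOP localization class: n, mean, sd, min, max and quartiles per
#' class, with per-replicate provenance counts carried alongside so the
#' contribution of each biological replicate is visible. Cells are the unit
#' of analysis (replicates are pooled).
#'
#' @param records Per-cell tibble (see [read_cell_table()] for columns).
#' @param variant If given, restrict to this variant label first.
#' @return A tibble with one row per localization class present, including
#'   a `replicate_counts` list-column of per-replicate cell counts. If only
#'   one class is present the single-row summary carries attribute
#'   `absent_class` naming the missing one.
#' @examples
#' cells <- gen_cell_table(seed = 1, n_cells = 60)
#' summarize_by_class(cells)
#' @export
summarize_by_class <- function(records, variant = NULL) {
  records <- validate_cell_table(records)
  if (!is.null(variant)) {
    records <- dplyr::filter(records, .data$variant == !!variant)
  }
  if (nrow(records) == 0) {
    stop("no cell records", if (!is.null(variant))
      paste0(" for variant '", variant, "'") else "", call. = FALSE)
  }
  out <- records |>
    dplyr::group_by(.data$spop_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$mean_gfp_intensity),
      sd = stats::sd(.data$mean_gfp_intensity),
      min = min(.data$mean_gfp_intensity),
      max = max(.data$mean_gfp_intensity),
      q25 = stats::quantile(.data$mean_gfp_intensity, 0.25, names = FALSE),
      median = stats::median(.data$mean_gfp_intensity),
      q75 = stats::quantile(.data$mean_gfp_intensity, 0.75, names = FALSE),
      n_replicates = dplyr::n_distinct(.data$replicate),
      replicate_counts = list(
        dplyr::count(dplyr::pick(dplyr::everything()), .data$replicate)),
      .groups = "drop"
    )
  absent <- setdiff(c("diffuse", "speckled"), out$spop_class)
  if (length(absent)) attr(out, "absent_class") <- absent
  out
}

#' Two-group test of expression difference between localization classes
#'
#' Two-tailed two-sample t test of per-cell mean nuclear GFP intensity,
#' diffuse versus speckled SPOP localization. Pooled-variance (Student's)
#' by default; Welch available via `var_equal = FALSE`. The t statistic's
#' sign follows (diffuse mean - speckled mean). When either class has
#' fewer than 2 cells or the pooled variance is zero the comparison is
#' returned as not-applicable rather than an error, mirroring the fact
#' that the test is only meaningful for variants producing two distinct
#' localization patterns.
#'
#' @inheritParams summarize_by_class
#' @param var_equal Pool variances (Student's t, default) or not (Welch).
#' @return An object of class `class_comparison` with [tidy()] and
#'   [glance()] methods.
#' @examples
#' cells <- gen_cell_table(seed = 1, n_cells = 80, slope = 3)
#' compare_classes(cells)
#' @export
compare_classes <- function(records, variant = NULL, var_equal = TRUE) {
  records <- validate_cell_table(records)
  if (!is.null(variant)) {
    records <- dplyr::filter(records, .data$variant == !!variant)
  }
  x <- records$mean_gfp_intensity[records$spop_class == "diffuse"]
  y <- records$mean_gfp_intensity[records$spop_class == "speckled"]

  na_result <- function(reason) {
    structure(list(applicable = FALSE, reason = reason,
                   variant = variant, n_diffuse = length(x),
                   n_speckled = length(y), estimate = NA_real_,
                   t_statistic = NA_real_, df = NA_real_,
                   p_value = NA_real_,
                   method = if (var_equal) "student" else "welch"),
              class = "class_comparison")
  }
  if (length(x) < 2 || length(y) < 2) {
    return(na_result("need at least 2 cells in each localization class"))
  }
  pooled_var <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2)
  if (pooled_var == 0) {
    return(na_result("zero variance in intensities"))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal,
                      alternative = "two.sided")
  structure(list(
    applicable = TRUE, reason = NA_character_, variant = variant,
    n_diffuse = length(x), n_speckled = length(y),
    estimate = mean(x) - mean(y),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    method = if (var_equal) "student" else "welch"
  ), class = "class_comparison")
}

#' @export
print.class_comparison <- function(x, ...) {
  cat("Diffuse vs speckled SPOP localization: GFP intensity comparison\n")
  if (!is.null(x$variant)) cat("  variant:", x$variant, "\n")
  cat(sprintf("  n: %d diffuse, %d speckled\n", x$n_diffuse, x$n_speckled))
  if (!x$applicable) {
    cat("  test not applicable:", x$reason, "\n")
  } else {
    cat(sprintf("  %s t = %.4f, df = %.4g, two-tailed p = %.4g\n",
                if (x$method == "student") "Student's" else "Welch",
                x$t_statistic, x$df, x$p_value))
    cat(sprintf("  mean difference (diffuse - speckled): %.4g\n",
                x$estimate))
  }
  invisible(x)
}

#' @rdname compare_classes
#' @param x A `class_comparison` object.
#' @param ... Unused.
#' @export
tidy.class_comparison <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate,
    t_statistic = x$t_statistic,
    df = x$df,
    p_value = x$p_value,
    method = x$method,
    applicable = x$applicable
  )
}

#' @rdname compare_classes
#' @export
glance.class_comparison <- function(x, ...) {
  tibble::tibble(
    variant = x$variant %||% NA_character_,
    n_diffuse = x$n_diffuse,
    n_speckled = x$n_speckled,
    t_statistic = x$t_statistic,
    df = x$df,
    p_value = x$p_value,
    applicable = x$applicable,
    reason = x$reason
  )
}
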