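#' Fit a direct anisotropy titration
#'
#' Least-squares estimation of the probe dissociation constant from a
#' direct-mode fluorescence anisotropy titration: receptor is titrated into
#' a fixed trace of labeled probe, and anisotropy rises as probe is bound.
#' The model is [predict_anisotropy()] applied to the ligand-depletion
#' isotherm [direct_fraction_bound()]. Each replicate is fitted separately
#' over (log10 K_D, r_free, r_bound, and optionally g); per-replicate
#' estimates are then aggregated to a mean and standard error of the mean.
#'
#' Initialization scans a log-spaced K_D grid, solving the endpoints by
#' linear least squares at each grid point, and refines from the best grid
#' point with Levenberg-Marquardt. Replicates that fail to converge are
#' excluded from aggregation with a warning. Residuals are unweighted.
#'
#' @param data A data frame with columns `titrant_conc` (total receptor,
#'   molar), `anisotropy`, and optionally `replicate`. Use
#'   [read_titration()] to load the CSV dialect with explicit units.
#' @param probe_total Total probe concentration, molar.
#' @param g Bound/free fluorescence intensity ratio; fixed at this value
#'   unless `fit_g = TRUE`.
#' @param fit_g If `TRUE`, fit g as a free parameter (default fixed at
#'   `g = 1`, i.e. pure anisotropy mixing).
#' @param endpoints Optional numeric vector `c(r_free, r_bound)` to fix the
#'   endpoint anisotropies (e.g. from control wells) instead of fitting
#'   them.
#' @param saturation_threshold Fraction of the fitted dynamic range that
#'   must be reached at the highest titrant concentration for the estimate
#'   to be reported as a point estimate; see [classify_bound_estimate()].
#' @return An object of class `affinity_fit`; see [tidy.affinity_fit()] and
#'   [glance.affinity_fit()] for tabular views.
#' @examples
#' sim <- gen_direct_titration(kd = 2.6e-6, seed = 1, noise_sd = 0)
#' fit <- fit_direct(sim, probe_total = 4e-8)
#' glance(fit)
#' @export
fit_direct <- function(data, probe_total, g = 1, fit_g = FALSE,
                       endpoints = NULL, saturation_threshold = 0.8) {
  stopifnot(probe_total > 0, g > 0)
  data <- validate_titration(data, mode = "direct")
  model_fb <- function(conc, kd) {
    direct_fraction_bound(probe_total, conc, kd)
  }
  fit_titration(data, model_fb,
                mode = "direct", g = g, fit_g = fit_g,
                endpoints = endpoints,
                fixed = list(probe_total = probe_total),
                saturation_threshold = saturation_threshold)
}

#' Fit a competition anisotropy titration
#'
#' Estimates the competitor dissociation constant K_B from a
#' competition-mode titration: unlabeled competitor is titrated into a
#' fixed mixture of labeled probe and receptor, displacing the probe and
#' lowering anisotropy. The model is [predict_anisotropy()] applied to
#' [competitive_fraction_bound()], the exact (cubic) solution of the
#' complete competitive binding equilibrium -- no excess-ligand or
#' IC50-to-Ki approximation. The probe parameters `probe_kd`, `probe_total`
#' and `receptor_total` are fixed from the direct experiment.
#'
#' K_B is optimized in log10 space with grid-search initialization over
#' `[1e-9, 1e-1]` M, because competitor affinities in these assays span
#' many orders of magnitude. After fitting, the result is classified as a
#' point estimate or a lower bound via [classify_bound_estimate()]: a
#' titration whose model-predicted displacement at the highest competitor
#' concentration falls short of saturation (e.g. solubility-limited
#' competitors) only supports "K_D > value".
#'
#' @param data A data frame with columns `titrant_conc` (total competitor,
#'   molar), `anisotropy`, and optionally `replicate`.
#' @param probe_kd Probe dissociation constant, molar (from the direct
#'   fit).
#' @param probe_total,receptor_total Fixed total concentrations, molar.
#' @inheritParams fit_direct
#' @return An object of class `affinity_fit`.
#' @examples
#' sim <- gen_competition_titration(kb = 1.4e-4, seed = 1, noise_sd = 0)
#' fit <- fit_competition(sim, probe_kd = 2.6e-6, probe_total = 4e-8,
#'                        receptor_total = 6e-6)
#' glance(fit)
#' @export
fit_competition <- function(data, probe_kd, probe_total, receptor_total,
                            g = 1, fit_g = FALSE, endpoints = NULL,
                            saturation_threshold = 0.8) {
  stopifnot(probe_kd > 0, probe_total > 0, receptor_total > 0, g > 0)
  data <- validate_titration(data, mode = "competition")
  model_fb <- function(conc, kd) {
    competitive_fraction_bound(receptor_total, probe_total, conc,
                               probe_kd, kd)
  }
  fit_titration(data, model_fb,
                mode = "competition", g = g, fit_g = fit_g,
                endpoints = endpoints,
                fixed = list(probe_kd = probe_kd,
                             probe_total = probe_total,
                             receptor_total = receptor_total),
                saturation_threshold = saturation_threshold)
}

# bounds of the log10-K grid search / optimizer
.lk_bounds <- c(-9, -1)

# shared per-replicate fitting engine for both modes.
# model_fb(conc, kd) must return fraction bound.
fit_titration <- function(data, model_fb, mode, g, fit_g, endpoints,
                          fixed, saturation_threshold) {
  fit_endpoints_free <- is.null(endpoints)
  if (!fit_endpoints_free) {
    stopifnot(length(endpoints) == 2, endpoints[1] != endpoints[2])
  }

  predict_r <- function(conc, lk, r_free, r_bound, gg) {
    predict_anisotropy(model_fb(conc, 10^lk), r_free, r_bound, gg)
  }

  one_replicate <- function(df) {
    conc <- df$titrant_conc
    y <- df$anisotropy
    if (length(unique(y)) == 1L) {
      stop("anisotropy series is flat; K_D is not identifiable",
           call. = FALSE)
    }
    # grid search: for each candidate K, endpoints by linear least squares
    lk_grid <- seq(.lk_bounds[1], .lk_bounds[2], by = 0.25)
    grid <- purrr::map(lk_grid, function(lk) {
      fb <- model_fb(conc, 10^lk)
      w <- g * fb / ((1 - fb) + g * fb)  # weight of bound endpoint
      if (fit_endpoints_free) {
        X <- cbind(1 - w, w)
        cf <- tryCatch(stats::lm.fit(X, y)$coefficients,
                       error = function(e) c(NA_real_, NA_real_))
        if (anyNA(cf)) return(list(ss = Inf))
        pred <- X %*% cf
        list(ss = sum((y - pred)^2), r_free = cf[1], r_bound = cf[2])
      } else {
        pred <- endpoints[1] * (1 - w) + endpoints[2] * w
        list(ss = sum((y - pred)^2),
             r_free = endpoints[1], r_bound = endpoints[2])
      }
    })
    best <- grid[[which.min(purrr::map_dbl(grid, "ss"))]]
    lk0 <- lk_grid[which.min(purrr::map_dbl(grid, "ss"))]

    start <- list(lk = lk0)
    lower <- c(lk = .lk_bounds[1])
    upper <- c(lk = .lk_bounds[2])
    if (fit_endpoints_free) {
      start$r_free <- unname(best$r_free)
      start$r_bound <- unname(best$r_bound)
      lower <- c(lower, r_free = -Inf, r_bound = -Inf)
      upper <- c(upper, r_free = Inf, r_bound = Inf)
    }
    if (fit_g) {
      start$lg <- log10(g)
      lower <- c(lower, lg = -3)
      upper <- c(upper, lg = 3)
    }

    form <- if (fit_endpoints_free && fit_g) {
      y ~ predict_r(conc, lk, r_free, r_bound, 10^lg)
    } else if (fit_endpoints_free) {
      y ~ predict_r(conc, lk, r_free, r_bound, g)
    } else if (fit_g) {
      y ~ predict_r(conc, lk, endpoints[1], endpoints[2], 10^lg)
    } else {
      y ~ predict_r(conc, lk, endpoints[1], endpoints[2], g)
    }

    fit <- tryCatch(
      minpack.lm::nlsLM(form, start = start, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(list(converged = FALSE, message = conditionMessage(fit)))
    }
    cf <- stats::coef(fit)
    pinned <- cf[["lk"]] <= .lk_bounds[1] + 1e-6 ||
      cf[["lk"]] >= .lk_bounds[2] - 1e-6
    list(
      converged = !pinned,
      pinned = pinned,
      kd = 10^cf[["lk"]],
      r_free = if (fit_endpoints_free) cf[["r_free"]] else endpoints[1],
      r_bound = if (fit_endpoints_free) cf[["r_bound"]] else endpoints[2],
      g = if (fit_g) 10^cf[["lg"]] else g,
      rss = sum(stats::resid(fit)^2),
      n = length(y)
    )
  }

  reps <- split(data, data$replicate)
  res <- purrr::map(reps, one_replicate)
  per_rep <- tibble::tibble(
    replicate = names(reps),
    kd = purrr::map_dbl(res, ~ .x$kd %||% NA_real_),
    r_free = purrr::map_dbl(res, ~ .x$r_free %||% NA_real_),
    r_bound = purrr::map_dbl(res, ~ .x$r_bound %||% NA_real_),
    g = purrr::map_dbl(res, ~ .x$g %||% NA_real_),
    rss = purrr::map_dbl(res, ~ .x$rss %||% NA_real_),
    n = purrr::map_int(res, ~ as.integer(.x$n %||% NA_integer_)),
    converged = purrr::map_lgl(res, "converged")
  )
  ok <- per_rep$converged
  if (!any(ok)) {
    # K pinned at bounds in every replicate: the estimate is only a bound,
    # but the fitted values still parameterize the classification below
    ok <- !is.na(per_rep$kd)
    if (!any(ok)) {
      stop("no replicate fit converged; check the titration design",
           call. = FALSE)
    }
    warning("K pinned at optimizer bounds in all replicates; ",
            "result is a bound, not a point estimate", call. = FALSE)
  } else if (any(!ok)) {
    warning(sum(!ok), " replicate(s) excluded from aggregation ",
            "(non-convergence or K pinned at optimizer bounds)",
            call. = FALSE)
  }
  agg <- aggregate_replicates(per_rep$kd[ok], warn_singleton = FALSE)

  out <- structure(
    list(
      mode = mode,
      kd_mean = agg$mean,
      kd_sem = agg$sem,
      per_replicate = per_rep,
      endpoints = list(r_free = mean(per_rep$r_free[ok]),
                       r_bound = mean(per_rep$r_bound[ok]),
                       g = mean(per_rep$g[ok])),
      fixed = fixed,
      residual_rms = sqrt(sum(per_rep$rss[ok]) / sum(per_rep$n[ok])),
      converged = all(ok),
      any_pinned = any(purrr::map_lgl(res, ~ isTRUE(.x$pinned))),
      max_titrant = max(data$titrant_conc),
      model_fb = model_fb,
      data = data,
      status = NA_character_
    ),
    class = "affinity_fit"
  )
  out$status <- classify_bound_estimate(
    out, saturation_threshold = saturation_threshold)
  out
}

#' Aggregate per-replicate dissociation constants
#'
#' Mean and standard error of the mean (sample sd / sqrt(n)) across
#' replicate-level K_D estimates, the convention used to report affinities
#' from repeated titrations. A singleton yields an undefined (NA) SEM with
#' a warning.
#'
#' @param kds Numeric vector of per-replicate dissociation constants,
#'   molar. Must be non-empty.
#' @param warn_singleton Warn when `length(kds) == 1`.
#' @return A list with elements `mean`, `sem`, `n`.
#' @examples
#' aggregate_replicates(c(1.0e-4, 1.4e-4, 1.8e-4))
#' @export
aggregate_replicates <- function(kds, warn_singleton = TRUE) {
  if (length(kds) == 0) stop("no replicate estimates to aggregate",
                             call. = FALSE)
  if (anyNA(kds)) stop("replicate estimates contain NA", call. = FALSE)
  n <- length(kds)
  if (n == 1L) {
    if (warn_singleton) {
      warning("single replicate: SEM is undefined", call. = FALSE)
    }
    return(list(mean = kds, sem = NA_real_, n = 1L))
  }
  list(mean = mean(kds), sem = stats::sd(kds) / sqrt(n), n = n)
}

#' Classify a fitted K_D as point estimate or lower bound
#'
#' A titration that never approaches saturation (for instance when
#' competitor solubility caps the accessible concentration range) cannot
#' pin down K_D; only "K_D > value" is defensible. This classifier codifies
#' that judgment: the fitted model is evaluated at the highest titrant
#' concentration, and if the achieved fraction of the fitted dynamic range
#' (probe displacement for competition mode, probe saturation for direct
#' mode) is below `saturation_threshold`, or the optimizer pinned K at its
#' bounds, the result is `"lower_bound_only"`; otherwise
#' `"point_estimate"`.
#'
#' @param fit An `affinity_fit` object.
#' @param max_titrant Highest titrant concentration to evaluate at, molar;
#'   defaults to the maximum in the fitted data.
#' @param saturation_threshold Required fraction of the dynamic range at
#'   `max_titrant`, in `[0, 1]`. `0` always yields a point estimate.
#' @return `"point_estimate"` or `"lower_bound_only"`.
#' @export
classify_bound_estimate <- function(fit, max_titrant = NULL,
                                    saturation_threshold = 0.8) {
  stopifnot(inherits(fit, "affinity_fit"),
            saturation_threshold >= 0, saturation_threshold <= 1)
  if (is.null(max_titrant)) max_titrant <- fit$max_titrant
  if (isTRUE(fit$any_pinned)) return("lower_bound_only")
  kd <- fit$kd_mean
  fb_end <- fit$model_fb(max_titrant, kd)
  if (fit$mode == "competition") {
    fb0 <- fit$model_fb(0, kd)
    achieved <- if (fb0 > 0) (fb0 - fb_end) / fb0 else 1
  } else {
    achieved <- fb_end  # direct: fraction of full 0 -> 1 range reached
  }
  if (achieved < saturation_threshold) "lower_bound_only" else
    "point_estimate"
}

# titration-table validation shared by both fit modes
validate_titration <- function(data, mode) {
  if (!is.data.frame(data)) stop("data must be a data frame", call. = FALSE)
  need <- c("titrant_conc", "anisotropy")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (!"replicate" %in% names(data)) data$replicate <- "R1"
  data$replicate <- as.character(data$replicate)
  if (anyNA(data$titrant_conc) || anyNA(data$anisotropy)) {
    stop("titrant_conc and anisotropy must not contain NA", call. = FALSE)
  }
  if (any(data$titrant_conc < 0)) {
    stop("titrant concentrations must be non-negative", call. = FALSE)
  }
  n_distinct_pos <- data |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$titrant_conc),
                     pos = sum(.data$titrant_conc > 0)) |>
    dplyr::ungroup()
  if (any(n_distinct_pos$k < 5)) {
    stop("each replicate needs at least 5 distinct titrant concentrations",
         call. = FALSE)
  }
  if (mode == "competition" && any(n_distinct_pos$pos == 0)) {
    stop("competition series has zero competitor at all points; ",
         "titrant axis is degenerate", call. = FALSE)
  }
  dplyr::arrange(data, .data$replicate, .data$titrant_conc)
}

#' @export
print.affinity_fit <- function(x, ...) {
  cat(sprintf("Anisotropy titration fit (%s mode)\n", x$mode))
  cat(sprintf("  %s\n", format_kd(x)))
  cat(sprintf("  replicates: %d fitted, %d converged\n",
              nrow(x$per_replicate), sum(x$per_replicate$converged)))
  cat(sprintf("  endpoints: r_free = %.4f, r_bound = %.4f, g = %.3g\n",
              x$endpoints$r_free, x$endpoints$r_bound, x$endpoints$g))
  cat(sprintf("  residual RMS: %.2e anisotropy units\n", x$residual_rms))
  invisible(x)
}

# human-readable K_D line; lower bounds render as "K_D > value"
format_kd <- function(fit) {
  val <- fit$kd_mean * 1e6
  sem <- fit$kd_sem * 1e6
  if (identical(fit$status, "lower_bound_only")) {
    sprintf("K_D > %.3g uM (lower bound: titration not saturated)", val)
  } else if (is.na(sem)) {
    sprintf("K_D = %.3g uM", val)
  } else {
    sprintf("K_D = %.3g +/- %.3g uM (mean +/- SEM, n = %d)",
            val, sem, sum(fit$per_replicate$converged))
  }
}

#' @rdname fit_direct
#' @param x An `affinity_fit` object.
#' @param ... Unused.
#' @export
tidy.affinity_fit <- function(x, ...) {
  x$per_replicate
}

#' @rdname fit_direct
#' @export
glance.affinity_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    kd_mean = x$kd_mean,
    kd_sem = x$kd_sem,
    status = x$status,
    n_replicates = nrow(x$per_replicate),
    n_converged = sum(x$per_replicate$converged),
    r_free = x$endpoints$r_free,
    r_bound = x$endpoints$r_bound,
    g = x$endpoints$g,
    residual_rms = x$residual_rms,
    converged = x$converged
  )
}
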