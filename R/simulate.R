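#' Simulate a direct anisotropy titration
#'
#' Generates a direct-mode titration: a log-spaced series of receptor
#' concentrations added to a fixed trace of labeled probe, anisotropy from
#' the ligand-depletion isotherm plus additive Gaussian noise (the
#' instrument-like noise model for a plate-reader anisotropy channel).
#' Defaults emulate the standard design for these assays: 40 nM probe and
#' receptor spanning 0.001 to 300 uM, three technical replicates.
#'
#' All generators are fully deterministic given `seed`, which is a required
#' argument -- there is no hidden global random state. Ground truth
#' (generating parameters) is attached as the `"truth"` attribute for
#' closed-loop recovery tests.
#'
#' @param kd True probe dissociation constant, molar.
#' @param seed Integer random seed (required).
#' @param probe_total Total probe concentration, molar.
#' @param receptor_range Range of receptor concentrations, molar; points
#'   are log-spaced across it.
#' @param n_points Titration points per replicate.
#' @param n_replicates Number of technical replicates.
#' @param noise_sd Additive Gaussian anisotropy noise SD (0.005 is a
#'   plausible plate-reader figure).
#' @param r_free,r_bound,g Anisotropy endpoints and intensity ratio of the
#'   simulated probe.
#' @return A tibble with columns `titrant_conc` (molar), `conc_unit`,
#'   `anisotropy`, `replicate`; attributes `mode = "direct"` and `truth`.
#' @examples
#' gen_direct_titration(kd = 2.6e-6, seed = 1)
#' @export
gen_direct_titration <- function(kd, seed, probe_total = 4e-8,
                                 receptor_range = c(1e-9, 3e-4),
                                 n_points = 12L, n_replicates = 3L,
                                 noise_sd = 0.005, r_free = 0.08,
                                 r_bound = 0.20, g = 1) {
  stopifnot(kd > 0, probe_total > 0, length(receptor_range) == 2,
            all(receptor_range > 0), n_points >= 2, n_replicates >= 1,
            noise_sd >= 0, g > 0)
  check_seed(seed)
  conc <- exp(seq(log(receptor_range[1]), log(receptor_range[2]),
                  length.out = n_points))
  out <- with_local_seed(seed, {
    purrr::map(seq_len(n_replicates), function(i) {
      fb <- direct_fraction_bound(probe_total, conc, kd)
      r <- predict_anisotropy(fb, r_free, r_bound, g)
      tibble::tibble(titrant_conc = conc, conc_unit = "M",
                     anisotropy = r + stats::rnorm(length(r), 0, noise_sd),
                     replicate = paste0("R", i))
    }) |> dplyr::bind_rows()
  })
  structure(out, mode = "direct",
            truth = list(kd = kd, probe_total = probe_total,
                         r_free = r_free, r_bound = r_bound, g = g,
                         noise_sd = noise_sd, seed = seed))
}

#' Simulate a competition anisotropy titration
#'
#' Generates a competition-mode titration: a serial dilution of unlabeled
#' competitor added to a fixed probe/receptor mixture, with anisotropy
#' from the exact competitive-binding model plus additive Gaussian noise.
#' Defaults emulate the standard competition design: 40 nM probe, 6 uM
#' receptor, twelve 3-fold serial dilutions from 2 mM (reaching ~0.01 uM),
#' three technical replicates.
#'
#' @param kb True competitor dissociation constant, molar. A very large
#'   value (e.g. `1e3`) produces a flat mock/non-binder control series.
#' @param ka Probe dissociation constant, molar.
#' @param receptor_total Total receptor concentration, molar.
#' @param top_conc Highest competitor concentration, molar.
#' @param dilution_factor Serial dilution factor between points.
#' @inheritParams gen_direct_titration
#' @return A tibble as in [gen_direct_titration()] with
#'   `mode = "competition"`.
#' @examples
#' gen_competition_titration(kb = 1.4e-4, seed = 1)
#' @export
gen_competition_titration <- function(kb, seed, ka = 2.6e-6,
                                      probe_total = 4e-8,
                                      receptor_total = 6e-6,
                                      top_conc = 2e-3, dilution_factor = 3,
                                      n_points = 12L, n_replicates = 3L,
                                      noise_sd = 0.005, r_free = 0.08,
                                      r_bound = 0.20, g = 1) {
  stopifnot(kb > 0, ka > 0, probe_total > 0, receptor_total > 0,
            top_conc > 0, dilution_factor > 1, n_points >= 2,
            n_replicates >= 1, noise_sd >= 0, g > 0)
  check_seed(seed)
  conc <- sort(top_conc / dilution_factor^(seq_len(n_points) - 1L))
  out <- with_local_seed(seed, {
    purrr::map(seq_len(n_replicates), function(i) {
      fb <- competitive_fraction_bound(receptor_total, probe_total, conc,
                                       ka, kb)
      r <- predict_anisotropy(fb, r_free, r_bound, g)
      tibble::tibble(titrant_conc = conc, conc_unit = "M",
                     anisotropy = r + stats::rnorm(length(r), 0, noise_sd),
                     replicate = paste0("R", i))
    }) |> dplyr::bind_rows()
  })
  structure(out, mode = "competition",
            truth = list(kb = kb, ka = ka, probe_total = probe_total,
                         receptor_total = receptor_total, r_free = r_free,
                         r_bound = r_bound, g = g, noise_sd = noise_sd,
                         seed = seed))
}

#' Simulate an NMR titration peak-list pair
#'
#' Generates apo and ligand-added per-residue peak lists over a disordered
#' sequence window, with intensity attenuation planted in specified motif
#' regions. Apo intensities are log-normal; bound intensities are the apo
#' values attenuated by the per-region depth; both measurements carry
#' multiplicative log-normal noise (positivity-preserving). A configured
#' fraction of residues is removed from both lists to emulate peaks lost
#' to spectral overlap. Defaults plant two regions, residues 220-235
#' (depth 0.9) and 265-275 (depth 0.8), in the window 204-283 of a
#' disordered substrate C-terminus.
#'
#' @param seed Integer random seed (required).
#' @param window Integer residue window (native protein numbering).
#' @param regions Tibble with columns `start`, `end`, `depth` (fractional
#'   attenuation, `0 <= depth < 1` removes that fraction of intensity).
#'   Regions must lie inside `window` and must not overlap.
#' @param missing_frac Fraction of window residues dropped from both lists
#'   (peak overlap).
#' @param noise_sd SD of multiplicative log-normal noise applied
#'   independently to each measured intensity (0.1 gives about 10% noise).
#' @param intensity_meanlog,intensity_sdlog Log-normal parameters of the
#'   apo intensity distribution (arbitrary units).
#' @return A list with elements `apo` and `bound` (tibbles with `residue`,
#'   `intensity`) and `truth` (list: `regions`, `missing_residues`,
#'   `window`).
#' @examples
#' sim <- gen_nmr_titration(seed = 1, missing_frac = 0.1, noise_sd = 0.1)
#' str(sim$truth)
#' @export
gen_nmr_titration <- function(seed, window = 204:283,
                              regions = tibble::tibble(
                                start = c(220L, 265L),
                                end = c(235L, 275L),
                                depth = c(0.9, 0.8)),
                              missing_frac = 0, noise_sd = 0,
                              intensity_meanlog = log(100),
                              intensity_sdlog = 0.3) {
  check_seed(seed)
  window <- sort(unique(as.integer(window)))
  stopifnot(nrow(regions) >= 0, missing_frac >= 0, missing_frac < 1,
            noise_sd >= 0)
  if (nrow(regions) > 0) {
    stopifnot(all(regions$start <= regions$end),
              all(regions$depth >= 0), all(regions$depth < 1))
    if (!all(regions$start %in% window) || !all(regions$end %in% window)) {
      stop("planted regions must lie inside the sequence window",
           call. = FALSE)
    }
    reg <- dplyr::arrange(regions, .data$start)
    if (nrow(reg) > 1 && any(reg$start[-1] <= reg$end[-nrow(reg)])) {
      stop("planted regions overlap", call. = FALSE)
    }
  }
  with_local_seed(seed, {
    n <- length(window)
    base <- stats::rlnorm(n, intensity_meanlog, intensity_sdlog)
    depth <- rep(0, n)
    for (i in seq_len(nrow(regions))) {
      in_reg <- window >= regions$start[i] & window <= regions$end[i]
      depth[in_reg] <- regions$depth[i]
    }
    apo_i <- base * exp(stats::rnorm(n, 0, noise_sd))
    bound_i <- base * (1 - depth) * exp(stats::rnorm(n, 0, noise_sd))
    drop <- stats::rbinom(n, 1, missing_frac) == 1
    missing <- window[drop]
    keep <- !drop
    list(
      apo = tibble::tibble(residue = window[keep],
                           intensity = apo_i[keep]),
      bound = tibble::tibble(residue = window[keep],
                             intensity = bound_i[keep]),
      truth = list(regions = regions, missing_residues = missing,
                   window = window, seed = seed)
    )
  })
}

#' Simulate a per-cell localization table
#'
#' Generates per-cell records in which substrate expression (mean nuclear
#' GFP intensity, log-normal across cells) drives the probability of
#' diffuse SPOP localization through a logistic threshold model:
#' \deqn{P(\mathrm{diffuse}) = \mathrm{logit}^{-1}\big(
#'   \mathrm{slope} \cdot (\log I - \mathrm{midpoint})\big)}
#' so high-expressing cells tend to relocalize SPOP out of nuclear
#' speckles. `slope = 0` gives the null model (class independent of
#' intensity, P = 1/2), used for type-I-error calibration.
#' `binding_deficient = TRUE` forces P(diffuse) = 0 regardless of
#' expression, emulating variants whose motif deletions abolish the
#' interaction so SPOP stays punctate in every cell.
#'
#' @param seed Integer random seed (required).
#' @param n_cells Number of cells.
#' @param n_replicates Number of biological replicates cells are assigned
#'   to (round-robin).
#' @param variant Variant label stored in the table (e.g. `"WT"`,
#'   `"dSBM1"`).
#' @param intensity_meanlog,intensity_sdlog Log-normal parameters of the
#'   per-cell intensity distribution (grayscale units).
#' @param midpoint_log Log-intensity at which P(diffuse) = 1/2 (the
#'   expression threshold); defaults to the distribution median.
#' @param slope Steepness of the logistic threshold (per log-intensity
#'   unit).
#' @param binding_deficient Force all cells speckled.
#' @return A tibble with columns `cell_id`, `replicate`, `variant`,
#'   `mean_gfp_intensity`, `spop_class`; `truth` attribute carries the
#'   generating parameters.
#' @examples
#' gen_cell_table(seed = 1, n_cells = 10)
#' @export
gen_cell_table <- function(seed, n_cells = 100L, n_replicates = 3L,
                           variant = "WT",
                           intensity_meanlog = log(50),
                           intensity_sdlog = 0.8,
                           midpoint_log = intensity_meanlog, slope = 2,
                           binding_deficient = FALSE) {
  check_seed(seed)
  stopifnot(n_cells >= 1, n_replicates >= 1, intensity_sdlog > 0)
  with_local_seed(seed, {
    intensity <- stats::rlnorm(n_cells, intensity_meanlog, intensity_sdlog)
    p_diffuse <- if (binding_deficient) {
      rep(0, n_cells)
    } else {
      stats::plogis(slope * (log(intensity) - midpoint_log))
    }
    cls <- ifelse(stats::rbinom(n_cells, 1, p_diffuse) == 1,
                  "diffuse", "speckled")
    out <- tibble::tibble(
      cell_id = sprintf("cell%04d", seq_len(n_cells)),
      replicate = paste0("B", ((seq_len(n_cells) - 1L) %% n_replicates) + 1L),
      variant = variant,
      mean_gfp_intensity = intensity,
      spop_class = cls
    )
    structure(out,
              truth = list(midpoint_log = midpoint_log, slope = slope,
                           binding_deficient = binding_deficient,
                           seed = seed))
  })
}

# seed hygiene: run code under a seed without touching the caller's RNG
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_seed <- function(seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 ||
      is.na(seed)) {
    stop("an explicit integer seed is required", call. = FALSE)
  }
  invisible(TRUE)
}
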