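#' Convert concentrations to molar
#'
#' All model functions in this package work in molar units internally.
#' Input tables carry an explicit unit column so that the nM-to-mM span of
#' typical titration designs never relies on guessed scaling.
#'
#' @param x Numeric vector of concentrations.
#' @param unit Character vector (recycled) of units; one of `"M"`, `"mM"`,
#'   `"uM"` (also accepted as `"µM"`/`"μM"`), `"nM"`, `"pM"`.
#' @return Numeric vector in molar.
#' @examples
#' conc_to_molar(c(40, 6), c("nM", "uM"))
#' @export
conc_to_molar <- function(x, unit) {
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, "μM" = 1e-6,
             nM = 1e-9, pM = 1e-12)
  unit <- as.character(unit)
  bad <- !(unit %in% names(scale))
  if (any(bad)) {
    stop("unknown concentration unit(s): ",
         paste(unique(unit[bad]), collapse = ", "),
         "; expected one of M, mM, uM, nM, pM", call. = FALSE)
  }
  x * unname(scale[unit])
}

#' Fraction of probe bound in a direct titration (ligand-depletion isotherm)
#'
#' Exact single-site isotherm that accounts for depletion of free receptor
#' by the probe, i.e. the quadratic rather than hyperbolic binding curve:
#' \deqn{FB = \frac{A_T + R_T + K_D - \sqrt{(A_T + R_T + K_D)^2 - 4 A_T R_T}}{2 A_T}}
#' evaluated in the numerically stable form
#' \eqn{FB = 2 R_T / (S + \sqrt{S^2 - 4 A_T R_T})} with
#' \eqn{S = A_T + R_T + K_D}, which avoids catastrophic cancellation when
#' the probe is in trace amounts.
#'
#' @param probe_total Total probe (labeled ligand) concentration, molar. Must
#'   be positive.
#' @param receptor_total Total receptor concentration, molar (the titrated
#'   species in a direct anisotropy experiment). Non-negative.
#' @param kd Dissociation constant of the probe-receptor complex, molar.
#'   Must be positive.
#' @return Fraction of probe bound, in `[0, 1]`. Vectorized over all
#'   arguments.
#' @seealso [competitive_fraction_bound()] for the three-species competition
#'   case, which reduces to this function at zero competitor.
#' @examples
#' # 40 nM probe titrated with receptor at K_D
#' direct_fraction_bound(4e-8, 2.6e-6, 2.6e-6)
#' @export
direct_fraction_bound <- function(probe_total, receptor_total, kd) {
  if (any(probe_total <= 0)) stop("probe_total must be positive", call. = FALSE)
  if (any(kd <= 0)) stop("kd must be positive", call. = FALSE)
  if (any(receptor_total < 0)) {
    stop("receptor_total must be non-negative", call. = FALSE)
  }
  s <- probe_total + receptor_total + kd
  disc <- s^2 - 4 * probe_total * receptor_total
  disc[disc < 0] <- 0  # roundoff guard; analytically disc >= kd^2 > 0
  fb <- 2 * receptor_total / (s + sqrt(disc))
  pmin(pmax(fb, 0), 1)
}

# cubic coefficients of the complete competitive binding model in [R]
competition_cubic_coefs <- function(receptor_total, probe_total,
                                    competitor_total, probe_kd,
                                    competitor_kd) {
  a <- probe_kd + competitor_kd + probe_total + competitor_total -
    receptor_total
  b <- competitor_kd * (probe_total - receptor_total) +
    probe_kd * (competitor_total - receptor_total) +
    probe_kd * competitor_kd
  c <- -probe_kd * competitor_kd * receptor_total
  list(a = a, b = b, c = c)
}

#' Free receptor concentration in a probe/competitor/receptor mixture
#'
#' Exact solution of the complete competitive binding equilibrium: one
#' receptor and two mutually exclusive ligands (labeled probe and unlabeled
#' competitor), with no excess-ligand approximation. Free receptor
#' \eqn{[R]} is the physical root of the cubic
#' \eqn{[R]^3 + a[R]^2 + b[R] + c = 0} with
#' \eqn{a = K_A + K_B + A_T + B_T - R_T},
#' \eqn{b = K_B(A_T - R_T) + K_A(B_T - R_T) + K_A K_B},
#' \eqn{c = -K_A K_B R_T}, obtained trigonometrically as
#' \deqn{[R] = -a/3 + (2/3)\sqrt{a^2 - 3b}\,\cos(\theta/3), \quad
#'   \theta = \arccos\frac{-2a^3 + 9ab - 27c}{2\sqrt{(a^2 - 3b)^3}}.}
#'
#' The arccos argument is clamped to `[-1, 1]` against floating-point
#' overshoot. If the cubic is degenerate (`a^2 - 3b` not safely positive,
#' which can only occur at measure-zero parameter combinations) the function
#' falls back to the bracketing bisection solver [solve_equilibrium()] with
#' a warning.
#'
#' @param receptor_total,probe_total,competitor_total Total concentrations,
#'   molar. `competitor_total = 0` encodes "no competitor".
#' @param probe_kd,competitor_kd Dissociation constants of probe and
#'   competitor, molar; both must be positive.
#' @return Free receptor concentration, molar, in `[0, receptor_total]`.
#'   Vectorized.
#' @examples
#' competitive_free_receptor(6e-6, 4e-8, 1.4e-4, 2.6e-6, 1.4e-4)
#' @export
competitive_free_receptor <- function(receptor_total, probe_total,
                                      competitor_total, probe_kd,
                                      competitor_kd) {
  check_system(receptor_total, probe_total, competitor_total,
               probe_kd, competitor_kd)
  n <- max(lengths(list(receptor_total, probe_total, competitor_total,
                        probe_kd, competitor_kd)))
  receptor_total <- rep_len(receptor_total, n)
  probe_total <- rep_len(probe_total, n)
  competitor_total <- rep_len(competitor_total, n)
  probe_kd <- rep_len(probe_kd, n)
  competitor_kd <- rep_len(competitor_kd, n)

  co <- competition_cubic_coefs(receptor_total, probe_total,
                                competitor_total, probe_kd, competitor_kd)
  disc <- co$a^2 - 3 * co$b
  # degeneracy guard relative to the coefficient scale, not absolute
  ok <- disc > .Machine$double.eps * (co$a^2 + 3 * abs(co$b) +
                                        .Machine$double.xmin)
  r <- rep(NA_real_, n)
  if (any(ok)) {
    a <- co$a[ok]; b <- co$b[ok]; c <- co$c[ok]; d <- disc[ok]
    arg <- (-2 * a^3 + 9 * a * b - 27 * c) / (2 * sqrt(d^3))
    theta <- acos(pmin(pmax(arg, -1), 1))
    rr <- -a / 3 + (2 / 3) * sqrt(d) * cos(theta / 3)
    # the trig root loses precision to cancellation when [R] << a; a few
    # Newton steps on the (well-conditioned, strictly increasing)
    # mass-balance residual restore full double accuracy
    rt <- receptor_total[ok]; at <- probe_total[ok]
    bt <- competitor_total[ok]; ka <- probe_kd[ok]; kb <- competitor_kd[ok]
    rr <- pmin(pmax(rr, 0), rt)
    for (it in 1:4) {
      f <- rr * (1 + at / (ka + rr) + bt / (kb + rr)) - rt
      fp <- 1 + at * ka / (ka + rr)^2 + bt * kb / (kb + rr)^2
      rr <- pmin(pmax(rr - f / fp, 0), rt)
    }
    r[ok] <- rr
  }
  if (any(!ok)) {
    warning("degenerate cubic discriminant; falling back to bisection ",
            "solver for ", sum(!ok), " input(s)", call. = FALSE)
    idx <- which(!ok)
    r[idx] <- vapply(idx, function(i) {
      solve_equilibrium(receptor_total[i], probe_total[i],
                        competitor_total[i], probe_kd[i],
                        competitor_kd[i])$free_receptor
    }, numeric(1))
  }
  pmin(pmax(r, 0), receptor_total)
}

#' Fraction of probe bound under competition
#'
#' Fraction of the labeled probe in complex with receptor in the presence of
#' an unlabeled competitor: \eqn{FSB = [R]/(K_A + [R])} with free receptor
#' from the exact cubic solution [competitive_free_receptor()]. Monotone
#' non-increasing in competitor concentration; reduces to
#' [direct_fraction_bound()] at zero competitor.
#'
#' @inheritParams competitive_free_receptor
#' @return Fraction of probe bound, in `[0, 1]`. Vectorized.
#' @examples
#' competitive_fraction_bound(6e-6, 4e-8, 1.4e-4, 2.6e-6, 1.4e-4)
#' @export
competitive_fraction_bound <- function(receptor_total, probe_total,
                                       competitor_total, probe_kd,
                                       competitor_kd) {
  r <- competitive_free_receptor(receptor_total, probe_total,
                                 competitor_total, probe_kd, competitor_kd)
  fb <- r / (probe_kd + r)
  pmin(pmax(fb, 0), 1)
}

#' Predict anisotropy from fraction bound
#'
#' Intensity-weighted two-state anisotropy mixing:
#' \deqn{r = \frac{r_{free}(1 - FB) + g\, r_{bound}\, FB}{(1 - FB) + g\, FB}}
#' where `g` is the ratio of bound-state to free-state fluorescence
#' intensity. At `g = 1` (the default throughout the package) this is plain
#' linear mixing between the free and bound endpoint anisotropies.
#'
#' @param frac_bound Fraction of probe bound, in `[0, 1]`.
#' @param r_free,r_bound Anisotropy of the free and bound probe
#'   (dimensionless endpoints).
#' @param g Bound/free fluorescence intensity ratio; must be positive.
#' @return Predicted anisotropy, between `r_free` and `r_bound`. Vectorized.
#' @examples
#' predict_anisotropy(0.5, r_free = 0.08, r_bound = 0.20)
#' @export
predict_anisotropy <- function(frac_bound, r_free, r_bound, g = 1) {
  if (any(g <= 0)) stop("g must be positive", call. = FALSE)
  if (any(frac_bound < -1e-12 | frac_bound > 1 + 1e-12)) {
    stop("frac_bound must lie in [0, 1]", call. = FALSE)
  }
  fb <- pmin(pmax(frac_bound, 0), 1)
  (r_free * (1 - fb) + g * r_bound * fb) / ((1 - fb) + g * fb)
}

#' Bisection solver for the competitive binding equilibrium
#'
#' Independent numerical solver for the three-species equilibrium, used as
#' the verification oracle for the closed-form cubic and as its fallback at
#' degenerate inputs -- never in the fitting hot path. It bisects the scalar
#' mass-balance residual
#' \deqn{f([R]) = [R]\left(1 + \frac{A_T}{K_A + [R]} +
#'   \frac{B_T}{K_B + [R]}\right) - R_T}
#' on the guaranteed bracket \eqn{[0, R_T]} (f is strictly increasing, so
#' the root is unique), then reads off all species by mass action.
#'
#' @inheritParams competitive_free_receptor
#' @param tol Relative tolerance on free receptor (bracket width relative to
#'   `receptor_total`).
#' @param max_iter Iteration cap; exceeding it without reaching `tol` is an
#'   error reporting the residual.
#' @return A one-row tibble with columns `free_receptor`, `free_probe`,
#'   `free_competitor`, `complex_probe`, `complex_competitor` (molar).
#'   Scalar inputs only.
#' @examples
#' solve_equilibrium(6e-6, 4e-8, 1.4e-4, 2.6e-6, 1.4e-4)
#' @export
solve_equilibrium <- function(receptor_total, probe_total, competitor_total,
                              probe_kd, competitor_kd, tol = 1e-12,
                              max_iter = 1000L) {
  check_system(receptor_total, probe_total, competitor_total,
               probe_kd, competitor_kd)
  stopifnot(length(receptor_total) == 1, tol > 0)
  resid <- function(r) {
    r * (1 + probe_total / (probe_kd + r) +
           competitor_total / (competitor_kd + r)) - receptor_total
  }
  lo <- 0
  hi <- receptor_total
  if (receptor_total == 0) {
    r <- 0
  } else {
    # converge relative to the root itself (free receptor can sit many
    # orders of magnitude below receptor_total under tight binding)
    iter <- 0L
    while ((hi - lo) > tol * max(lo, .Machine$double.xmin)) {
      iter <- iter + 1L
      if (iter > max_iter) {
        stop(sprintf(
          "bisection failed to converge: bracket width %.3e, residuals f(lo)=%.3e f(hi)=%.3e",
          hi - lo, resid(lo), resid(hi)), call. = FALSE)
      }
      mid <- (lo + hi) / 2
      if (mid <= lo || mid >= hi) break  # bit-level convergence
      if (resid(mid) > 0) hi <- mid else lo <- mid
    }
    r <- (lo + hi) / 2
  }
  ra <- probe_total * r / (probe_kd + r)
  rb <- competitor_total * r / (competitor_kd + r)
  tibble::tibble(
    free_receptor = r,
    free_probe = probe_total - ra,
    free_competitor = competitor_total - rb,
    complex_probe = ra,
    complex_competitor = rb
  )
}

# shared validation of equilibrium-system invariants
check_system <- function(receptor_total, probe_total, competitor_total,
                         probe_kd, competitor_kd) {
  if (any(receptor_total < 0) || any(probe_total < 0) ||
      any(competitor_total < 0)) {
    stop("total concentrations must be non-negative", call. = FALSE)
  }
  if (any(probe_kd <= 0) || any(competitor_kd <= 0)) {
    stop("dissociation constants must be positive", call. = FALSE)
  }
  invisible(TRUE)
}
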