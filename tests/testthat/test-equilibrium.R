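test_that("direct isotherm handles limits and the depletion regime", {
  # no receptor -> nothing bound
  expect_equal(direct_fraction_bound(4e-8, 0, 2.6e-6), 0)
  # trace probe at receptor = K_D -> half saturation
  expect_equal(direct_fraction_bound(1e-12, 2.6e-6, 2.6e-6), 0.5,
               tolerance = 1e-6)
  # depletion-corrected value at the standard 40 nM probe / 6 uM receptor
  # design (frozen from the bisection mass-balance oracle)
  expect_equal(direct_fraction_bound(4e-8, 6e-6, 2.6e-6), 0.6966915701,
               tolerance = 1e-7)
  # trace-probe limit reduces to the hyperbolic isotherm
  r <- c(1e-7, 1e-6, 1e-5)
  expect_equal(direct_fraction_bound(1e-15, r, 2.6e-6), r / (2.6e-6 + r),
               tolerance = 1e-6)
})

test_that("direct isotherm is bounded and monotone in receptor", {
  r <- 10^seq(-9, -2, length.out = 200)
  fb <- direct_fraction_bound(4e-8, r, 2.6e-6)
  expect_true(all(fb >= 0 & fb <= 1))
  expect_true(all(diff(fb) >= 0))
  # strong depletion: probe well above K_D still bounded
  fb2 <- direct_fraction_bound(1e-3, r, 1e-8)
  expect_true(all(fb2 >= 0 & fb2 <= 1))
})

test_that("direct isotherm rejects invalid domains", {
  expect_error(direct_fraction_bound(0, 1e-6, 1e-6), "probe_total")
  expect_error(direct_fraction_bound(-1e-9, 1e-6, 1e-6), "probe_total")
  expect_error(direct_fraction_bound(1e-8, 1e-6, 0), "kd")
  expect_error(direct_fraction_bound(1e-8, -1e-6, 1e-6), "receptor_total")
})

test_that("cubic solution reduces to the two-species case at zero competitor", {
  r_grid <- 10^seq(-9, -3.5, length.out = 100)
  fb_direct <- direct_fraction_bound(4e-8, r_grid, 2.6e-6)
  fb_comp <- competitive_fraction_bound(r_grid, 4e-8, 0, 2.6e-6, 1)
  expect_equal(fb_comp, fb_direct, tolerance = 1e-10)
})

test_that("an infinitely weak competitor leaves the probe curve unchanged", {
  r0 <- competitive_free_receptor(6e-6, 4e-8, 0, 2.6e-6, 1)
  r_weak <- competitive_free_receptor(6e-6, 4e-8, 1e-4, 2.6e-6, 1e3)
  expect_equal(r_weak, r0, tolerance = 1e-3)
})

test_that("cubic solution matches the frozen oracle value", {
  # 40 nM probe, 6 uM receptor, competitor 140 uM at K_B = 140 uM
  # (frozen from the bisection oracle)
  r <- competitive_free_receptor(6e-6, 4e-8, 1.4e-4, 2.6e-6, 1.4e-4)
  expect_equal(r, 3.02116005e-6, tolerance = 1e-6)
  fsb <- competitive_fraction_bound(6e-6, 4e-8, 1.4e-4, 2.6e-6, 1.4e-4)
  expect_equal(fsb, 0.5374620228, tolerance = 1e-6)
})

test_that("probe displacement is monotone in competitor and complete at excess", {
  b <- 10^seq(-8, -1, length.out = 60)
  fsb <- competitive_fraction_bound(6e-6, 4e-8, b, 2.6e-6, 1e-5)
  expect_true(all(diff(fsb) <= 1e-12))
  expect_lt(fsb[length(fsb)], 0.01)
  # tighter competitor displaces more at fixed B_T
  fsb_tight <- competitive_fraction_bound(6e-6, 4e-8, 1e-4, 2.6e-6, 1e-6)
  fsb_loose <- competitive_fraction_bound(6e-6, 4e-8, 1e-4, 2.6e-6, 1e-3)
  expect_lt(fsb_tight, fsb_loose)
})

test_that("closed-form free receptor agrees with the bisection oracle", {
  sys <- random_systems(200, seed = 101)
  r_closed <- competitive_free_receptor(sys$receptor_total,
                                        sys$probe_total,
                                        sys$competitor_total,
                                        sys$probe_kd, sys$competitor_kd)
  r_oracle <- purrr::pmap_dbl(sys, function(receptor_total, probe_total,
                                            competitor_total, probe_kd,
                                            competitor_kd) {
    solve_equilibrium(receptor_total, probe_total, competitor_total,
                      probe_kd, competitor_kd)$free_receptor
  })
  expect_lt(max(abs(r_closed - r_oracle) / r_oracle), 1e-8)
})

test_that("oracle solver conserves mass and reduces correctly", {
  sys <- random_systems(100, seed = 202)
  worst <- 0
  for (i in seq_len(nrow(sys))) {
    sp <- solve_equilibrium(sys$receptor_total[i], sys$probe_total[i],
                            sys$competitor_total[i], sys$probe_kd[i],
                            sys$competitor_kd[i])
    expect_true(all(unlist(sp) >= 0))
    res <- c(
      (sp$free_receptor + sp$complex_probe + sp$complex_competitor -
         sys$receptor_total[i]) / sys$receptor_total[i],
      (sp$free_probe + sp$complex_probe - sys$probe_total[i]) /
        sys$probe_total[i],
      (sp$free_competitor + sp$complex_competitor -
         sys$competitor_total[i]) / sys$competitor_total[i]
    )
    worst <- max(worst, abs(res))
  }
  expect_lt(worst, 1e-12)
  # two-species reduction: no competitor -> no competitor complex
  sp0 <- solve_equilibrium(6e-6, 4e-8, 0, 2.6e-6, 1)
  expect_equal(sp0$complex_competitor, 0)
  # quadratic root for the two-species case
  quad_fb <- direct_fraction_bound(4e-8, 6e-6, 2.6e-6)
  expect_equal(sp0$complex_probe / 4e-8, quad_fb, tolerance = 1e-9)
})

test_that("equivalent probe and competitor split complexes symmetrically", {
  sp <- solve_equilibrium(6e-6, 5e-6, 5e-6, 1e-5, 1e-5)
  expect_equal(sp$complex_probe, sp$complex_competitor, tolerance = 1e-10)
})

test_that("anisotropy mixing respects endpoints and the g correction", {
  expect_equal(predict_anisotropy(0, 0.08, 0.20, 1), 0.08)
  expect_equal(predict_anisotropy(1, 0.08, 0.20, 1), 0.20)
  expect_equal(predict_anisotropy(0.5, 0.08, 0.20, 1), 0.14)
  # g = 1 is linear mixing
  fb <- seq(0, 1, 0.1)
  expect_equal(predict_anisotropy(fb, 0.08, 0.20, 1),
               0.08 + 0.12 * fb)
  # g != 1 skews toward the brighter state but stays within endpoints
  r <- predict_anisotropy(fb, 0.08, 0.20, 2.5)
  expect_true(all(r >= 0.08 - 1e-12 & r <= 0.20 + 1e-12))
  expect_true(all(predict_anisotropy(fb, 0.08, 0.20, 2.5) >=
                    predict_anisotropy(fb, 0.08, 0.20, 1) - 1e-12))
  expect_error(predict_anisotropy(0.5, 0.08, 0.20, 0), "g must be")
  expect_error(predict_anisotropy(1.5, 0.08, 0.20, 1), "frac_bound")
})

test_that("unit conversion covers the nM-to-mM span and rejects junk", {
  expect_equal(conc_to_molar(c(40, 6, 2, 1), c("nM", "uM", "mM", "M")),
               c(4e-8, 6e-6, 2e-3, 1))
  expect_equal(conc_to_molar(1, "µM"), 1e-6)
  expect_error(conc_to_molar(1, "furlongs"), "unknown concentration unit")
})
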