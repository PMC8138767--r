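test_that("sparky peak lists parse assignments to residue numbers", {
  f <- write_sparky_fixture(c(
    "Assignment w1 w2 Height",
    "G220N-H 109.12 8.21 5400.2",
    "V229N-H 121.44 8.02 3100.9",
    "S273N-H 115.30 8.55 4100.0"))
  tab <- read_peak_list(f, "sparky_list")
  expect_equal(tab$residue, c(220L, 229L, 273L))
  expect_equal(tab$intensity, c(5400.2, 3100.9, 4100.0))
})

test_that("unparseable rows are skipped and duplicates are an error", {
  f <- write_sparky_fixture(c(
    "G220N-H 109.1 8.2 5400",
    "?-? 112.0 8.4 999",
    "V229N-H 121.4 8.0 3100"))
  expect_message(tab <- read_peak_list(f, "sparky_list"),
                 "skipped 1 unparseable")
  expect_equal(tab$residue, c(220L, 229L))

  f2 <- write_sparky_fixture(c(
    "G220N-H 109.1 8.2 5400",
    "V229N-H 121.4 8.0 3100",
    "V229C-H 121.5 8.1 2000"))
  expect_error(read_peak_list(f2, "sparky_list"), "229")

  f3 <- write_sparky_fixture(c("?-? 1 2 3", "?-? 4 5 6"))
  expect_error(suppressMessages(read_peak_list(f3, "sparky_list")),
               "no parseable rows")
})

test_that("generic CSV peak lists are read and the dialect auto-detected", {
  f <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(residue = c(204, 210), intensity = c(9, 7)),
                   f)
  expect_equal(read_peak_list(f, "generic_csv")$residue, c(204L, 210L))
  expect_equal(read_peak_list(f)$residue, c(204L, 210L))  # auto
})

test_that("intensity change implements 1 - I_bound/I_unbound after scaling", {
  res <- 204:215
  # residue 204 attenuated to 20% of apo; rest unchanged
  pp <- make_peak_pair(res, change = c(0.80, rep(0, 11)))
  prof <- intensity_change(pp$apo, pp$bound)
  expect_equal(prof$percent_change[prof$residue == 204], 0.80,
               tolerance = 1e-12)
  expect_equal(prof$percent_change[prof$residue == 210], 0,
               tolerance = 1e-12)
  # identity: equal tables give zero change everywhere
  prof0 <- intensity_change(pp$apo, pp$apo)
  expect_true(all(abs(prof0$percent_change) < 1e-12))
})

test_that("normalization absorbs arbitrary per-dataset scale factors", {
  set.seed(31)
  res <- 204:243
  apo <- tibble::tibble(residue = res, intensity = rlnorm(40, log(100), 0.4))
  change <- ifelse(res >= 220 & res <= 230, 0.85, 0)
  bound <- tibble::tibble(residue = res,
                          intensity = apo$intensity * (1 - change))
  p1 <- intensity_change(apo, bound)
  bound_scaled <- dplyr::mutate(bound, intensity = intensity * 7.3)
  apo_scaled <- dplyr::mutate(apo, intensity = intensity * 0.02)
  p2 <- intensity_change(apo_scaled, bound_scaled)
  expect_equal(p1$percent_change, p2$percent_change, tolerance = 1e-12)
  # all three normalization statistics are scale invariant here
  for (norm in c("total", "max")) {
    a <- intensity_change(apo, bound, normalization = norm)
    b <- intensity_change(apo_scaled, bound_scaled, normalization = norm)
    expect_equal(a$percent_change, b$percent_change, tolerance = 1e-12)
  }
})

test_that("incomplete residues are flagged and excluded from scoring", {
  res <- 204:215
  pp <- make_peak_pair(res, change = rep(0.5, 12))
  bound_missing <- dplyr::filter(pp$bound, residue != 208)
  prof <- intensity_change(pp$apo, bound_missing, window = res)
  row <- prof[prof$residue == 208, ]
  expect_true(row$missing)
  expect_identical(row$missing_reason, "omitted")
  expect_true(is.na(row$percent_change))
  # and too little overlap between the tables is an error
  expect_error(
    intensity_change(pp$apo, dplyr::slice_head(pp$bound, n = 5)),
    "at least 10 residues")
  # a zero normalization statistic is an error
  zero <- dplyr::mutate(pp$bound, intensity = 0)
  expect_error(intensity_change(pp$apo, zero, normalization = "max"),
               "normalization statistic")
})

test_that("threshold schemes bin on lower-exclusive/upper-inclusive intervals", {
  s4 <- bin_scheme("sbm1_4bin")
  expect_equal(s4$label, c("<70", "70 to 80", "80 to 90", ">90"))
  res <- 204:214
  chg <- c(0.95, 0.85, 0.75, 0.50, 0.90, 0.80, 0.70, 0.05, 0, 0.3, 0.6)
  prof <- tibble::tibble(residue = res, intensity_unbound = 1,
                         intensity_bound = 1 - chg, percent_change = chg,
                         missing = FALSE, missing_reason = NA_character_)
  b4 <- bin_changes(prof, "sbm1_4bin")
  expect_identical(b4$bin[b4$residue == 204], ">90")
  expect_identical(b4$bin[b4$residue == 205], "80 to 90")
  expect_identical(b4$bin[b4$residue == 206], "70 to 80")
  expect_identical(b4$bin[b4$residue == 207], "<70")
  # boundary values fall in the lower bin of the pair
  expect_identical(b4$bin[b4$residue == 208], "80 to 90")  # 90
  expect_identical(b4$bin[b4$residue == 209], "70 to 80")  # 80
  expect_identical(b4$bin[b4$residue == 210], "<70")       # 70

  b3 <- bin_changes(prof, "sbm2_3bin")
  expect_identical(b3$bin[b3$residue == 205], ">70")   # 0.85
  expect_identical(b3$bin[b3$residue == 214], "40 to 70")  # 0.60
  expect_identical(b3$bin[b3$residue == 211], "<40")   # 0.05
})

test_that("binning partitions residues and missing data goes to the darkest bin", {
  sim <- gen_nmr_titration(seed = 32, missing_frac = 0.1, noise_sd = 0.05)
  prof <- intensity_change(sim$apo, sim$bound, window = 204:283)
  binned <- bin_changes(prof, "sbm1_4bin")
  expect_false(anyNA(binned$bin))
  expect_equal(sum(table(binned$bin)), nrow(binned))
  expect_true(all(binned$bin[binned$missing] == "<70"))
  b3 <- bin_changes(prof, "sbm2_3bin")
  expect_true(all(b3$bin[b3$missing] == "<40"))
})

test_that("planted motif regions are detected exactly on clean profiles", {
  sim <- gen_nmr_titration(seed = 33)
  prof <- intensity_change(sim$apo, sim$bound, window = 204:283)
  reg <- detect_binding_regions(prof)
  expect_equal(reg$start_residue, c(220L, 265L))
  expect_equal(reg$end_residue, c(235L, 275L))
  expect_equal(reg$mean_percent_change, c(0.9, 0.8), tolerance = 1e-6)
})

test_that("region detection respects threshold, run length, and gaps", {
  res <- 204:283
  # flat profile: nothing to find
  flat <- make_peak_pair(res, change = rep(0.05, length(res)))
  pf <- intensity_change(flat$apo, flat$bound, window = res)
  expect_equal(nrow(detect_binding_regions(pf)), 0L)
  # a single attenuated residue is below the minimum run
  single <- make_peak_pair(res, change = ifelse(res == 230, 0.9, 0.05))
  ps <- intensity_change(single$apo, single$bound, window = res)
  expect_equal(nrow(detect_binding_regions(ps, min_run = 4)), 0L)
  expect_equal(nrow(detect_binding_regions(ps, min_run = 1)), 1L)
  # an interior missing residue within max_gap does not split the run
  chg <- ifelse(res >= 220 & res <= 235, 0.9, 0.05)
  pp <- make_peak_pair(res, change = chg)
  bound_hole <- dplyr::filter(pp$bound, residue != 227)
  ph <- intensity_change(pp$apo, bound_hole, window = res)
  reg <- detect_binding_regions(ph, max_gap = 1)
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$start_residue, reg$end_residue), c(220L, 235L))
  # but a gap beyond max_gap splits it
  bound_hole2 <- dplyr::filter(pp$bound, !residue %in% 226:227)
  ph2 <- intensity_change(pp$apo, bound_hole2, window = res)
  expect_equal(nrow(detect_binding_regions(ph2, max_gap = 1)), 2L)
  expect_equal(nrow(detect_binding_regions(ph2, max_gap = 2)), 1L)
})

test_that("attribute export is deterministic and round-trips", {
  sim <- gen_nmr_titration(seed = 34, missing_frac = 0.05)
  prof <- intensity_change(sim$apo, sim$bound, window = 204:283)
  binned <- bin_changes(prof, "sbm1_4bin")
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  export_attributes(binned, f1)
  export_attributes(binned, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_attributes(f1)
  expect_equal(back$residue, binned$residue)
  expect_equal(back$bin_rank, binned$bin_rank)
  expect_equal(back$bin, binned$bin)
  # empty profile writes a header-only file with a warning
  f3 <- tempfile(fileext = ".tsv")
  expect_warning(export_attributes(binned[0, ], f3), "header-only")
  expect_equal(nrow(read_attributes(f3)), 0L)
})

test_that("the NMR generator honors its contract", {
  # same seed, same tables
  a <- gen_nmr_titration(seed = 35, missing_frac = 0.1, noise_sd = 0.1)
  b <- gen_nmr_titration(seed = 35, missing_frac = 0.1, noise_sd = 0.1)
  expect_identical(a, b)
  # zero depth -> no signal
  none <- gen_nmr_titration(seed = 36,
                            regions = tibble::tibble(start = integer(),
                                                     end = integer(),
                                                     depth = numeric()))
  p <- intensity_change(none$apo, none$bound, window = 204:283)
  expect_true(all(abs(p$percent_change) < 1e-9))
  # missing fraction approximately honored (binomial draw over 80 residues)
  n_missing <- length(a$truth$missing_residues)
  expect_gt(n_missing, 0)
  expect_lt(n_missing, 0.3 * 80)
  expect_false(any(a$apo$residue %in% a$truth$missing_residues))
  # overlapping plants are rejected
  expect_error(gen_nmr_titration(
    seed = 37, regions = tibble::tibble(start = c(220L, 230L),
                                        end = c(235L, 240L),
                                        depth = c(0.9, 0.8))),
    "overlap")
})

test_that("planted regions survive noise and missing residues", {
  hits <- 0L
  n_sim <- 40L
  for (i in seq_len(n_sim)) {
    sim <- gen_nmr_titration(seed = 4000 + i, missing_frac = 0.1,
                             noise_sd = 0.1)
    prof <- intensity_change(sim$apo, sim$bound, window = 204:283)
    det <- detect_binding_regions(prof, max_gap = 3)
    if (regions_within(det, sim$truth$regions, tol = 1L)) hits <- hits + 1L
  }
  expect_gte(hits, round(0.9 * n_sim))
})
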