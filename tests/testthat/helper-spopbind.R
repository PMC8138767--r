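# shared fixture builders for the test suite

# random equilibrium systems with log-uniform totals and K's
random_systems <- function(n, seed, range = c(1e-9, 1e-2)) {
  set.seed(seed)
  lo <- log10(range[1]); hi <- log10(range[2])
  tibble::tibble(
    receptor_total = 10^stats::runif(n, lo, hi),
    probe_total = 10^stats::runif(n, lo, hi),
    competitor_total = 10^stats::runif(n, lo, hi),
    probe_kd = 10^stats::runif(n, lo, hi),
    competitor_kd = 10^stats::runif(n, lo, hi)
  )
}

# peak tables on a common scale with a given attenuation pattern
make_peak_pair <- function(residues, change) {
  apo <- tibble::tibble(residue = residues, intensity = 100)
  bound <- tibble::tibble(residue = residues,
                          intensity = 100 * (1 - change))
  list(apo = apo, bound = bound)
}

# a small sparky-style peak list file
write_sparky_fixture <- function(lines, path = tempfile(fileext = ".list")) {
  writeLines(lines, path)
  path
}

# boundary agreement between planted and detected regions: for every
# planted region there is a detected region with max overlap whose start
# and end are both within tol residues
regions_within <- function(detected, planted, tol = 1L) {
  if (nrow(detected) == 0) return(FALSE)
  ok <- vapply(seq_len(nrow(planted)), function(i) {
    s <- planted$start[i]; e <- planted$end[i]
    overlap <- pmax(0, pmin(detected$end_residue, e) -
                      pmax(detected$start_residue, s) + 1)
    j <- which.max(overlap)
    overlap[j] > 0 &&
      abs(detected$start_residue[j] - s) <= tol &&
      abs(detected$end_residue[j] - e) <= tol
  }, logical(1))
  all(ok) && nrow(detected) == nrow(planted)
}
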