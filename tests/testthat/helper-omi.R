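# shared fixtures for the omiflim test suite; everything is generated in
# code, nothing is read from disk

default_bw <- 12500 / 256

test_irf <- function(n_bins = 256, bw = default_bw, t0 = 1200,
                     fwhm = 250) {
  make_irf(fwhm, bw, n_bins, t0)
}

# delta IRF: all mass in the first bin
delta_irf <- function(n_bins = 256, bw = default_bw) {
  make_irf(1e-6, bw, n_bins, 0)
}

# brute-force neighbourhood sum, the oracle for spatial_bin
brute_bin <- function(arr, r) {
  d <- dim(arr)
  out <- array(0, dim = d)
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    ys <- max(1, y - r):min(d[1], y + r)
    xs <- max(1, x - r):min(d[2], x + r)
    for (b in seq_len(d[3]))
      out[y, x, b] <- sum(arr[ys, xs, b])
  }
  out
}

# hand-assembled truth table for renderer tests (bypasses sample_population)
manual_truths <- function(cx, cy, ax = 4, ay = 4,
                          nadph = c(alpha1 = 0.75, tau1 = 400, tau2 = 2500),
                          fad = c(alpha1 = 0.75, tau1 = 300, tau2 = 2500),
                          photons = 2000, fad_photons = photons,
                          background = 0) {
  n <- length(cx)
  data.frame(cell_id = seq_len(n), condition = "control", donor_id = "sim",
             nadph_alpha1 = nadph[["alpha1"]], nadph_tau1 = nadph[["tau1"]],
             nadph_tau2 = nadph[["tau2"]],
             fad_alpha1 = fad[["alpha1"]], fad_tau1 = fad[["tau1"]],
             fad_tau2 = fad[["tau2"]],
             redox_true = photons / (photons + fad_photons),
             nadph_photons = photons, fad_photons = fad_photons,
             background = background,
             cx = cx, cy = cy, ax = rep(ax, n), ay = rep(ay, n),
             boundary_truncated = FALSE)
}

small_optics <- function(field = c(24, 24), n_bins = 256) {
  optics_config(field = field, n_bins = n_bins)
}

# a fixed GMM fit object for formula-level heterogeneity tests
manual_gmm <- function(w, mu, v = rep(1, length(w)), n = 100) {
  structure(list(k = length(w), weights = w, means = mu, variances = v,
                 loglik = NA_real_, bic = NA_real_, valid = TRUE,
                 n = n, seed = NA_integer_),
            class = "omi_gmm")
}
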