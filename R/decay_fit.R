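#' Biexponential decay parameters
#'
#' Container for the parameters of the biexponential fluorescence decay
#' model \eqn{I(t) = \alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2} + C}
#' with \eqn{\alpha_2 = 1 - \alpha_1}.  `amplitude` is the total number of
#' signal photons (integral of the background-free decay over the window).
#'
#' @param alpha1 Fractional amplitude of the short component, in `[0, 1]`.
#' @param tau1,tau2 Short and long lifetime components in picoseconds;
#'   `tau1 <= tau2` and both positive.
#' @param C Background counts per bin, `>= 0`.
#' @param amplitude Total signal photons, `> 0` unless the pixel is empty.
#' @return An object of class `biexp_params`.
#' @export
biexp_params <- function(alpha1, tau1, tau2, C = 0, amplitude = 1) {
  if (!is.finite(alpha1) || alpha1 < 0 || alpha1 > 1)
    stop("'alpha1' must lie in [0, 1]")
  if (!is.finite(tau1) || !is.finite(tau2) || tau1 <= 0 || tau2 <= 0)
    stop("lifetimes must be positive")
  if (tau1 > tau2) stop("'tau1' must not exceed 'tau2'")
  if (C < 0) stop("'C' must be non-negative")
  structure(list(alpha1 = alpha1, alpha2 = 1 - alpha1,
                 tau1 = tau1, tau2 = tau2, C = C, amplitude = amplitude),
            class = "biexp_params")
}

#' Amplitude-weighted mean fluorescence lifetime
#'
#' The mean lifetime is the amplitude-weighted average of the free and
#' bound lifetime components, \eqn{\tau_m = \alpha_1\tau_1 + \alpha_2\tau_2}.
#' It always lies between `tau1` and `tau2`.
#'
#' @param params A [biexp_params()] object, or a list with fields `alpha1`,
#'   `tau1`, `tau2`.
#' @return Mean lifetime in picoseconds.
#' @examples
#' mean_lifetime(biexp_params(0.5, 400, 2400))  # 1400
#' @export
mean_lifetime <- function(params) {
  params$alpha1 * params$tau1 + (1 - params$alpha1) * params$tau2
}

#' Integrated fluorescence intensity of a decay
#'
#' Area under the photon-arrival histogram: the plain sum of per-bin counts.
#'
#' @param counts Numeric vector of per-bin photon counts.
#' @return Scalar total counts.
#' @export
integrate_intensity <- function(counts) {
  sum(as.numeric(counts))
}

# Wrapped (periodic) monoexponential sampled at bin centres.  Fluorophores
# with lifetimes comparable to the repetition period do not fully decay
# within one window; the steady-state histogram is the periodic sum
# exp(-t/tau) / (1 - exp(-T/tau)) with T the window length.
wrapped_exp <- function(tcent, tau, window) {
  exp(-tcent / tau) / (1 - exp(-window / tau))
}

# Core forward model used by the fitter: expected counts per bin for a
# biexponential convolved (circularly) with the IRF.  `irf_fft` is the
# precomputed FFT of the IRF weights.  The signal part is renormalized to
# sum exactly to `amplitude`, so amplitude is the total signal photons in
# the window by construction.
model_decay_core <- function(alpha1, tau1, tau2, C, amplitude,
                             irf_fft, tcent, window) {
  f <- alpha1 * wrapped_exp(tcent, tau1, window) +
    (1 - alpha1) * wrapped_exp(tcent, tau2, window)
  conv <- Re(stats::fft(stats::fft(f) * irf_fft, inverse = TRUE)) /
    length(f)
  conv[conv < 0] <- 0  # clip FFT round-off
  s <- sum(conv)
  if (s <= 0) return(rep(C, length(f)))
  conv * (amplitude / s) + C
}

#' Expected TCSPC histogram for a biexponential decay convolved with an IRF
#'
#' Computes the per-bin expected photon counts for the decay model
#' \eqn{\alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2}}, wrapped
#' periodically over the acquisition window (incomplete-decay handling for
#' high repetition rates) and circularly convolved with the instrument
#' response, scaled so that the signal counts sum to `params$amplitude`,
#' plus the constant background `params$C` per bin.
#'
#' @param params A [biexp_params()] object.
#' @param irf An [make_irf()] object whose length sets the number of bins.
#' @param n_bins,bin_width_ps Time axis; defaults taken from `irf`.
#' @return Numeric vector of expected counts per bin.
#' @export
model_decay <- function(params, irf, n_bins = length(irf$values),
                        bin_width_ps = irf$bin_width_ps) {
  if (n_bins != length(irf$values))
    stop("'n_bins' must match the IRF length")
  if (params$tau1 <= 0 || params$tau2 <= 0)
    stop("lifetimes must be positive")
  tcent <- bin_centers(n_bins, bin_width_ps)
  window <- n_bins * bin_width_ps
  model_decay_core(params$alpha1, params$tau1, params$tau2,
                   params$C, params$amplitude,
                   stats::fft(irf$values), tcent, window)
}

#' Spatially bin a decay cube
#'
#' Enhances per-pixel photon counts by summing, bin-wise, the decays of the
#' `(2*radius+1)^2` neighbourhood of each pixel (3x3 for the default
#' `radius = 1`).  At image borders the neighbourhood is truncated: no
#' padding, so no photons are invented.
#'
#' @param cube A decay cube as produced by [render_field()] (class
#'   `omi_decay_cube`) or a bare 3-d array `rows x cols x n_bins`.
#' @param radius Neighbourhood radius; `0` returns the input unchanged.
#' @return Object of the same type with summed counts.
#' @export
spatial_bin <- function(cube, radius = 1L) {
  arr <- cube_counts(cube)
  radius <- as.integer(radius)
  if (radius < 0) stop("'radius' must be non-negative")
  nr <- dim(arr)[1]; nc <- dim(arr)[2]
  if (2L * radius + 1L > min(nr, nc))
    stop("'radius' exceeds half the image size")
  if (radius == 0L) return(cube)
  out <- array(0, dim = dim(arr))
  for (dy in -radius:radius) {
    ys <- max(1, 1 + dy):min(nr, nr + dy)   # destination rows
    yo <- ys - dy                            # source rows
    for (dx in -radius:radius) {
      xs <- max(1, 1 + dx):min(nc, nc + dx)
      xo <- xs - dx
      out[ys, xs, ] <- out[ys, xs, ] + arr[yo, xo, , drop = FALSE]
    }
  }
  set_cube_counts(cube, out)
}

#' Peak-count intensity threshold mask
#'
#' A pixel passes if the maximum count over its (binned) decay bins is at
#' least `min_peak_counts`; used to exclude pixels with too little
#' fluorescence signal for a reliable lifetime fit.
#'
#' @param cube Decay cube (apply after [spatial_bin()]).
#' @param min_peak_counts Non-negative threshold (counts); the comparison is
#'   `>=`.
#' @return Logical matrix `rows x cols`.
#' @export
threshold_mask <- function(cube, min_peak_counts) {
  if (min_peak_counts < 0) stop("'min_peak_counts' must be non-negative")
  arr <- cube_counts(cube)
  apply(arr, c(1, 2), max) >= min_peak_counts
}

#' Fit configuration for per-pixel decay fitting
#'
#' @param channel `"NADPH"` or `"FAD"`; sets channel-specific starting
#'   values (`tau2` starts longer for FAD).
#' @param bin_radius Spatial binning radius applied before fitting.
#' @param min_peak_counts Intensity threshold on the binned peak count.
#' @param weighting `"neyman"` (weights `1/max(O, 1)`, the TCSPC
#'   least-squares convention) or `"pearson"` (`1/max(M, 1)`, recomputed
#'   from the model each iteration).
#' @param tau_bounds_ps Lower/upper bounds for both lifetime components.
#' @param init Optional named list overriding starting values
#'   (`alpha1`, `tau1`, `tau2`).
#' @param chi2_max If finite, converged fits with reduced chi-squared above
#'   this value are flagged invalid in [fit_image()] maps (quality filter;
#'   disabled by default because roughly half of correctly specified
#'   Poisson fits exceed 1).
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @return A list of class `omi_fit_config`.
#' @export
fit_config <- function(channel = c("NADPH", "FAD"), bin_radius = 1L,
                       min_peak_counts = 50, weighting = c("neyman", "pearson"),
                       tau_bounds_ps = c(50, 10000), init = NULL,
                       chi2_max = Inf, maxiter = 100L) {
  channel <- match.arg(channel)
  weighting <- match.arg(weighting)
  defaults <- list(alpha1 = 0.7, tau1 = 300,
                   tau2 = if (channel == "FAD") 2500 else 2000)
  if (!is.null(init)) defaults[names(init)] <- init
  structure(list(channel = channel, bin_radius = as.integer(bin_radius),
                 min_peak_counts = min_peak_counts, weighting = weighting,
                 tau_bounds_ps = tau_bounds_ps, init = defaults,
                 chi2_max = chi2_max, maxiter = as.integer(maxiter)),
            class = "omi_fit_config")
}

#' Fit one pixel's decay to the IRF-convolved biexponential model
#'
#' Weighted least squares: minimizes \eqn{\sum_i w_i (O_i - M_i)^2} over
#' `(amplitude, alpha1, tau1, tau2, C)` with a bounded
#' Levenberg-Marquardt optimizer ([minpack.lm::nls.lm]).  Components are
#' sorted after the fit so the reported `tau1 <= tau2` (the model is
#' symmetric under component exchange).  The reduced chi-squared is
#' \eqn{\chi^2 / (n_{bins} - 5)} for the 5 free parameters.
#'
#' @param counts Observed per-bin photon counts.
#' @param irf An IRF on the same time axis.
#' @param config A [fit_config()].
#' @return A list of class `omi_pixel_fit`: `params` ([biexp_params()]),
#'   `tau_m` (ps), `intensity` (integrated raw counts), `chi2_red`,
#'   `converged`.  Degenerate input (all-zero decay) yields
#'   `converged = FALSE` with `NA` parameters, never `NaN` propagation.
#' @export
fit_pixel <- function(counts, irf, config = fit_config()) {
  n <- length(counts)
  if (n != length(irf$values))
    stop("decay length must match the IRF length")
  intensity <- sum(counts)
  if (intensity <= 0 || sum(counts > 0) < 10) {
    return(structure(list(params = NULL, tau_m = NA_real_,
                          intensity = intensity, chi2_red = NA_real_,
                          converged = FALSE),
                     class = "omi_pixel_fit"))
  }
  tcent <- bin_centers(n, irf$bin_width_ps)
  window <- n * irf$bin_width_ps
  irf_fft <- stats::fft(irf$values)

  # background start value: mean of the pre-rise bins (before the IRF peak)
  pre <- which(tcent < irf$t0_ps - 2 * irf$bin_width_ps)
  C0 <- if (length(pre) >= 3) mean(counts[pre]) else 0
  A0 <- max(intensity - n * C0, max(counts))
  p0 <- c(amp = A0, alpha1 = config$init$alpha1,
          tau1 = config$init$tau1, tau2 = config$init$tau2, C = max(C0, 0))

  w_obs <- 1 / pmax(counts, 1)
  resid_fn <- function(p) {
    m <- model_decay_core(p[2], p[3], p[4], p[5], p[1], irf_fft, tcent,
                          window)
    w <- if (config$weighting == "neyman") w_obs else 1 / pmax(m, 1)
    sqrt(w) * (counts - m)
  }
  lb <- c(1e-6, 0, config$tau_bounds_ps[1], config$tau_bounds_ps[1], 0)
  ub <- c(Inf, 1, config$tau_bounds_ps[2], config$tau_bounds_ps[2], Inf)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = lb, upper = ub, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = config$maxiter, nprint = 0)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(params = NULL, tau_m = NA_real_,
                          intensity = intensity, chi2_red = NA_real_,
                          converged = FALSE),
                     class = "omi_pixel_fit"))
  }
  p <- fit$par
  # enforce tau1 <= tau2 by exchanging components (model is exchange-symmetric)
  if (p["tau1"] > p["tau2"]) {
    p[c("tau1", "tau2")] <- p[c("tau2", "tau1")]
    p["alpha1"] <- 1 - p["alpha1"]
  }
  chi2 <- sum(resid_fn(c(p["amp"], p["alpha1"], p["tau1"], p["tau2"],
                         p["C"]))^2)
  params <- biexp_params(alpha1 = min(max(p[["alpha1"]], 0), 1),
                         tau1 = p[["tau1"]], tau2 = p[["tau2"]],
                         C = p[["C"]], amplitude = p[["amp"]])
  structure(list(params = params,
                 tau_m = mean_lifetime(params),
                 intensity = intensity,
                 chi2_red = chi2 / (n - 5),
                 converged = fit$info %in% 1:3),
            class = "omi_pixel_fit")
}

#' Fit every above-threshold pixel of a decay cube
#'
#' Orchestrates the per-pixel pipeline: spatial binning, intensity
#' thresholding, and the IRF-convolved biexponential fit at every pixel
#' that passes the threshold.  Produces per-parameter maps with `NA` at
#' invalid pixels (below threshold, non-converged, or failing the optional
#' chi-squared filter).
#'
#' @param cube An `omi_decay_cube`.
#' @param irf The IRF on the cube's time axis.
#' @param config A [fit_config()].
#' @param verbose Print a one-line progress summary.
#' @return A list of class `omi_fit_map` with matrices `tau_m`, `tau1`,
#'   `tau2`, `alpha1`, `C`, `amplitude`, `intensity`, `chi2_red`, logical
#'   matrices `thresholded`, `converged`, `valid`
#'   (`thresholded & converged`, plus the chi-squared filter when enabled),
#'   and metadata `channel`, `config`.
#' @export
fit_image <- function(cube, irf, config = fit_config(), verbose = FALSE) {
  binned <- spatial_bin(cube, config$bin_radius)
  keep <- threshold_mask(binned, config$min_peak_counts)
  arr <- cube_counts(binned)
  nr <- dim(arr)[1]; nc <- dim(arr)[2]
  mk <- function() matrix(NA_real_, nr, nc)
  maps <- list(tau_m = mk(), tau1 = mk(), tau2 = mk(), alpha1 = mk(),
               C = mk(), amplitude = mk(), intensity = mk(),
               chi2_red = mk())
  converged <- matrix(FALSE, nr, nc)
  idx <- which(keep)
  if (length(idx) == 0L)
    warning("no pixel passed the intensity threshold; empty fit map")
  for (i in idx) {
    yx <- arrayInd(i, c(nr, nc))
    f <- fit_pixel(arr[yx[1], yx[2], ], irf, config)
    converged[i] <- f$converged
    maps$intensity[i] <- f$intensity
    maps$chi2_red[i] <- f$chi2_red
    if (f$converged) {
      maps$tau_m[i] <- f$tau_m
      maps$tau1[i] <- f$params$tau1
      maps$tau2[i] <- f$params$tau2
      maps$alpha1[i] <- f$params$alpha1
      maps$C[i] <- f$params$C
      maps$amplitude[i] <- f$params$amplitude
    }
  }
  valid <- keep & converged
  if (is.finite(config$chi2_max))
    valid <- valid & !is.na(maps$chi2_red) & maps$chi2_red <= config$chi2_max
  maps$tau_m[!valid] <- NA_real_
  maps$tau1[!valid] <- NA_real_
  maps$tau2[!valid] <- NA_real_
  maps$alpha1[!valid] <- NA_real_
  if (verbose)
    message(sprintf("fit_image[%s]: %d/%d pixels above threshold, %d valid",
                    cube_channel(cube), length(idx), nr * nc, sum(valid)))
  structure(c(maps, list(thresholded = keep, converged = converged,
                         valid = valid, channel = cube_channel(cube),
                         config = config)),
            class = "omi_fit_map")
}

# --- small accessors shared with the generator -----------------------------

cube_counts <- function(cube) {
  if (inherits(cube, "omi_decay_cube")) cube$counts else cube
}

set_cube_counts <- function(cube, counts) {
  if (inherits(cube, "omi_decay_cube")) { cube$counts <- counts; cube }
  else counts
}

cube_channel <- function(cube) {
  if (inherits(cube, "omi_decay_cube")) cube$channel else NA_character_
}
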