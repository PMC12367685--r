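#' Construct a Gaussian instrument response function
#'
#' Builds a discretized instrument response function (IRF) on the TCSPC time
#' axis.  The IRF is modelled as a Gaussian of given full width at half
#' maximum centred at `t0_ps`, sampled at bin centres, truncated to the
#' acquisition window and normalized to unit sum.  A Gaussian is a standard
#' surrogate for a measured second-harmonic-generation IRF; measured IRFs can
#' be loaded with [read_irf()].
#'
#' @param fwhm_ps Full width at half maximum of the Gaussian, in picoseconds.
#'   Must be positive.  Values much smaller than `bin_width_ps` produce a
#'   delta-like IRF with all mass in the bin containing `t0_ps`.
#' @param bin_width_ps Width of one TCSPC time bin in picoseconds.
#' @param n_bins Number of time bins.
#' @param t0_ps Position of the IRF peak in picoseconds; must lie inside the
#'   window `[0, n_bins * bin_width_ps)`.
#' @return An object of class `omi_irf`: a list with elements `values`
#'   (length `n_bins`, non-negative, summing to 1), `bin_width_ps` and
#'   `t0_ps`.
#' @examples
#' irf <- make_irf(fwhm_ps = 250, bin_width_ps = 48.8, n_bins = 256,
#'                 t0_ps = 1200)
#' sum(irf$values)  # 1
#' @export
make_irf <- function(fwhm_ps, bin_width_ps, n_bins, t0_ps = 0) {
  if (!is.numeric(fwhm_ps) || length(fwhm_ps) != 1L || fwhm_ps <= 0)
    stop("'fwhm_ps' must be a single positive number")
  if (!is.numeric(bin_width_ps) || length(bin_width_ps) != 1L ||
      bin_width_ps <= 0)
    stop("'bin_width_ps' must be a single positive number")
  if (n_bins < 2L) stop("'n_bins' must be at least 2")
  window <- n_bins * bin_width_ps
  if (t0_ps < 0 || t0_ps >= window)
    stop("'t0_ps' must lie within [0, n_bins * bin_width_ps)")

  t <- bin_centers(n_bins, bin_width_ps)
  sigma <- fwhm_ps / (2 * sqrt(2 * log(2)))
  v <- exp(-0.5 * ((t - t0_ps) / sigma)^2)
  if (sum(v) <= 0 || !all(is.finite(v))) {
    # delta limit: Gaussian underflows everywhere, put all mass at t0's bin
    v <- numeric(n_bins)
    v[min(n_bins, floor(t0_ps / bin_width_ps) + 1L)] <- 1
  }
  new_irf(v / sum(v), bin_width_ps, t0_ps)
}

new_irf <- function(values, bin_width_ps, t0_ps) {
  structure(list(values = values, bin_width_ps = bin_width_ps,
                 t0_ps = t0_ps),
            class = "omi_irf")
}

#' Read a measured IRF from a JSON array or two-column CSV
#'
#' JSON input is an array of per-bin weights (or an object with a `values`
#' field plus optional `bin_width_ps`); CSV input has columns
#' `bin`/`value`.  Values are clipped checked for non-negativity and
#' renormalized to unit sum.
#'
#' @param path File path (`.json` or `.csv`).
#' @param bin_width_ps Bin width; required for CSV, optional for JSON when
#'   present in the file.
#' @return An `omi_irf` object; `t0_ps` is taken as the centre of the
#'   maximum bin.
#' @export
read_irf <- function(path, bin_width_ps = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.list(x) && !is.null(x$values)) {
      if (is.null(bin_width_ps)) bin_width_ps <- x$bin_width_ps
      v <- as.numeric(x$values)
    } else v <- as.numeric(x)
  } else {
    d <- utils::read.csv(path)
    v <- as.numeric(d$value)[order(as.numeric(d$bin))]
  }
  if (is.null(bin_width_ps))
    stop("'bin_width_ps' must be supplied when the file does not carry it")
  if (any(v < 0)) stop("IRF values must be non-negative")
  if (sum(v) <= 0) stop("IRF values must not all be zero")
  t0 <- (which.max(v) - 0.5) * bin_width_ps
  new_irf(v / sum(v), bin_width_ps, t0)
}

#' @export
print.omi_irf <- function(x, ...) {
  cat(sprintf("<omi_irf> %d bins x %.3g ps, peak at %.0f ps\n",
              length(x$values), x$bin_width_ps, x$t0_ps))
  invisible(x)
}

# centres of the TCSPC time bins, in ps
bin_centers <- function(n_bins, bin_width_ps) {
  (seq_len(n_bins) - 0.5) * bin_width_ps
}
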