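#' Optics / acquisition configuration for synthetic scenes
#'
#' Defaults mirror a standard 80 MHz TCSPC configuration: 256 time bins
#' spanning a 12.5 ns repetition period (bin width ~48.8 ps), 256 max field
#' and 0.5 um pixels.
#'
#' @param field Image size `c(rows, cols)` in pixels.
#' @param n_bins Number of TCSPC time bins.
#' @param laser_period_ps Repetition period in ps.
#' @param bin_width_ps Bin width; default spreads `n_bins` bins over the
#'   period.
#' @param pixel_size_um Pixel size in micrometres.
#' @return A list of class `omi_optics`.
#' @export
optics_config <- function(field = c(64, 64), n_bins = 256,
                          laser_period_ps = 12500,
                          bin_width_ps = laser_period_ps / n_bins,
                          pixel_size_um = 0.5) {
  if (n_bins * bin_width_ps > laser_period_ps + 1e-9)
    stop("acquisition window exceeds the laser period")
  structure(list(field = as.integer(field), n_bins = as.integer(n_bins),
                 laser_period_ps = laser_period_ps,
                 bin_width_ps = bin_width_ps,
                 pixel_size_um = pixel_size_um),
            class = "omi_optics")
}

#' Default per-condition decay-parameter distributions
#'
#' Two conditions emulating quiescent ("control") and PMA-activated
#' neutrophils.  Activation shifts NAD(P)H towards the free pool: lower
#' mean lifetime (shorter components), higher free fraction alpha1, and a
#' higher optical redox ratio.  Means are configuration, not measured
#' ground truth; the directions of the shifts are the biologically
#' established ones.
#'
#' @param effect Multiplier on the control-vs-PMA parameter shifts; `1` is
#'   the default scenario, `0` gives two identical conditions (a null
#'   scenario for calibration checks).
#' @return Named list of condition specifications consumed by
#'   [scenario_config()].
#' @export
default_conditions <- function(effect = 1) {
  ctrl <- list(
    nadph = c(alpha1 = 0.70, tau1 = 400, tau2 = 2500),
    fad   = c(alpha1 = 0.75, tau1 = 300, tau2 = 2500),
    redox = 0.55)
  pma <- list(
    nadph = c(alpha1 = 0.70 + 0.08 * effect, tau1 = 400 - 20 * effect,
              tau2 = 2500 - 200 * effect),
    fad   = c(alpha1 = 0.75 + 0.03 * effect, tau1 = 300 - 20 * effect,
              tau2 = 2500 - 100 * effect),
    redox = 0.55 + 0.07 * effect)
  list(control = ctrl, PMA = pma)
}

#' Scenario configuration for the synthetic TCSPC scene generator
#'
#' Describes the cell populations to simulate: per-condition means for the
#' biexponential decay parameters of both channels, between-cell standard
#' deviations, photon budgets and the cell geometry.
#'
#' @param conditions Named list as produced by [default_conditions()].
#' @param n_cells Cells per field (one field is rendered per condition).
#' @param sd Named list of between-cell SDs: `alpha1`, `tau1` (ps),
#'   `tau2` (ps), `redox`.
#' @param photon_budget Expected signal photons per pixel for the NAD(P)H
#'   channel (before spatial binning).  TCSPC instruments record count
#'   *rates*, not per-pixel totals, so this is a free parameter of the
#'   simulation.
#' @param background_counts Expected background counts per bin (offset `C`).
#' @param cell_radius_px Range (min, max) of ellipse semi-axes in pixels.
#' @param optics An [optics_config()].
#' @param allow_boundary If `TRUE`, cell centres may fall close enough to
#'   the field edge for the ellipse to be truncated (flagged in the truth
#'   table).
#' @return A list of class `omi_scenario`.
#' @export
scenario_config <- function(conditions = default_conditions(),
                            n_cells = 20,
                            sd = list(alpha1 = 0.02, tau1 = 15, tau2 = 80,
                                      redox = 0.03),
                            photon_budget = 1200,
                            background_counts = 0.05,
                            cell_radius_px = c(3.5, 6),
                            optics = optics_config(),
                            allow_boundary = FALSE) {
  if (length(conditions) == 0) stop("at least one condition is required")
  if (anyDuplicated(names(conditions)))
    stop("condition names must be unique")
  if (any(unlist(sd) < 0)) stop("all SDs must be non-negative")
  if (photon_budget < 0) stop("'photon_budget' must be non-negative")
  structure(list(conditions = conditions, n_cells = as.integer(n_cells),
                 sd = sd, photon_budget = photon_budget,
                 background_counts = background_counts,
                 cell_radius_px = cell_radius_px, optics = optics,
                 allow_boundary = allow_boundary),
            class = "omi_scenario")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw one condition's per-cell decay parameters (both channels) plus
# geometry.  Lifetimes are sorted per cell so tau1 <= tau2 always holds.
sample_condition <- function(cond_name, spec, n, sd, config) {
  draw_channel <- function(m) {
    a1 <- clip(stats::rnorm(n, m[["alpha1"]], sd$alpha1), 0.01, 0.99)
    t1 <- clip(stats::rnorm(n, m[["tau1"]], sd$tau1), 60, 9000)
    t2 <- clip(stats::rnorm(n, m[["tau2"]], sd$tau2), 60, 9000)
    swap <- t1 > t2
    tmp <- t1[swap]; t1[swap] <- t2[swap]; t2[swap] <- tmp
    a1[swap] <- 1 - a1[swap]
    list(alpha1 = a1, tau1 = t1, tau2 = t2)
  }
  np <- draw_channel(spec$nadph)
  fd <- draw_channel(spec$fad)
  redox <- clip(stats::rnorm(n, spec$redox, sd$redox), 0.05, 0.95)
  fld <- config$optics$field
  rr <- config$cell_radius_px
  ax <- stats::runif(n, rr[1], rr[2])
  ay <- stats::runif(n, rr[1], rr[2])
  geo <- place_cells(n, fld, ax, ay, config$allow_boundary)
  nadph_ph <- config$photon_budget
  data.frame(
    condition = cond_name, donor_id = "sim",
    nadph_alpha1 = np$alpha1, nadph_tau1 = np$tau1, nadph_tau2 = np$tau2,
    fad_alpha1 = fd$alpha1, fad_tau1 = fd$tau1, fad_tau2 = fd$tau2,
    redox_true = redox,
    nadph_photons = nadph_ph,
    fad_photons = nadph_ph * (1 - redox) / redox,
    background = config$background_counts,
    cx = geo$cx, cy = geo$cy, ax = ax, ay = ay,
    boundary_truncated = geo$boundary,
    stringsAsFactors = FALSE)
}

# Rejection-sample non-overlapping axis-aligned ellipse centres (overlap
# test uses bounding circles).  After 1000 failed attempts a cell is placed
# anyway, with a warning; overlap resolution at render time is
# deterministic (later cell_id wins).
place_cells <- function(n, field, ax, ay, allow_boundary,
                        max_attempts = 1000L) {
  cx <- cy <- numeric(n)
  r <- pmax(ax, ay)
  forced <- FALSE
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      mx <- if (allow_boundary) 0 else ax[i] + 1
      my <- if (allow_boundary) 0 else ay[i] + 1
      x <- stats::runif(1, mx, field[2] - mx)
      y <- stats::runif(1, my, field[1] - my)
      if (i == 1 ||
          all(sqrt((cx[seq_len(i - 1)] - x)^2 +
                   (cy[seq_len(i - 1)] - y)^2) >
              r[seq_len(i - 1)] + r[i] + 1)) {
        ok <- TRUE; break
      }
    }
    if (!ok) forced <- TRUE
    cx[i] <- x; cy[i] <- y
  }
  if (forced)
    warning("could not place all cells without overlap; later cell ids ",
            "overwrite earlier ones where masks collide")
  boundary <- (cx - ax < 0.5) | (cx + ax > field[2] + 0.5) |
    (cy - ay < 0.5) | (cy + ay > field[1] + 0.5)
  list(cx = cx, cy = cy, boundary = boundary)
}

#' Sample a ground-truth cell population
#'
#' Draws `n_cells` cells per condition from the configured parameter
#' distributions (Gaussian, clipped to valid ranges, lifetimes sorted so
#' `tau1 <= tau2`), assigns ellipse geometry by rejection sampling, and
#' returns one truth row per cell.  Deterministic for a fixed seed.
#'
#' @param config A [scenario_config()].
#' @param seed Integer master seed.
#' @return A `data.frame` of class `omi_truths`, one row per cell, with
#'   decay parameters for both channels, the true per-cell redox ratio,
#'   photon budgets, geometry and a `boundary_truncated` flag.  `cell_id`
#'   is unique across conditions.
#' @export
sample_population <- function(config, seed) {
  if (!inherits(config, "omi_scenario")) stop("'config' must be an omi_scenario")
  set.seed(as.integer(seed))
  parts <- lapply(names(config$conditions), function(nm)
    sample_condition(nm, config$conditions[[nm]], config$n_cells,
                     config$sd, config))
  out <- do.call(rbind, parts)
  out <- cbind(cell_id = seq_len(nrow(out)), out)
  class(out) <- c("omi_truths", "data.frame")
  out
}

# deterministic per-cell substream so adding a cell never shifts the noise
# of existing cells
cell_seed <- function(master, cell_id) {
  as.integer((as.double(master) * 48271 + as.double(cell_id) * 16807) %%
               2147483629)
}

#' Render one field of view into decay cubes and a label mask
#'
#' Forward model: every pixel of a cell carries that cell's expected decay
#' (the wrapped biexponential convolved with the IRF, scaled to its photon
#' budget) plus the flat background offset; background pixels carry only
#' the offset.  Per-bin counts are Poisson-sampled, each cell from its own
#' deterministic random substream.  Where ellipses overlap, the later
#' `cell_id` wins (with a warning at placement time).
#'
#' @param truths Truth rows for the cells of this field (typically one
#'   condition's subset of [sample_population()] output).
#' @param irf The IRF to convolve with; length must equal `optics$n_bins`.
#' @param optics An [optics_config()].
#' @param seed Master seed for the Poisson noise.
#' @param noise If `FALSE`, returns the noiseless expectation (non-integer
#'   counts); used for exact identity checks.
#' @return A list of class `omi_scene`: `nadph` and `fad` decay cubes
#'   (class `omi_decay_cube`), `mask` (integer label matrix, 0 =
#'   background), and `truths`.
#' @export
render_field <- function(truths, irf, optics = optics_config(), seed = 1,
                         noise = TRUE) {
  if (nrow(truths) == 0) stop("'truths' must contain at least one cell")
  if (length(irf$values) != optics$n_bins)
    stop("IRF length must match optics$n_bins")
  nr <- optics$field[1]; nc <- optics$field[2]; nb <- optics$n_bins
  tcent <- bin_centers(nb, optics$bin_width_ps)
  window <- nb * optics$bin_width_ps
  irf_fft <- stats::fft(irf$values)

  mask <- matrix(0L, nr, nc)
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  for (i in seq_len(nrow(truths))) {
    inside <- ((xs - truths$cx[i]) / truths$ax[i])^2 +
      ((ys - truths$cy[i]) / truths$ay[i])^2 <= 1
    mask[inside] <- truths$cell_id[i]
  }

  bg <- truths$background[1]
  render_channel <- function(prefix, photons_col) {
    arr <- array(0, dim = c(nr, nc, nb))
    flat <- matrix(arr, nr * nc, nb)  # pixels x bins view
    exp_bg <- rep(bg, nb)
    bg_idx <- which(mask == 0L)
    flat[bg_idx, ] <- matrix(exp_bg, length(bg_idx), nb, byrow = TRUE)
    for (i in seq_len(nrow(truths))) {
      px <- which(mask == truths$cell_id[i])
      if (length(px) == 0) next
      expd <- model_decay_core(
        truths[[paste0(prefix, "_alpha1")]][i],
        truths[[paste0(prefix, "_tau1")]][i],
        truths[[paste0(prefix, "_tau2")]][i],
        bg, truths[[photons_col]][i], irf_fft, tcent, window)
      flat[px, ] <- matrix(expd, length(px), nb, byrow = TRUE)
    }
    if (noise) {
      # background stream (cell id 0), then one substream per cell
      set.seed(cell_seed(seed, 0L))
      flat[bg_idx, ] <- matrix(
        stats::rpois(length(bg_idx) * nb, flat[bg_idx, ]),
        length(bg_idx), nb)
      for (i in seq_len(nrow(truths))) {
        px <- which(mask == truths$cell_id[i])
        if (length(px) == 0) next
        set.seed(cell_seed(seed, truths$cell_id[i]))
        flat[px, ] <- matrix(stats::rpois(length(px) * nb, flat[px, ]),
                             length(px), nb)
      }
    }
    structure(list(counts = array(flat, dim = c(nr, nc, nb)),
                   channel = if (prefix == "nadph") "NADPH" else "FAD",
                   bin_width_ps = optics$bin_width_ps,
                   laser_period_ps = optics$laser_period_ps,
                   pixel_size_um = optics$pixel_size_um,
                   seed = seed),
              class = "omi_decay_cube")
  }

  missing_ids <- setdiff(truths$cell_id, unique(as.vector(mask)))
  if (length(missing_ids) > 0)
    message("cells fully occluded in mask: ",
            paste(missing_ids, collapse = ", "))

  structure(list(nadph = render_channel("nadph", "nadph_photons"),
                 fad = render_channel("fad", "fad_photons"),
                 mask = mask, truths = truths),
            class = "omi_scene")
}

#' @export
print.omi_scene <- function(x, ...) {
  cat(sprintf("<omi_scene> %dx%d px, %d cells, conditions: %s\n",
              nrow(x$mask), ncol(x$mask), nrow(x$truths),
              paste(unique(x$truths$condition), collapse = ", ")))
  invisible(x)
}
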