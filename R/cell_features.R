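#' Per-pixel optical redox ratio map
#'
#' The optical redox ratio at each pixel is NAD(P)H / (NAD(P)H + FAD)
#' computed from the integrated intensities of the two channels.  Pixels
#' where both intensities are zero (or either is missing) are `NA` —
#' excluded, never coerced to 0.
#'
#' @param nadph_intensity,fad_intensity Co-registered intensity matrices.
#' @return Matrix of redox values in `[0, 1]`, `NA` where undefined.
#' @export
redox_map <- function(nadph_intensity, fad_intensity) {
  if (!all(dim(nadph_intensity) == dim(fad_intensity)))
    stop("intensity maps must have the same shape")
  denom <- nadph_intensity + fad_intensity
  out <- nadph_intensity / denom
  out[!is.na(denom) & denom == 0] <- NA_real_
  out
}

# ---- mask morphology -------------------------------------------------------

# second-moment eccentricity and convex-hull solidity of a pixel region
region_morphology <- function(px_y, px_x, pixel_size_um) {
  n <- length(px_y)
  area <- n * pixel_size_um^2
  if (n < 3) return(list(area_um2 = area, eccentricity = 0, solidity = 1))
  cv <- stats::cov(cbind(px_x, px_y)) * (n - 1) / n
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ecc <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))
  # hull over pixel corners so the hull encloses the full pixel area
  corners <- cbind(c(px_x - 0.5, px_x - 0.5, px_x + 0.5, px_x + 0.5),
                   c(px_y - 0.5, px_y + 0.5, px_y - 0.5, px_y + 0.5))
  h <- grDevices::chull(corners)
  hx <- corners[h, 1]; hy <- corners[h, 2]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  sol <- if (hull_area > 0) min(1, n / hull_area) else 1
  list(area_um2 = area, eccentricity = ecc, solidity = sol)
}

#' Extract per-cell OMI and morphology features
#'
#' Aggregates the per-pixel fit maps of both channels and the redox map
#' over a label mask: unweighted mean over each map's valid pixels inside
#' each cell, fractional amplitudes reported as percentages, plus mask
#' geometry (area, eccentricity, solidity).  Cells with fewer than
#' `min_pixels` pixels valid in both channels are dropped, with the reason
#' recorded in the `"dropped"` attribute.
#'
#' @param nadph_fits,fad_fits `omi_fit_map` objects from [fit_image()].
#' @param redox Redox matrix from [redox_map()].
#' @param mask Integer label matrix (0 = background).
#' @param metadata Named list merged into every row (e.g. `condition`,
#'   `donor_id`, `timepoint`).
#' @param pixel_size_um Pixel size for the area calculation.
#' @param min_pixels Minimum number of doubly-valid pixels per cell.
#' @return A `data.frame` of class `omi_cell_features`, one row per
#'   surviving cell; attribute `"dropped"` lists removed labels and
#'   reasons.
#' @export
extract_cell_features <- function(nadph_fits, fad_fits, redox, mask,
                                  metadata = list(), pixel_size_um = 0.5,
                                  min_pixels = 10L) {
  if (!all(dim(mask) == dim(nadph_fits$tau_m)))
    stop("mask and fit maps must have the same shape")
  labels <- sort(setdiff(unique(as.vector(mask)), 0L))
  rows <- list(); dropped <- list()
  for (lab in labels) {
    px <- which(mask == lab)
    both_valid <- sum(nadph_fits$valid[px] & fad_fits$valid[px])
    if (both_valid < min_pixels) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(cell_id = lab, rule = "too_few_valid_pixels")
      next
    }
    m <- function(map) mean(map[px], na.rm = TRUE)
    yx <- arrayInd(px, dim(mask))
    morph <- region_morphology(yx[, 1], yx[, 2], pixel_size_um)
    a1n <- m(nadph_fits$alpha1)
    row <- data.frame(
      cell_id = lab,
      nadph_tau_m = m(nadph_fits$tau_m),
      nadph_tau1 = m(nadph_fits$tau1),
      nadph_tau2 = m(nadph_fits$tau2),
      nadph_alpha1_pct = 100 * a1n,
      nadph_alpha2_pct = 100 * (1 - a1n),
      nadph_intensity = m(nadph_fits$intensity),
      fad_tau_m = m(fad_fits$tau_m),
      fad_tau1 = m(fad_fits$tau1),
      fad_tau2 = m(fad_fits$tau2),
      fad_alpha1_pct = 100 * m(fad_fits$alpha1),
      fad_intensity = m(fad_fits$intensity),
      redox_ratio = mean(redox[px], na.rm = TRUE),
      area_um2 = morph$area_um2,
      eccentricity = morph$eccentricity,
      solidity = morph$solidity,
      n_valid_pixels = both_valid)
    for (nm in names(metadata)) row[[nm]] <- metadata[[nm]]
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(0))
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(cell_id = integer(0), rule = character(0))
  class(out) <- c("omi_cell_features", "data.frame")
  out
}

# ---- cell exclusion rules --------------------------------------------------

#' Cell exclusion criteria
#'
#' @param border_rule Boundary rule (default on): cells whose mask touches
#'   the image border are removed when the majority of the cell lies
#'   outside the frame — for a convex cell, having less than 50% of its
#'   area inside the image is equivalent to its widest extent parallel to
#'   the touched border lying on the border itself, which is what is
#'   tested.  `FALSE` disables the rule.
#' @param area_range Optional `c(min, max)` cell area in um^2; proxies for
#'   the manual "small red blood cell / other cell type" size rules.
#' @param nadph_tau_m_range Optional `c(min, max)` on NAD(P)H mean
#'   lifetime in ps; proxies for the manual lifetime-based exclusion of
#'   non-neutrophil cells.
#' @return A list of class `omi_filter_criteria`.
#' @export
filter_criteria <- function(border_rule = TRUE, area_range = NULL,
                            nadph_tau_m_range = NULL) {
  structure(list(border_rule = isTRUE(border_rule),
                 area_range = area_range,
                 nadph_tau_m_range = nadph_tau_m_range),
            class = "omi_filter_criteria")
}

# Border-truncation test for a convex cell region.  A convex cell has
# less than half of its area inside the frame exactly when its centre
# lies on or beyond the border, i.e. when the cell's widest extent
# parallel to a touched border sits on the border row/column itself
# (the width profile of a convex shape is unimodal about its centre).
majority_truncated <- function(yx, nr, nc) {
  col_counts <- table(factor(yx[, 2], levels = 1:nc))
  row_counts <- table(factor(yx[, 1], levels = 1:nr))
  (col_counts[1] > 0 && col_counts[1] >= max(col_counts)) ||
    (col_counts[nc] > 0 && col_counts[nc] >= max(col_counts)) ||
    (row_counts[1] > 0 && row_counts[1] >= max(row_counts)) ||
    (row_counts[nr] > 0 && row_counts[nr] >= max(row_counts))
}

#' Apply cell exclusion rules to a feature table
#'
#' Implements the boundary rule (cells touching the image border with less
#' than half of their area inside the frame, decided by the convex-shape
#' width-profile test of [filter_criteria()]) plus optional area and
#' NAD(P)H mean-lifetime range rules.  Every removal is recorded with its
#' rule in the `"removals"` attribute.
#'
#' @param table An `omi_cell_features` table.
#' @param mask The label mask the table was extracted from.
#' @param criteria A [filter_criteria()].
#' @return The filtered table; attribute `"removals"` is a `data.frame`
#'   with `cell_id` and `rule`.
#' @export
filter_cells <- function(table, mask, criteria = filter_criteria()) {
  nr <- nrow(mask); nc <- ncol(mask)
  removed <- list()
  drop_ids <- integer(0)
  mark <- function(id, rule) {
    removed[[length(removed) + 1L]] <<- data.frame(cell_id = id,
                                                   rule = rule)
    drop_ids <<- c(drop_ids, id)
  }
  for (i in seq_len(nrow(table))) {
    id <- table$cell_id[i]
    px <- which(mask == id)
    yx <- arrayInd(px, dim(mask))
    touches <- any(yx[, 1] == 1L | yx[, 1] == nr |
                     yx[, 2] == 1L | yx[, 2] == nc)
    if (criteria$border_rule && touches &&
        majority_truncated(yx, nr, nc)) {
      mark(id, "boundary"); next
    }
    if (!is.null(criteria$area_range) &&
        (table$area_um2[i] < criteria$area_range[1] ||
         table$area_um2[i] > criteria$area_range[2])) {
      mark(id, "area"); next
    }
    if (!is.null(criteria$nadph_tau_m_range) &&
        (table$nadph_tau_m[i] < criteria$nadph_tau_m_range[1] ||
         table$nadph_tau_m[i] > criteria$nadph_tau_m_range[2])) {
      mark(id, "nadph_tau_m"); next
    }
  }
  out <- table[!(table$cell_id %in% drop_ids), , drop = FALSE]
  attr(out, "removals") <- if (length(removed)) do.call(rbind, removed)
  else data.frame(cell_id = integer(0), rule = character(0))
  attr(out, "dropped") <- attr(table, "dropped")
  class(out) <- class(table)
  out
}

#' Integrated density of an intensity z-stack
#'
#' Sum of pixel intensities over all slices, excluding pixels flagged as
#' background (e.g. not part of the imaged larva).  Used to quantify
#' whole-field oxidative-burst reporter signal per timepoint.
#'
#' @param zstack 3-d array `rows x cols x slices` (a single matrix is
#'   treated as one slice).
#' @param exclude Optional logical matrix (`TRUE` = exclude), applied to
#'   every slice.
#' @return Scalar integrated density.
#' @export
integrated_density <- function(zstack, exclude = NULL) {
  if (is.matrix(zstack)) zstack <- array(zstack, dim = c(dim(zstack), 1))
  if (length(zstack) == 0) stop("'zstack' must be non-empty")
  if (is.null(exclude)) return(sum(zstack))
  if (!all(dim(exclude) == dim(zstack)[1:2]))
    stop("'exclude' must match the slice shape")
  if (all(exclude)) stop("all pixels excluded; integrated density undefined")
  keep <- !as.vector(exclude)
  sum(apply(zstack, 3, function(sl) sum(sl[keep])))
}
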