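test_that("redox map handles symmetry, boundaries and degenerate pixels", {
  n <- matrix(c(100, 50, 0, 0), 2, 2)
  f <- matrix(c(100, 0, 80, 0), 2, 2)
  r <- redox_map(n, f)
  expect_equal(r[1, 1], 0.5)
  expect_equal(r[2, 1], 1.0)  # FAD = 0
  expect_equal(r[1, 2], 0.0)  # NAD(P)H = 0
  expect_true(is.na(r[2, 2]))  # both zero: excluded, not 0
  expect_error(redox_map(n, matrix(0, 3, 3)), "shape")
})

make_constant_fit_map <- function(mask, tau1, tau2, alpha1, intensity) {
  inside <- mask > 0
  mk <- function(v) { m <- matrix(NA_real_, nrow(mask), ncol(mask))
                      m[inside] <- v; m }
  structure(list(tau_m = mk(alpha1 * tau1 + (1 - alpha1) * tau2),
                 tau1 = mk(tau1), tau2 = mk(tau2), alpha1 = mk(alpha1),
                 C = mk(0), amplitude = mk(intensity),
                 intensity = mk(intensity),
                 chi2_red = mk(0.9), thresholded = inside,
                 converged = inside, valid = inside,
                 channel = "NADPH", config = NULL),
            class = "omi_fit_map")
}

test_that("constant-parameter cells are aggregated exactly", {
  mask <- matrix(0L, 10, 10); mask[3:7, 3:7] <- 1L
  nf <- make_constant_fit_map(mask, 400, 2500, 0.75, 900)
  ff <- make_constant_fit_map(mask, 300, 2400, 0.80, 600)
  rx <- redox_map(nf$intensity, ff$intensity)
  tab <- extract_cell_features(nf, ff, rx, mask,
                               metadata = list(condition = "control"),
                               pixel_size_um = 1)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$nadph_tau_m, 0.75 * 400 + 0.25 * 2500)
  expect_equal(tab$nadph_alpha1_pct, 75)
  expect_equal(tab$nadph_alpha1_pct + tab$nadph_alpha2_pct, 100)
  expect_equal(tab$fad_alpha1_pct, 80)
  expect_equal(tab$redox_ratio, 900 / 1500)
  expect_equal(tab$area_um2, 25)
  expect_equal(tab$n_valid_pixels, 25)
  expect_equal(tab$condition, "control")
})

test_that("feature table is invariant to label permutation", {
  mask <- matrix(0L, 12, 12)
  mask[2:4, 2:4] <- 1L; mask[7:10, 7:10] <- 2L
  nf <- make_constant_fit_map(mask, 400, 2500, 0.7, 800)
  ff <- make_constant_fit_map(mask, 300, 2400, 0.8, 500)
  rx <- redox_map(nf$intensity, ff$intensity)
  t1 <- extract_cell_features(nf, ff, rx, mask, pixel_size_um = 1,
                              min_pixels = 5)
  # relabel 1 <-> 2
  mask2 <- mask; mask2[mask == 1L] <- 2L; mask2[mask == 2L] <- 1L
  t2 <- extract_cell_features(nf, ff, rx, mask2, pixel_size_um = 1,
                              min_pixels = 5)
  expect_equal(t1$area_um2, rev(t2$area_um2))
  expect_equal(t1$nadph_tau_m, rev(t2$nadph_tau_m))
})

test_that("cells with too few valid pixels are dropped with a reason", {
  mask <- matrix(0L, 10, 10); mask[2:3, 2:3] <- 1L; mask[6:9, 6:9] <- 2L
  nf <- make_constant_fit_map(mask, 400, 2500, 0.7, 800)
  ff <- make_constant_fit_map(mask, 300, 2400, 0.8, 500)
  rx <- redox_map(nf$intensity, ff$intensity)
  tab <- extract_cell_features(nf, ff, rx, mask, pixel_size_um = 1,
                               min_pixels = 10)
  expect_equal(tab$cell_id, 2)
  dropped <- attr(tab, "dropped")
  expect_equal(dropped$cell_id, 1)
  expect_equal(dropped$rule, "too_few_valid_pixels")
})

test_that("boundary rule removes a half-truncated cell and only that cell", {
  # render two cells: one interior, one with its centre just outside the
  # left edge so less than half its ellipse is inside the frame
  irf <- test_irf()
  tr <- manual_truths(cx = c(16, -0.5), cy = c(12, 12), ax = 5, ay = 5,
                      photons = 1500, background = 0.05)
  opt <- small_optics(field = c(24, 24))
  sc <- render_field(tr, irf, opt, seed = 4)
  tab <- process_scene(sc, irf, metadata = list(condition = "control"))
  expect_setequal(tab$cell_id, c(1, 2))
  kept <- filter_cells(tab, sc$mask, filter_criteria())
  expect_equal(kept$cell_id, 1)
  rem <- attr(kept, "removals")
  expect_equal(rem$cell_id, 2)
  expect_equal(rem$rule, "boundary")
})

test_that("interior cells pass the boundary rule untouched", {
  mask <- matrix(0L, 20, 20); mask[5:10, 5:10] <- 1L
  nf <- make_constant_fit_map(mask, 400, 2500, 0.7, 800)
  ff <- make_constant_fit_map(mask, 300, 2400, 0.8, 500)
  rx <- redox_map(nf$intensity, ff$intensity)
  tab <- extract_cell_features(nf, ff, rx, mask, pixel_size_um = 1)
  kept <- filter_cells(tab, mask, filter_criteria())
  expect_equal(nrow(kept), 1)
  expect_equal(nrow(attr(kept, "removals")), 0)
})

test_that("area range rule removes out-of-range cells with rule tag", {
  mask <- matrix(0L, 20, 20); mask[5:10, 5:10] <- 1L  # 36 px = 9 um^2
  nf <- make_constant_fit_map(mask, 400, 2500, 0.7, 800)
  ff <- make_constant_fit_map(mask, 300, 2400, 0.8, 500)
  rx <- redox_map(nf$intensity, ff$intensity)
  tab <- extract_cell_features(nf, ff, rx, mask, pixel_size_um = 0.5)
  kept <- filter_cells(tab, mask, filter_criteria(area_range = c(20, 500)))
  expect_equal(nrow(kept), 0)
  expect_equal(attr(kept, "removals")$rule, "area")
})

test_that("integrated density sums slices and honours the exclusion mask", {
  st <- array(3, dim = c(2, 2, 2))
  expect_equal(integrated_density(st), 24)
  excl <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(integrated_density(st, excl), 12)
  expect_error(integrated_density(st, matrix(TRUE, 2, 2)), "excluded")
  set.seed(5)
  r <- array(runif(3 * 4 * 5), dim = c(3, 4, 5))
  brute <- 0
  for (z in 1:5) for (y in 1:3) for (x in 1:4) brute <- brute + r[y, x, z]
  expect_equal(integrated_density(r), brute)
})
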