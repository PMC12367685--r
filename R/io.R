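#' Write a decay cube as a multi-page TIFF with a JSON sidecar
#'
#' One 16-bit page per time bin (TZYX order: page index is the time bin),
#' plus `<path>.json` carrying channel, bin width, laser period, pixel
#' size and the generator seed.  Counts must fit in 16 bits.
#'
#' @param cube An `omi_decay_cube`.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_decay_cube <- function(cube, path) {
  arr <- cube$counts
  if (max(arr) > 65535)
    stop("counts exceed the 16-bit TIFF range")
  pages <- lapply(seq_len(dim(arr)[3]),
                  function(b) arr[, , b] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(channel = cube$channel, bin_width_ps = cube$bin_width_ps,
         laser_period_ps = cube$laser_period_ps,
         pixel_size_um = cube$pixel_size_um, seed = cube$seed,
         order = "TZYX"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a decay cube written by [write_decay_cube()]
#'
#' @param path `.tif` path; the `<path>.json` sidecar must sit beside it.
#' @return An `omi_decay_cube`.
#' @export
read_decay_cube <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                          length(pages)))
  for (b in seq_along(pages)) arr[, , b] <- pages[[b]]
  structure(list(counts = arr, channel = meta$channel,
                 bin_width_ps = meta$bin_width_ps,
                 laser_period_ps = meta$laser_period_ps,
                 pixel_size_um = meta$pixel_size_um, seed = meta$seed),
            class = "omi_decay_cube")
}

#' Write / read a 16-bit label mask TIFF (0 = background)
#'
#' @param mask Integer label matrix.
#' @param path `.tif` path.
#' @return `path` (write) or an integer matrix (read).
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535) stop("labels exceed the 16-bit TIFF range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Write a rendered scene (cubes, mask, truth table) to a directory
#'
#' @param scene An `omi_scene` from [render_field()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_decay_cube(scene$nadph, file.path(dir, "nadph.tif"))
  write_decay_cube(scene$fad, file.path(dir, "fad.tif"))
  write_label_mask(scene$mask, file.path(dir, "mask.tif"))
  utils::write.csv(as.data.frame(scene$truths),
                   file.path(dir, "truths.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  structure(list(
    nadph = read_decay_cube(file.path(dir, "nadph.tif")),
    fad = read_decay_cube(file.path(dir, "fad.tif")),
    mask = read_label_mask(file.path(dir, "mask.tif")),
    truths = utils::read.csv(file.path(dir, "truths.csv"))),
    class = "omi_scene")
}
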