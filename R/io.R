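# File round-tripping: multi-page TIFF (one page per time bin, 16-bit
# unsigned, little-endian) plus a JSON sidecar "<stem>.meta.json" carrying
# timing metadata and the pixel size.  Plain images are written as
# single-page 32-bit TIFF with a value scale recorded in the sidecar so the
# round trip is exact to ~2^-32 relative.

sidecar_path <- function(path) {
  paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".meta.json")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stopf("metadata sidecar not found: %s", sp,
          class = "phasorFSTM_metadata_error")
  jsonlite::fromJSON(sp)
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Write a TCSPC stack to a multi-page TIFF with JSON sidecar
#'
#' Time bins become TIFF pages (16-bit unsigned); timing metadata and pixel
#' size go to `<stem>.meta.json`.  The round trip through [read_stack()] is
#' bit-exact.
#'
#' @param stack A valid [tcspc_stack()].
#' @param path Output TIFF path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  bad <- validate_stack(stack)
  if (length(bad)) stopf("refusing to write invalid stack: %s",
                         paste(bad, collapse = "; "),
                         class = "phasorFSTM_validation_error")
  if (max(stack$counts) > 65535)
    stopf("counts exceed the 16-bit limit (max %d > 65535)",
          max(stack$counts), class = "phasorFSTM_overflow_error")
  tm <- stack$timing
  pages <- lapply(seq_len(tm$n_bins),
                  function(k) stack$counts[, , k] / 65535)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                                 compression = "LZW", reduce = FALSE),
                 error = function(e) stopf("cannot write %s: %s", path,
                                           conditionMessage(e),
                                           class = "phasorFSTM_io_error"))
  write_sidecar(path, list(kind = "tcspc_stack",
                           period_ns = tm$period_ns, n_bins = tm$n_bins,
                           bin_width_ns = tm$bin_width_ns,
                           gaussian_pulse_bin = tm$gaussian_pulse_bin,
                           donut_pulse_bin = tm$donut_pulse_bin,
                           pixel_size_nm = stack$pixel_size_nm))
  invisible(path)
}

#' Read a TCSPC stack written by [write_stack()]
#'
#' @param path TIFF path; the sidecar `<stem>.meta.json` must exist.
#' @return A validated [tcspc_stack()], bit-identical to what was written.
#' @export
read_stack <- function(path) {
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_bins)
    stopf("page count (%d) does not match sidecar n_bins (%d)",
          length(pages), meta$n_bins, class = "phasorFSTM_shape_error")
  d <- dim(pages[[1L]])
  counts <- array(as.integer(unlist(pages, use.names = FALSE)),
                  dim = c(d[1L], d[2L], length(pages)))
  if (any(counts < 0) || any(counts > 65535))
    stopf("counts out of the uint16 range on disk",
          class = "phasorFSTM_validation_error")
  timing <- timing_config(period_ns = meta$period_ns, n_bins = meta$n_bins,
                          gaussian_pulse_bin = meta$gaussian_pulse_bin,
                          donut_pulse_bin = meta$donut_pulse_bin,
                          bin_width_ns = meta$bin_width_ns)
  tcspc_stack(counts, timing, meta$pixel_size_nm)
}

#' Write a single-beam decay stack (same dialect as [write_stack()])
#'
#' @param decay A [decay_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_decay_stack <- function(decay, path) {
  if (max(decay$counts) > 65535)
    stopf("counts exceed the 16-bit limit", class = "phasorFSTM_overflow_error")
  pages <- lapply(seq_len(decay$window_len),
                  function(k) decay$counts[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW",
                  reduce = FALSE)
  write_sidecar(path, list(kind = "decay_stack",
                           beam_label = decay$beam_label,
                           window_origin_bin = decay$window_origin_bin,
                           window_len = decay$window_len,
                           bin_width_ns = decay$bin_width_ns,
                           pixel_size_nm = decay$pixel_size_nm))
  invisible(path)
}

#' @rdname write_decay_stack
#' @export
read_decay_stack <- function(path) {
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$window_len)
    stopf("page count (%d) does not match sidecar window_len (%d)",
          length(pages), meta$window_len, class = "phasorFSTM_shape_error")
  d <- dim(pages[[1L]])
  counts <- array(as.integer(unlist(pages, use.names = FALSE)),
                  dim = c(d[1L], d[2L], length(pages)))
  decay_stack(counts, meta$window_origin_bin, meta$bin_width_ns,
              meta$beam_label, meta$pixel_size_nm)
}

#' Write / read a plain intensity image (32-bit TIFF + sidecar scale)
#'
#' Values are stored scaled to `[0, 1]` at 32-bit depth with the scale kept
#' in the JSON sidecar, giving ~2^-32 relative round-trip accuracy.
#'
#' @param image An [intensity_image()].
#' @param path Output TIFF path.
#' @return `path` (write) or an [intensity_image()] (read).
#' @export
write_intensity_image <- function(image, path) {
  v <- image$values
  scale <- max(v)
  if (scale <= 0) scale <- 1
  tiff::writeTIFF(v / scale, path, bits.per.sample = 32L,
                  compression = "LZW", reduce = FALSE)
  write_sidecar(path, list(kind = "intensity_image", value_scale = scale,
                           pixel_size_nm = image$pixel_size_nm))
  invisible(path)
}

#' @rdname write_intensity_image
#' @export
read_intensity_image <- function(path) {
  meta <- read_sidecar(path)
  v <- tiff::readTIFF(path)
  if (is.list(v)) v <- v[[1L]]
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  intensity_image(v * meta$value_scale, meta$pixel_size_nm)
}
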