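# Quantitative evaluation: profile FWHM, signal-to-background ratio, and
# unmixing accuracy against ground truth.

#' Measure the FWHM of an intensity profile
#'
#' Samples the image along a line segment by bilinear interpolation, finds
#' the global peak, and returns the distance between the two half-maximum
#' crossings bracketing it, each located by linear interpolation between
#' samples.  The half-maximum level is half the peak value (zero
#' baseline).
#'
#' @param image An [intensity_image()].
#' @param line 2 x 2 matrix `rbind(p0, p1)` of endpoints in nm (x, y).
#' @param sampling_nm Sampling step along the line; defaults to a quarter
#'   pixel and must not exceed the pixel size.
#' @return A `profile_measurement` list: `endpoints`, `positions_nm`,
#'   `samples`, `peak_value`, `fwhm_nm` (NA when undefined), `defined`.
#' @export
measure_fwhm <- function(image, line, sampling_nm = NULL) {
  v <- image$values
  px <- image$pixel_size_nm
  if (is.null(sampling_nm)) sampling_nm <- px / 4
  if (sampling_nm > px)
    stopf("sampling_nm must be <= the pixel size",
          class = "phasorFSTM_parameter_error")
  line <- as.matrix(line)
  p0 <- line[1L, ]; p1 <- line[2L, ]
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) stopf("degenerate profile line",
                      class = "phasorFSTM_parameter_error")
  n <- max(2L, ceiling(len / sampling_nm) + 1L)
  tt <- seq(0, 1, length.out = n)
  xs <- p0[1L] + tt * (p1[1L] - p0[1L])
  ys <- p0[2L] + tt * (p1[2L] - p0[2L])
  prof <- bilinear_sample(v, xs, ys, px)
  pos <- tt * len
  res <- list(endpoints = line, positions_nm = pos, samples = prof,
              peak_value = max(prof), fwhm_nm = NA_real_, defined = FALSE)
  class(res) <- "profile_measurement"
  pk <- which.max(prof)
  half <- prof[pk] / 2
  if (prof[pk] <= 0) return(res)
  # left crossing: last index before the peak where profile < half
  left <- NA_real_
  for (i in rev(seq_len(pk - 1L))) {
    if (prof[i] < half) {
      frac <- (half - prof[i]) / (prof[i + 1L] - prof[i])
      left <- pos[i] + frac * (pos[i + 1L] - pos[i])
      break
    }
  }
  right <- NA_real_
  if (pk < n) for (i in pk:(n - 1L)) {
    if (prof[i + 1L] < half) {
      frac <- (prof[i] - half) / (prof[i] - prof[i + 1L])
      right <- pos[i] + frac * (pos[i + 1L] - pos[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(res)
  res$fwhm_nm <- right - left
  res$defined <- TRUE
  res
}

#' Mean FWHM over several profile lines
#'
#' @param image An [intensity_image()].
#' @param lines List of 2 x 2 endpoint matrices (nm); measurements that
#'   have no half-maximum crossing are reported and excluded.
#' @param sampling_nm Passed to [measure_fwhm()].
#' @return List with `mean_nm`, `se_nm`, `n`, `fwhm_nm` (per defined
#'   profile), and `n_excluded`.
#' @export
mean_fwhm <- function(image, lines, sampling_nm = NULL) {
  ms <- lapply(lines, function(ln) measure_fwhm(image, ln, sampling_nm))
  ok <- vapply(ms, `[[`, TRUE, "defined")
  if (sum(ok) < 2L)
    stopf("fewer than 2 profiles have a defined FWHM",
          class = "phasorFSTM_measurement_error")
  f <- vapply(ms[ok], `[[`, 0, "fwhm_nm")
  list(mean_nm = mean(f), se_nm = stats::sd(f) / sqrt(length(f)),
       n = length(f), fwhm_nm = f, n_excluded = sum(!ok))
}

#' Signal-to-background ratio
#'
#' Mean intensity over the signal mask divided by the mean over the
#' background mask.  A zero background mean yields `Inf`.
#'
#' @param image An [intensity_image()] or matrix.
#' @param signal_mask,background_mask Disjoint non-empty logical matrices.
#' @return The ratio (possibly `Inf`).
#' @export
compute_sbr <- function(image, signal_mask, background_mask) {
  v <- if (inherits(image, "intensity_image")) image$values else image
  if (!any(signal_mask) || !any(background_mask))
    stopf("masks must be non-empty", class = "phasorFSTM_parameter_error")
  if (any(signal_mask & background_mask))
    stopf("masks must be disjoint", class = "phasorFSTM_parameter_error")
  sig <- mean(v[signal_mask])
  bg <- mean(v[background_mask])
  if (bg == 0) Inf else sig / bg
}

#' Unmixing accuracy against a ground-truth label map
#'
#' Confusion-matrix scores over pixels with non-zero truth; unassigned
#' predictions (label 0) count as misses.
#'
#' @param predicted,truth Integer label matrices of identical shape.
#' @return List with `per_class` (data.frame of precision, recall, F1 per
#'   class), `macro_f1`, and the confusion `table`.
#' @export
assignment_scores <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth)))
    stopf("shapes disagree", class = "phasorFSTM_parameter_error")
  keep <- truth > 0
  if (!any(keep)) stopf("no non-zero truth pixels",
                        class = "phasorFSTM_measurement_error")
  p <- as.integer(predicted[keep])
  t_ <- as.integer(truth[keep])
  classes <- sort(unique(t_))
  tab <- table(factor(t_, levels = classes),
               factor(p, levels = c(0L, classes)))
  per <- data.frame(class = classes, precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(t_ == cl & p == cl)
    fp <- sum(t_ != cl & p == cl)
    fn <- sum(t_ == cl & p != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    per[i, 2:4] <- c(prec, rec, f1)
  }
  list(per_class = per, macro_f1 = mean(per$f1), table = tab)
}
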