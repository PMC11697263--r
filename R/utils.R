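# Internal helpers shared across modules.

stopf <- function(fmt, ..., class = "phasorFSTM_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

is_odd <- function(x) x %% 2L == 1L

check_odd <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || !is_odd(as.integer(x)))
    stopf("%s must be a single odd positive integer", name,
          class = "phasorFSTM_parameter_error")
  as.integer(x)
}

# Median filter that respects NA (undefined) pixels: an NA pixel stays NA,
# a defined pixel takes the median over its defined neighbours (incl. self).
median_filter_na <- function(m, kernel_px = 3L, passes = 1L) {
  kernel_px <- check_odd(kernel_px, "kernel_px")
  passes <- as.integer(passes)
  if (kernel_px == 1L || passes <= 0L) return(m)
  h <- (kernel_px - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  offs <- expand.grid(dr = -h:h, dc = -h:h)
  nao <- is.na(m)
  for (p in seq_len(passes)) {
    pad <- matrix(NA_real_, nr + 2L * h, nc + 2L * h)
    pad[h + seq_len(nr), h + seq_len(nc)] <- m
    stk <- matrix(NA_real_, nr * nc, nrow(offs))
    for (q in seq_len(nrow(offs))) {
      stk[, q] <- pad[(h + offs$dr[q]) + seq_len(nr),
                      (h + offs$dc[q]) + seq_len(nc)]
    }
    m <- matrix(apply(stk, 1L, stats::median, na.rm = TRUE), nr, nc)
    m[nao] <- NA_real_
  }
  m
}

# Bilinear interpolation of a matrix at physical coordinates (nm).
# x runs along columns, y along rows; pixel (r, c) is centred at
# ((c - 0.5) * px, (r - 0.5) * px).  Points outside the grid are clamped.
bilinear_sample <- function(values, x_nm, y_nm, pixel_size_nm) {
  nr <- nrow(values); nc <- ncol(values)
  fc <- x_nm / pixel_size_nm + 0.5
  fr <- y_nm / pixel_size_nm + 0.5
  fc <- pmin(pmax(fc, 1), nc)
  fr <- pmin(pmax(fr, 1), nr)
  c0 <- pmin(floor(fc), nc - 1L); r0 <- pmin(floor(fr), nr - 1L)
  wc <- fc - c0; wr <- fr - r0
  v00 <- values[cbind(r0, c0)]
  v01 <- values[cbind(r0, c0 + 1L)]
  v10 <- values[cbind(r0 + 1L, c0)]
  v11 <- values[cbind(r0 + 1L, c0 + 1L)]
  (1 - wr) * ((1 - wc) * v00 + wc * v01) + wr * ((1 - wc) * v10 + wc * v11)
}

# Circular FFT convolution machinery (used by Richardson-Lucy).
psf_otf <- function(psf, dims) {
  kr <- nrow(psf); kc <- ncol(psf)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  pad <- matrix(0, dims[1L], dims[2L])
  ridx <- ((-hr:hr) %% dims[1L]) + 1L
  cidx <- ((-hc:hc) %% dims[2L]) + 1L
  pad[ridx, cidx] <- pad[ridx, cidx] + psf
  stats::fft(pad)
}

conv_circ <- function(x, otf) {
  Re(stats::fft(stats::fft(x) * otf, inverse = TRUE)) / length(x)
}

# 8-connected component labelling by iterative minimum-label propagation.
label_components <- function(mask) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  shift_min <- function(l) {
    big <- max(l) + 1L
    l[l == 0L] <- big
    up    <- rbind(l[-1L, , drop = FALSE], big)
    down  <- rbind(big, l[-nr, , drop = FALSE])
    left  <- cbind(l[, -1L, drop = FALSE], big)
    right <- cbind(big, l[, -nc, drop = FALSE])
    ul <- rbind(cbind(l[-1L, -1L, drop = FALSE], big), big)
    ur <- rbind(cbind(big, l[-1L, -nc, drop = FALSE]), big)
    dl <- rbind(big, cbind(l[-nr, -1L, drop = FALSE], big))
    dr <- rbind(big, cbind(big, l[-nr, -nc, drop = FALSE]))
    out <- pmin(l, up, down, left, right, ul, ur, dl, dr)
    out[!mask] <- 0L
    out
  }
  repeat {
    nxt <- shift_min(lab)
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  ids <- sort(unique(lab[lab > 0L]))
  matrix(match(lab, ids, nomatch = 0L), nr, nc) * (lab > 0L)
}

named_list <- function(...) {
  out <- list(...)
  stopifnot(!is.null(names(out)))
  out
}
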