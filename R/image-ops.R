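# Low-level image primitives shared across modules. Images are numeric arrays
# indexed [row, col] or [row, col, channel], intensities in [0, 1]; masks are
# integer matrices with the same row/col convention.

#' 2-D convolution with zero padding ("same" output size)
#'
#' Direct convolution used by the filter networks. The kernel is applied in
#' correlation orientation (no flipping), matching the convention of deep
#' learning frameworks.
#'
#' @param x numeric matrix.
#' @param kernel numeric matrix with odd dimensions.
#' @return Matrix of the same size as `x`.
#' @keywords internal
conv2d_same <- function(x, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  h <- nrow(x); w <- ncol(x)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- matrix(0, h + 2 * ph, w + 2 * pw)
  xp[(ph + 1):(ph + h), (pw + 1):(pw + w)] <- x
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      k <- kernel[i, j]
      if (k != 0) out <- out + k * xp[(i):(i + h - 1), (j):(j + w - 1)]
    }
  }
  out
}

#' Separable Gaussian smoothing with reflective boundaries
#'
#' @param x numeric matrix.
#' @param sigma standard deviation in pixels; `sigma = 0` returns `x`.
#' @param radius kernel half-width; defaults to `ceiling(4 * sigma)`.
#' @return Smoothed matrix, same size.
#' @export
gaussian_smooth <- function(x, sigma, radius = NULL) {
  stopifnot(is.matrix(x), is_scalar_number(sigma), sigma >= 0)
  if (sigma == 0) return(x)
  r <- radius %||% ceiling(4 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  reflect_idx <- function(n, r) {
    idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - rev(seq_len(min(r, n))))
    if (r > n) dm_abort("gaussian_smooth: radius exceeds image size")
    idx
  }
  # rows
  xp <- x[reflect_idx(nrow(x), r), , drop = FALSE]
  tmp <- matrix(0, nrow(x), ncol(x))
  for (i in seq_along(k)) tmp <- tmp + k[i] * xp[(i):(i + nrow(x) - 1), , drop = FALSE]
  # cols
  xp <- tmp[, reflect_idx(ncol(x), r), drop = FALSE]
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_along(k)) out <- out + k[i] * xp[, (i):(i + ncol(x) - 1), drop = FALSE]
  out
}

#' Bilinear resize (align-corners off)
#'
#' Resamples a matrix to a new size using bilinear interpolation with
#' half-pixel centre alignment: output pixel centre `(i - 0.5) / h_out` maps to
#' input coordinate `(i - 0.5) * h_in / h_out`, clamped to the valid range.
#' This is the convention used for Delta-Map upscaling and is the one the
#' brute-force oracle in the test-suite re-implements.
#'
#' @param x numeric matrix.
#' @param h_out,w_out target size in pixels.
#' @return `h_out` x `w_out` matrix.
#' @export
bilinear_resize <- function(x, h_out, w_out) {
  stopifnot(is.matrix(x), h_out >= 1, w_out >= 1)
  h <- nrow(x); w <- ncol(x)
  src <- function(n_out, n_in) {
    pos <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
    pmin(pmax(pos, 0), n_in - 1)
  }
  ry <- src(h_out, h); rx <- src(w_out, w)
  y0 <- floor(ry); x0 <- floor(rx)
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- ry - y0; fx <- rx - x0
  a <- x[cbind(rep(y0 + 1, w_out), rep(x0 + 1, each = h_out))]
  b <- x[cbind(rep(y0 + 1, w_out), rep(x1 + 1, each = h_out))]
  c_ <- x[cbind(rep(y1 + 1, w_out), rep(x0 + 1, each = h_out))]
  d <- x[cbind(rep(y1 + 1, w_out), rep(x1 + 1, each = h_out))]
  fy_m <- matrix(fy, h_out, w_out)
  fx_m <- matrix(fx, h_out, w_out, byrow = TRUE)
  top <- matrix(a, h_out, w_out) * (1 - fx_m) + matrix(b, h_out, w_out) * fx_m
  bot <- matrix(c_, h_out, w_out) * (1 - fx_m) + matrix(d, h_out, w_out) * fx_m
  top * (1 - fy_m) + bot * fy_m
}

#' Label connected components of a binary mask
#'
#' Two-pass flood fill. Components are numbered 1..n in raster order of their
#' first pixel.
#'
#' @param mask logical or 0/1 matrix; nonzero pixels are foreground.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of labels, 0 for background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  fg <- mask != 0
  lab <- matrix(0L, h, w)
  if (connectivity == 8) {
    di <- c(-1, -1, -1, 0, 0, 1, 1, 1); dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    di <- c(-1, 0, 0, 1); dj <- c(0, -1, 1, 0)
  }
  current <- 0L
  idx_fg <- which(fg)
  for (start in idx_fg) {
    if (lab[start] != 0L) next
    current <- current + 1L
    stack <- start
    lab[start] <- current
    while (length(stack) > 0) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pi <- ((p - 1) %% h) + 1
      pj <- ((p - 1) %/% h) + 1
      ni <- pi + di; nj <- pj + dj
      ok <- ni >= 1 & ni <= h & nj >= 1 & nj <= w
      q <- (nj[ok] - 1) * h + ni[ok]
      q <- q[fg[q] & lab[q] == 0L]
      if (length(q)) {
        lab[q] <- current
        stack <- c(stack, q)
      }
    }
  }
  lab
}

# Ruifrok-Johnston H&E(D) stain vectors (rows: hematoxylin, eosin, DAB),
# the standard published deconvolution basis.
hed_stain_matrix <- function() {
  m <- rbind(
    c(0.65, 0.70, 0.29),
    c(0.07, 0.99, 0.11),
    c(0.27, 0.57, 0.78)
  )
  m / sqrt(rowSums(m^2))
}

#' Convert an RGB image to HED stain concentrations
#'
#' Linear colour deconvolution in optical-density space with the standard
#' hematoxylin/eosin/DAB basis. Inverse of [hed_to_rgb()].
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @return H x W x 3 array of stain concentrations (H, E, D).
#' @export
rgb_to_hed <- function(image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  eps <- 1e-6
  od <- -log(pmax(image, eps))
  h <- dim(image)[1]; w <- dim(image)[2]
  flat <- matrix(od, h * w, 3)
  conc <- flat %*% solve(hed_stain_matrix())
  array(conc, dim = c(h, w, 3))
}

#' Render HED stain concentrations back to RGB
#'
#' @param hed H x W x 3 array of stain concentrations.
#' @return H x W x 3 RGB array in \[0, 1\].
#' @export
hed_to_rgb <- function(hed) {
  stopifnot(length(dim(hed)) == 3, dim(hed)[3] == 3)
  h <- dim(hed)[1]; w <- dim(hed)[2]
  flat <- matrix(hed, h * w, 3)
  od <- flat %*% hed_stain_matrix()
  array(pmin(pmax(exp(-od), 0), 1), dim = c(h, w, 3))
}
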