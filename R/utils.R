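# internal numeric helpers shared across modules

#' @importFrom stats dnorm rnorm rlnorm rbinom median mad approx lm coef plnorm integrate uniroot sd
#' @importFrom utils read.table write.csv head
NULL

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

.is_pos <- function(x) is.numeric(x) && all(is.finite(x)) && all(x > 0)

# 1-D Gaussian blur along one axis of a 3-D array, by shift-and-add with a
# truncated normalized kernel. Edge weights are renormalized so constant
# fields are preserved exactly and total intensity away from the boundary is
# conserved.
.blur_axis3d <- function(a, sigma, axis) {
  if (sigma <= 0) return(a)
  R <- max(1L, ceiling(3 * sigma))
  w <- dnorm(-R:R, 0, sigma)
  w <- w / sum(w)
  d <- dim(a)
  L <- d[axis]
  out <- array(0, d)
  norm <- numeric(L)
  for (j in seq_along(w)) {
    k <- j - R - 1L                 # offset in [-R, R]
    src <- max(1L, 1L + k):min(L, L + k)
    dst <- src - k
    norm[dst] <- norm[dst] + w[j]
    if (axis == 1L) out[dst, , ] <- out[dst, , ] + w[j] * a[src, , ]
    else if (axis == 2L) out[, dst, ] <- out[, dst, ] + w[j] * a[, src, ]
    else out[, , dst] <- out[, , dst] + w[j] * a[, , src]
  }
  sweep(out, axis, norm, "/")
}

.blur3d <- function(a, sigma_px) {
  a <- .blur_axis3d(a, sigma_px[1L], 1L)
  a <- .blur_axis3d(a, sigma_px[2L], 2L)
  .blur_axis3d(a, sigma_px[3L], 3L)
}

# linear upsampling of a 3-D array to target dims (used to lift a coarse
# smooth random field to voxel resolution without a full-resolution blur)
.upsample_axis3d <- function(a, n_out, axis) {
  n_in <- dim(a)[axis]
  if (n_in == n_out) return(a)
  # map output sample positions onto the input grid (cell-centered)
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  pos <- pmin(pmax(pos, 1), n_in)
  lo <- pmin(floor(pos), n_in - 1L)
  fr <- pos - lo
  idx <- function(i) switch(axis, a[i, , , drop = FALSE],
                            a[, i, , drop = FALSE], a[, , i, drop = FALSE])
  lo_part <- idx(lo)
  hi_part <- idx(lo + 1L)
  out <- sweep(lo_part, axis, 1 - fr, "*") + sweep(hi_part, axis, fr, "*")
  dim(out) <- replace(dim(a), axis, n_out)
  out
}

.upsample3d <- function(a, dims) {
  a <- .upsample_axis3d(a, dims[1L], 1L)
  a <- .upsample_axis3d(a, dims[2L], 2L)
  .upsample_axis3d(a, dims[3L], 3L)
}

# Otsu threshold of an intensity sample, delegated to EBImage on the
# normalized histogram. Returns the threshold on the original scale.
.otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  xn <- (x - rng[1L]) / diff(rng)
  m <- matrix(xn, nrow = 1L)
  thr <- EBImage::otsu(EBImage::Image(m), range = c(0, 1), levels = levels)
  rng[1L] + thr * diff(rng)
}
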