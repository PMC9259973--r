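# Conversion between multi-channel rasters and GA patch vectors.
#
# A pixel (R, G, B) in [0,1] is encoded as the multivector
# 0 + R*g1 + G*g2 + B*g12: the scalar slot is structurally zero and the
# three channels ride on the three non-scalar blades, so channel correlation
# survives every algebraic operation downstream.

#' Encode an RGB image as a GA image
#'
#' @param rgb An H x W x 3 numeric array with values in `[0, 1]`.  Values
#'   outside the unit range are min-max rescaled with a warning.
#' @return A `ga_image`: a [ga_array] of shape H x W whose `e0` plane is
#'   identically zero.
#' @export
encode_image <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("encode_image(): expected an H x W x 3 array")
  if (!all(is.finite(rgb))) stop("encode_image(): non-finite pixel values")
  rng <- range(rgb)
  if (rng[1L] < 0 || rng[2L] > 1) {
    warning(sprintf(
      "encode_image(): values outside [0,1] (range %.4g..%.4g); rescaling",
      rng[1L], rng[2L]))
    lo <- min(0, rng[1L]); hi <- max(1, rng[2L])
    rgb <- (rgb - lo) / (hi - lo)
  }
  H <- dim(rgb)[1L]; W <- dim(rgb)[2L]
  ch <- function(i) matrix(rgb[, , i], H, W)
  img <- new_ga_array(matrix(0, H, W), ch(1L), ch(2L), ch(3L))
  class(img) <- c("ga_image", class(img))
  img
}

#' Decode a GA image back to an RGB array
#'
#' The non-scalar planes become the R, G, B channels, clipped to `[0, 1]`.
#' Residual energy in the scalar slot (which reconstruction from a full
#' multivector dictionary can introduce) is discarded; if its largest entry
#' exceeds `e0_tolerance` the amount discarded is reported via `message()`.
#'
#' @param img A `ga_image` (or any H x W [ga_array]).
#' @param e0_tolerance Audit threshold on `max(abs(e0))`.
#' @return An H x W x 3 array in `[0, 1]`.
#' @export
decode_image <- function(img, e0_tolerance = 0.05) {
  stopifnot(is_ga_array(img), length(ga_dim(img)) == 2L)
  m <- max(abs(img$e0))
  if (m > e0_tolerance)
    message(sprintf(
      "decode_image(): discarding scalar residue (max |e0| = %.4g, rms = %.4g)",
      m, sqrt(mean(img$e0^2))))
  out <- array(0, c(ga_dim(img), 3L))
  out[, , 1L] <- img$e1
  out[, , 2L] <- img$e2
  out[, , 3L] <- img$e12
  pmin(pmax(out, 0), 1)
}

#' Extract sliding-window patches from a GA image
#'
#' Each `n x n` window is flattened column-major into a length `n^2` GA
#' vector; windows are enumerated row-major over their top-left corners at
#' the given step.
#'
#' @param img An H x W [ga_array].
#' @param n Patch side length (`n >= 2`, `n <= min(H, W)`).
#' @param step Window step in pixels (default 1, the dense sliding window).
#' @return A `ga_patchset`: list with `vectors` (an `n^2 x K` [ga_array]),
#'   `positions` (K x 2 matrix of 0-based top-left `(row, col)` corners, in
#'   row-major scan order), `patch_size`, `step` and `source_shape`.
#' @export
extract_patches <- function(img, n, step = 1L) {
  stopifnot(is_ga_array(img), length(ga_dim(img)) == 2L)
  d <- ga_dim(img); H <- d[1L]; W <- d[2L]
  n <- as.integer(n); step <- as.integer(step)
  if (n < 1L || n > min(H, W))
    stop("extract_patches(): patch size must satisfy 1 <= n <= min(H, W)")
  if (step < 1L) stop("extract_patches(): step must be >= 1")
  rows <- seq.int(1L, H - n + 1L, by = step)
  cols <- seq.int(1L, W - n + 1L, by = step)
  # row-major corner order: rows vary fastest within each... corners are
  # scanned row by row, i.e. column index varies fastest
  pos <- cbind(row = rep(rows, each = length(cols)) - 1L,
               col = rep(cols, times = length(rows)) - 1L)
  K <- nrow(pos)
  comp <- function(P) {
    out <- matrix(0, n * n, K)
    for (j in seq_len(n)) for (i in seq_len(n)) {
      out[(j - 1L) * n + i, ] <- P[cbind(pos[, 1L] + i, pos[, 2L] + j)]
    }
    out
  }
  vectors <- new_ga_array(comp(img$e0), comp(img$e1), comp(img$e2),
                          comp(img$e12))
  structure(list(vectors = vectors, positions = pos, patch_size = n,
                 step = step, source_shape = c(H, W)),
            class = "ga_patchset")
}

#' @export
print.ga_patchset <- function(x, ...) {
  cat(sprintf(
    "<ga_patchset: %d patches of %dx%d (step %d) from a %dx%d image>\n",
    nrow(x$positions), x$patch_size, x$patch_size, x$step,
    x$source_shape[1L], x$source_shape[2L]))
  invisible(x)
}

#' Per-pixel patch coverage counts
#'
#' @param patches A `ga_patchset` (or any list with `positions`,
#'   `patch_size`, `source_shape`).
#' @return An H x W integer matrix of how many patches cover each pixel.
#' @export
patch_coverage <- function(patches) {
  H <- patches$source_shape[1L]; W <- patches$source_shape[2L]
  n <- patches$patch_size
  cnt <- matrix(0L, H, W)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    idx <- cbind(patches$positions[, 1L] + i, patches$positions[, 2L] + j)
    cnt[idx] <- cnt[idx] + 1L
  }
  cnt
}

#' Rebuild a GA image from (possibly modified) patches by overlap averaging
#'
#' Each pixel is the arithmetic mean of every patch entry covering it, which
#' makes `reconstruct_image(extract_patches(X, n))` the identity.
#'
#' @param patches A `ga_patchset` whose `vectors` may have been replaced by
#'   processed columns of the same shape.
#' @return An H x W `ga_image`.
#' @export
reconstruct_image <- function(patches) {
  stopifnot(inherits(patches, "ga_patchset"))
  H <- patches$source_shape[1L]; W <- patches$source_shape[2L]
  n <- patches$patch_size
  if (ga_dim(patches$vectors)[1L] != n * n ||
      ga_dim(patches$vectors)[2L] != nrow(patches$positions))
    stop("reconstruct_image(): vectors inconsistent with positions")
  cnt <- patch_coverage(patches)
  if (any(cnt == 0L)) {
    bad <- which(cnt == 0L, arr.ind = TRUE)
    stop(sprintf(
      "reconstruct_image(): %d pixel(s) covered by no patch (first at row %d, col %d, 0-based); use step = 1 or a finer grid",
      nrow(bad), bad[1L, 1L] - 1L, bad[1L, 2L] - 1L))
  }
  acc <- function(V) {
    S <- matrix(0, H, W)
    for (j in seq_len(n)) for (i in seq_len(n)) {
      idx <- cbind(patches$positions[, 1L] + i, patches$positions[, 2L] + j)
      S[idx] <- S[idx] + V[(j - 1L) * n + i, ]
    }
    S / cnt
  }
  V <- patches$vectors
  img <- new_ga_array(acc(matrix(V$e0, n * n)), acc(matrix(V$e1, n * n)),
                      acc(matrix(V$e2, n * n)), acc(matrix(V$e12, n * n)))
  class(img) <- c("ga_image", class(img))
  img
}
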