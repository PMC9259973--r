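# Fusion-quality metrics between a fused image and its two sources.
# Every metric is reported as the mean of its two fused-vs-source terms,
# with the per-source sub-scores exposed so other conventions can be
# recomputed from the report.

as_img3 <- function(x, what) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3L] != 3L)
    stop(what, " must be an H x W x 3 array")
  x
}

check_same_shape <- function(F, S1, S2) {
  if (!identical(dim(F), dim(S1)) || !identical(dim(F), dim(S2)))
    stop("images must share one shape")
}

#' Correlation coefficient between a fused image and its sources
#'
#' Mean over the two sources of the Pearson correlation between the
#' flattened all-channel pixel vectors.
#'
#' @param F,S1,S2 H x W x 3 arrays of one shape.
#' @return A single real in `[-1, 1]`.
#' @export
fusion_cc <- function(F, S1, S2) {
  check_same_shape(F, S1, S2)
  one <- function(S) {
    if (stats::sd(as.vector(F)) == 0 || stats::sd(as.vector(S)) == 0)
      stop("fusion_cc(): zero-variance image; correlation undefined")
    stats::cor(as.vector(F), as.vector(S))
  }
  sub <- c(one(S1), one(S2))
  structure(mean(sub), per_source = sub)
}

#' Root-mean-square error between a fused image and its sources
#'
#' Mean over the two sources of the root-mean-square pixel difference over
#' all channels (unit intensity range).
#'
#' @inheritParams fusion_cc
#' @return A single nonnegative real.
#' @export
fusion_rmse <- function(F, S1, S2) {
  check_same_shape(F, S1, S2)
  sub <- c(sqrt(mean((F - S1)^2)), sqrt(mean((F - S2)^2)))
  structure(mean(sub), per_source = sub)
}

#' Peak signal-to-noise ratio between a fused image and its sources
#'
#' Mean over the two sources of `20 * log10(peak / rms_s)`.  An exact match
#' gives an infinite term, which is capped at `cap` dB and flagged.
#'
#' @inheritParams fusion_cc
#' @param peak Peak intensity (1 for unit-range floats).
#' @param cap Sentinel used in place of infinite terms (dB).
#' @return A single real (dB) with attributes `per_source` and `capped`.
#' @export
fusion_psnr <- function(F, S1, S2, peak = 1, cap = 120) {
  check_same_shape(F, S1, S2)
  sub <- c(psnr_pair(F, S1, peak), psnr_pair(F, S2, peak))
  capped <- !is.finite(sub)
  sub[capped] <- cap
  structure(mean(sub), per_source = sub, capped = any(capped))
}

luminance <- function(x) {
  if (length(dim(x)) == 3L) (x[, , 1L] + x[, , 2L] + x[, , 3L]) / 3 else x
}

joint_entropy_pair <- function(a, b, bins) {
  ia <- pmin(floor(pmin(pmax(a, 0), 1) * bins) + 1L, bins)
  ib <- pmin(floor(pmin(pmax(b, 0), 1) * bins) + 1L, bins)
  p <- table(factor(ia, levels = seq_len(bins)),
             factor(ib, levels = seq_len(bins)))
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Joint entropy between a fused image and its sources
#'
#' Mean over the two sources of the Shannon entropy (base 2) of the joint
#' `bins x bins` histogram of channel-mean luminance values.
#'
#' @inheritParams fusion_cc
#' @param bins Histogram bins per axis (default 256, matching 8-bit
#'   marginals).
#' @return A single nonnegative real (bits).
#' @export
joint_entropy <- function(F, S1, S2, bins = 256L) {
  check_same_shape(F, S1, S2)
  lf <- luminance(F)
  sub <- c(joint_entropy_pair(lf, luminance(S1), bins),
           joint_entropy_pair(lf, luminance(S2), bins))
  structure(mean(sub), per_source = sub)
}

#' Full fusion-quality report
#'
#' @inheritParams fusion_cc
#' @param bins Joint-entropy histogram bins.
#' @param peak PSNR peak intensity.
#' @return A `fusion_metrics` list with `cc`, `joint_entropy`, `psnr`,
#'   `rmse`, the per-source sub-scores and the parameters used.
#' @export
fusion_metrics <- function(F, S1, S2, bins = 256L, peak = 1) {
  F <- as_img3(F, "F"); S1 <- as_img3(S1, "S1"); S2 <- as_img3(S2, "S2")
  cc <- fusion_cc(F, S1, S2)
  je <- joint_entropy(F, S1, S2, bins)
  ps <- fusion_psnr(F, S1, S2, peak)
  rm <- fusion_rmse(F, S1, S2)
  structure(list(
    cc = as.numeric(cc), joint_entropy = as.numeric(je),
    psnr = as.numeric(ps), rmse = as.numeric(rm),
    per_source = list(cc = attr(cc, "per_source"),
                      joint_entropy = attr(je, "per_source"),
                      psnr = attr(ps, "per_source"),
                      rmse = attr(rm, "per_source")),
    psnr_capped = attr(ps, "capped"),
    parameters = list(bins = as.integer(bins), peak = peak)),
    class = "fusion_metrics")
}

#' @export
print.fusion_metrics <- function(x, ...) {
  cat("Fusion quality (mean over the two sources):\n")
  cat(sprintf("  CC            %.5f\n", x$cc))
  cat(sprintf("  Joint entropy %.4f bits\n", x$joint_entropy))
  cat(sprintf("  PSNR          %.4f dB%s\n", x$psnr,
              if (isTRUE(x$psnr_capped)) " (capped term)" else ""))
  cat(sprintf("  RMSE          %.4f\n", x$rmse))
  invisible(x)
}
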