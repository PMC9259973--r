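# End-to-end GA-SR fusion of two co-registered source images:
# encode -> sliding-window patches -> one shared dictionary (K-GASVD on the
# pooled patches) -> GAOMP codes per source -> per-column L1-max selection ->
# reconstruct x_F = D a_F -> overlap-average -> decode.

#' Fusion configuration
#'
#' @param patch_size Sliding-window side `n` (default 8, giving length-64
#'   patch vectors).
#' @param step Window step (default 1, the dense sliding window; larger
#'   steps trade quality for speed and must still cover every pixel).
#' @param atoms Dictionary size `M` (default 256).  A warning is issued when
#'   `M < patch_size^2` (undercomplete dictionary).
#' @param sparsity Per-patch atom budget `J` (default 8).
#' @param train_iters K-GASVD iterations (default 20).
#' @param tol Relative residual tolerance for the coder (default `1e-6`).
#' @param seed Master seed; all randomness (dictionary init, training-patch
#'   subsampling) derives from it.
#' @param e0_tolerance Audit threshold for scalar residue at decode.
#' @param train_patches Maximum number of pooled patches used for dictionary
#'   training (default 10000); sampled without replacement under `seed` when
#'   the pool is larger.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(patch_size = 8L, step = 1L, atoms = 256L,
                          sparsity = 8L, train_iters = 20L, tol = 1e-6,
                          seed = 0L, e0_tolerance = 0.05,
                          train_patches = 10000L) {
  cfg <- list(patch_size = as.integer(patch_size), step = as.integer(step),
              atoms = as.integer(atoms), sparsity = as.integer(sparsity),
              train_iters = as.integer(train_iters), tol = tol,
              seed = as.integer(seed), e0_tolerance = e0_tolerance,
              train_patches = as.integer(train_patches))
  if (cfg$patch_size < 2L) stop("fusion_config(): patch_size must be >= 2")
  if (cfg$step < 1L) stop("fusion_config(): step must be >= 1")
  if (cfg$sparsity < 1L) stop("fusion_config(): sparsity must be >= 1")
  if (cfg$train_iters < 1L) stop("fusion_config(): train_iters must be >= 1")
  if (cfg$atoms < cfg$patch_size^2)
    warning("fusion_config(): dictionary is undercomplete (atoms < patch_size^2)")
  class(cfg) <- "fusion_config"
  cfg
}

#' GA L1 norm of a coefficient vector
#'
#' The sum of the multivector magnitudes of the entries — the GA reading of
#' "sum of absolute values of the elements" used by the L1-max fusion rule.
#'
#' @param a A [ga_array].
#' @return A nonnegative real.
#' @export
l1_norm <- function(a) {
  stopifnot(is_ga_array(a))
  sum(ga_magnitude(a))
}

#' Fuse two sparse coefficient matrices by the L1-max rule
#'
#' Column `i` of the result is the source-1 column when its GA L1 norm is
#' `>=` the source-2 column's, otherwise the source-2 column; ties go to
#' source 1.  The rule selects whole columns, never blends them.
#'
#' @param A1,A2 M x K [ga_array] coefficient matrices of equal shape.
#' @return A list with `AF` (the fused M x K [ga_array]) and `mask`
#'   (integer vector: 1 or 2, the winning source per column).
#' @export
fuse_coefficients <- function(A1, A2) {
  stopifnot(is_ga_array(A1), is_ga_array(A2))
  if (!identical(ga_dim(A1), ga_dim(A2)))
    stop("fuse_coefficients(): shape mismatch")
  n1 <- colSums(ga_magnitude(A1))
  n2 <- colSums(ga_magnitude(A2))
  take1 <- n1 >= n2
  pick <- function(C1, C2) { C1[, !take1] <- C2[, !take1, drop = FALSE]; C1 }
  AF <- new_ga_array(pick(A1$e0, A2$e0), pick(A1$e1, A2$e1),
                     pick(A1$e2, A2$e2), pick(A1$e12, A2$e12))
  list(AF = AF, mask = ifelse(take1, 1L, 2L))
}

#' Fuse two co-registered RGB images with GA-SR
#'
#' Runs the full pipeline: both images are GA-encoded, cut into sliding
#' window patches, one shared dictionary is trained with [kgasvd()] on the
#' pooled (optionally subsampled) patches, both patch sets are sparse-coded
#' with GAOMP, coefficient columns are fused by the L1-max rule, fused
#' patches `x_F = D a_F` are overlap-averaged and decoded.  Fully
#' deterministic given `cfg$seed`.
#'
#' @param img1,img2 H x W x 3 arrays in `[0, 1]`, co-registered and of
#'   identical shape.
#' @param cfg A [fusion_config()].
#' @param dictionary Optional pre-trained [ga_dictionary]; when supplied,
#'   training is skipped.
#' @param verbose Print per-stage timings.
#' @return A `fusion_result`: list with `fused` (H x W x 3 array), `mask`
#'   (per-patch winning source), `dictionary`, `A1`, `A2`, `AF`
#'   (coefficient matrices), `config` and `timings` (seconds per stage).
#' @export
fuse_images <- function(img1, img2, cfg = fusion_config(),
                        dictionary = NULL, verbose = FALSE) {
  if (!identical(dim(img1), dim(img2)))
    stop("fuse_images(): source images must have identical shape")
  if (length(dim(img1)) != 3L || dim(img1)[3L] != 3L)
    stop("fuse_images(): sources must be H x W x 3 arrays")
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, t0) {
    timings[[name]] <<- tic() - t0
    if (verbose) message(sprintf("  %-12s %.2fs", name, timings[[name]]))
  }

  t0 <- tic()
  q1 <- encode_image(img1)
  q2 <- encode_image(img2)
  P1 <- extract_patches(q1, cfg$patch_size, cfg$step)
  P2 <- extract_patches(q2, cfg$patch_size, cfg$step)
  stage("extract", t0)

  if (is.null(dictionary)) {
    t0 <- tic()
    pool <- new_ga_array(cbind(P1$vectors$e0, P2$vectors$e0),
                         cbind(P1$vectors$e1, P2$vectors$e1),
                         cbind(P1$vectors$e2, P2$vectors$e2),
                         cbind(P1$vectors$e12, P2$vectors$e12))
    Kp <- ga_dim(pool)[2L]
    if (Kp > cfg$train_patches) {
      pick <- with_local_seed(cfg$seed + 1L, sample.int(Kp, cfg$train_patches))
      pool <- pool[, pick, drop = FALSE]
    }
    state <- kgasvd(pool, M = cfg$atoms, J = cfg$sparsity,
                    iters = cfg$train_iters, seed = cfg$seed, tol = cfg$tol)
    dictionary <- state$dictionary
    dictionary$meta <- c(dictionary$meta,
                         list(patch_size = cfg$patch_size, J = cfg$sparsity,
                              train_iters = cfg$train_iters,
                              provenance = "trained on pooled source patches"))
    stage("train", t0)
  } else {
    stopifnot(inherits(dictionary, "ga_dictionary"))
    if (dict_len(dictionary) != cfg$patch_size^2)
      stop("fuse_images(): dictionary atom length ", dict_len(dictionary),
           " does not match patch_size^2 = ", cfg$patch_size^2)
  }

  t0 <- tic()
  A1 <- code_patchset(P1, dictionary, J = cfg$sparsity, tol = cfg$tol)
  A2 <- code_patchset(P2, dictionary, J = cfg$sparsity, tol = cfg$tol)
  stage("code", t0)

  t0 <- tic()
  fc <- fuse_coefficients(A1, A2)
  XF <- ga_matmul(dictionary$atoms, fc$AF)
  PF <- P1
  PF$vectors <- XF
  QF <- reconstruct_image(PF)
  fused <- decode_image(QF, cfg$e0_tolerance)
  stage("fuse", t0)

  structure(list(fused = fused, mask = fc$mask, dictionary = dictionary,
                 A1 = A1, A2 = A2, AF = fc$AF, config = cfg,
                 timings = unlist(timings)),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  d <- dim(x$fused)
  cat(sprintf(
    "<fusion_result: %dx%d fused image, %d patches (%.1f%% from source 1)>\n",
    d[1L], d[2L], length(x$mask), 100 * mean(x$mask == 1L)))
  invisible(x)
}
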