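# Deterministic synthetic benchmarks: pseudo-colour phantom pairs with a
# known ground-truth scene, and GA sparse-recovery problems with a known
# dictionary and codes.  Phantoms imitate the look of functional
# nuclear-medicine pseudo-colour (smooth radial intensity blobs over a dark
# background, plus a few sharp structures); they are rendering stand-ins,
# not simulations of any imaging physics.

default_palette <- matrix(c(
  1.0, 0.15, 0.10,   # red-hot
  1.0, 0.80, 0.00,   # yellow
  0.20, 1.0, 0.25,   # green
  0.10, 0.45, 1.0,   # blue
  1.0, 0.40, 0.05),  # orange
  ncol = 3L, byrow = TRUE)

#' Generate a complementary phantom image pair with known ground truth
#'
#' Builds a ground-truth scene of smooth Gaussian colour blobs plus sharp
#' rectangular structures, then derives two complementary degradations:
#' each source reveals a different spatial part of the scene, so the truth
#' is recoverable only from both.  Same seed, same arguments: bit-identical
#' output.
#'
#' @param size Image side (`>= 32`); images are `size x size`.
#' @param seed Integer seed.
#' @param n_blobs Number of smooth colour blobs.
#' @param palette K x 3 matrix of RGB colours sampled for blobs and
#'   structures.
#' @param edge_density Approximate fraction of pixels covered by sharp
#'   structures (drives how many rectangles are drawn).
#' @param complement_mode How information is split across the pair:
#'   `"halves"` (source 1 keeps the left half, source 2 the right) or
#'   `"checker"` (alternating blocks of side `size/8`).
#' @param noise_sd Standard deviation of additive Gaussian noise (per
#'   channel, clipped to `[0, 1]`); 0 for noiseless.
#' @return A list with `img1`, `img2`, `truth` (each `size x size x 3`) and
#'   `spec` (the arguments).
#' @export
make_phantom_pair <- function(size = 64L, seed = 1L, n_blobs = 6L,
                              palette = default_palette,
                              edge_density = 0.05,
                              complement_mode = c("halves", "checker"),
                              noise_sd = 0) {
  size <- as.integer(size)
  if (size < 32L) stop("make_phantom_pair(): size must be >= 32")
  complement_mode <- match.arg(complement_mode)
  with_local_seed(seed, {
    xs <- matrix(rep(seq_len(size), each = size), size)   # column index
    ys <- matrix(rep(seq_len(size), times = size), size)  # row index
    truth <- array(0, c(size, size, 3L))
    for (b in seq_len(n_blobs)) {
      cx <- runif(1, 0.15, 0.85) * size
      cy <- runif(1, 0.15, 0.85) * size
      sg <- runif(1, size / 12, size / 5)
      amp <- runif(1, 0.5, 1)
      col <- palette[sample.int(nrow(palette), 1L), ]
      g <- amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sg^2))
      for (ch in 1:3) truth[, , ch] <- truth[, , ch] + col[ch] * g
    }
    n_rect <- max(1L, round(edge_density * size / 4))
    for (r in seq_len(n_rect)) {
      w <- sample(seq(3L, max(4L, size %/% 8L)), 1L)
      h <- sample(seq(3L, max(4L, size %/% 8L)), 1L)
      r0 <- sample.int(size - h, 1L)
      c0 <- sample.int(size - w, 1L)
      col <- palette[sample.int(nrow(palette), 1L), ] * runif(1, 0.6, 1)
      for (ch in 1:3) truth[r0 + seq_len(h), c0 + seq_len(w), ch] <- col[ch]
    }
    truth <- pmin(truth, 1)
    mask1 <- matrix(0, size, size)
    if (complement_mode == "halves") {
      mask1[, seq_len(size %/% 2L)] <- 1
    } else {
      blk <- max(1L, size %/% 8L)
      bi <- ((ys - 1L) %/% blk + (xs - 1L) %/% blk) %% 2L
      mask1[bi == 0L] <- 1
    }
    apply_mask <- function(m) {
      out <- truth
      for (ch in 1:3) out[, , ch] <- out[, , ch] * m
      if (noise_sd > 0)
        out <- out + array(rnorm(length(out), sd = noise_sd), dim(out))
      pmin(pmax(out, 0), 1)
    }
    img1 <- apply_mask(mask1)
    img2 <- apply_mask(1 - mask1)
    list(img1 = img1, img2 = img2, truth = truth,
         spec = list(size = size, seed = as.integer(seed),
                     n_blobs = as.integer(n_blobs),
                     edge_density = edge_density,
                     complement_mode = complement_mode,
                     noise_sd = noise_sd))
  })
}

# Mutual coherence of a GA dictionary: max over atom pairs i != j of the
# magnitude of the GA correlation sum_n gp(reverse(d_i), d_j) -- the same
# quantity GAOMP ranks atoms by.
dict_coherence <- function(D) {
  G <- crossprod(ga_embed(D$atoms))      # 4M x 4M
  M <- dict_natoms(D)
  best <- 0
  for (i in seq_len(M - 1L)) {
    ri <- 4L * (i - 1L) + 1L
    for (j in seq.int(i + 1L, M)) {
      cj <- 4L * (j - 1L) + 1L
      v <- G[ri:(ri + 3L), cj]           # correlation components of (i, j)
      best <- max(best, sqrt(sum(v^2)))
    }
  }
  best
}

#' Generate a GA sparse-recovery problem with known ground truth
#'
#' Draws a random unit-norm GA dictionary, k-sparse GA coefficient columns
#' with entry magnitudes in `[0.5, 2]`, and assembles `Q = D A (+ noise)`.
#'
#' @param N Signal length (GA entries per column).
#' @param M Number of atoms (`k < N <= M`).
#' @param k Exact number of nonzero multivector entries per column.
#' @param K_cols Number of signal columns.
#' @param noise_sd Standard deviation of additive Gaussian noise on every
#'   real component of `Q` (0 for noiseless).
#' @param seed Integer seed.
#' @param coef_type `"ga"` (default): nonzero coefficients are full
#'   multivectors with uniform direction on the component 3-sphere;
#'   `"scalar"`: signed scalar-blade gains.  GA-SR atoms are identifiable
#'   from data only up to right multiplication by an invertible multivector,
#'   so dictionary-recovery benchmarks use scalar gains (which pin that
#'   gauge, exactly as in the classical K-SVD benchmark), while sparse-coding
#'   benchmarks use the full GA coefficients.
#' @return A list with `D_true` ([ga_dictionary]), `A_true` (M x K_cols
#'   [ga_array]), `support` (k x K_cols matrix of true atom indices), `Q`
#'   (N x K_cols [ga_array]), `coherence` (mutual coherence of `D_true`)
#'   and the parameters.
#' @export
make_sparse_problem <- function(N, M, k, K_cols = 1L, noise_sd = 0,
                                seed = 1L, coef_type = c("ga", "scalar")) {
  if (!(k < N && N <= M)) stop("make_sparse_problem(): need k < N <= M")
  coef_type <- match.arg(coef_type)
  with_local_seed(seed, {
    rmat <- function() matrix(rnorm(N * M), N, M)
    D <- ga_dictionary(new_ga_array(rmat(), rmat(), rmat(), rmat()),
                       normalize = TRUE)
    A <- ga_zeros(c(M, K_cols))
    support <- matrix(0L, k, K_cols)
    for (j in seq_len(K_cols)) {
      idx <- sort(sample.int(M, k))
      support[, j] <- idx
      if (coef_type == "ga") {
        dirs <- matrix(rnorm(4L * k), 4L, k)
        dirs <- sweep(dirs, 2L, sqrt(colSums(dirs^2)), "/")
      } else {
        dirs <- rbind(sample(c(-1, 1), k, replace = TRUE),
                      matrix(0, 3L, k))
      }
      mags <- runif(k, 0.5, 2)
      A$e0[idx, j] <- dirs[1L, ] * mags
      A$e1[idx, j] <- dirs[2L, ] * mags
      A$e2[idx, j] <- dirs[3L, ] * mags
      A$e12[idx, j] <- dirs[4L, ] * mags
    }
    Q <- ga_matmul(D$atoms, A)
    if (noise_sd > 0) {
      nz <- function(x) x + matrix(rnorm(length(x), sd = noise_sd), nrow(x))
      Q <- new_ga_array(nz(Q$e0), nz(Q$e1), nz(Q$e2), nz(Q$e12))
    }
    list(D_true = D, A_true = A, support = support, Q = Q,
         coherence = dict_coherence(D),
         params = list(N = N, M = M, k = k, K_cols = K_cols,
                       noise_sd = noise_sd, seed = as.integer(seed),
                       coef_type = coef_type))
  })
}
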