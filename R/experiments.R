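# Benchmark experiments on synthetic ground truth: how reconstruction PSNR
# and atom recovery depend on dictionary size, the synthetic analogue of
# sweeping the atom count in the fusion pipeline.

#' Match learned atoms to reference atoms by embedding cosine
#'
#' Greedy one-to-one matching on the absolute cosine between interleaved
#' real component columns (sign- and permutation-invariant).
#'
#' @param learned,reference [ga_dictionary] objects with atoms of one GA
#'   length.
#' @return A numeric vector, one entry per reference atom: the cosine of its
#'   greedily matched learned atom (NA when `learned` has fewer atoms).
#' @export
match_atoms <- function(learned, reference) {
  L <- ga_interleave(learned$atoms)
  R <- ga_interleave(reference$atoms)
  C <- abs(crossprod(L, R))          # M_learned x M_ref cosines (unit atoms)
  out <- rep(NA_real_, ncol(R))
  for (step in seq_len(min(ncol(L), ncol(R)))) {
    ij <- arrayInd(which.max(C), dim(C))
    out[ij[2L]] <- C[ij[1L], ij[2L]]
    C[ij[1L], ] <- -1
    C[, ij[2L]] <- -1
  }
  out
}

#' Reconstruction PSNR and atom recovery versus dictionary size
#'
#' For each seed, draws a sparse problem from a known `M_true`-atom GA
#' dictionary (scalar-gain codes, which pin the gauge of the learned atoms),
#' trains K-GASVD dictionaries of each size in `M`, and records the
#' reconstruction PSNR of the training signals plus the fraction of true
#' atoms recovered at cosine `>= cos_cut`.
#'
#' @param N GA signal length.
#' @param M Integer vector of dictionary sizes to train.
#' @param k_sparse Nonzeros per training column (also the coding budget `J`).
#' @param n_train Number of training columns.
#' @param noise_sd Noise level of the training data.
#' @param seeds Integer vector of seeds (one experiment replicate each).
#' @param M_true Size of the generating dictionary (default `max(M)`).
#' @param iters K-GASVD iterations per fit.
#' @param cos_cut Cosine threshold counting an atom as recovered.
#' @param plot Draw a PSNR-versus-atom-count curve (base graphics).
#' @return A data.frame with one row per `(M, seed)`: `M`, `seed`, `psnr`
#'   (dB, reconstruction of the training signals, peak = max multivector
#'   magnitude of the data) and `recovery_rate`.
#' @export
atom_recovery_experiment <- function(N = 16L, M = c(8L, 16L, 24L, 32L),
                                     k_sparse = 2L, n_train = 1000L,
                                     noise_sd = 0, seeds = 1L,
                                     M_true = max(M), iters = 15L,
                                     cos_cut = 0.99, plot = FALSE) {
  stopifnot(length(M) >= 1L, length(seeds) >= 1L)
  rows <- list()
  for (seed in seeds) {
    prob <- make_sparse_problem(N, M_true, k_sparse, n_train,
                                noise_sd = noise_sd, seed = seed,
                                coef_type = "scalar")
    Yr <- ga_interleave(prob$Q)
    peak <- max(ga_magnitude(prob$Q))
    for (m in M) {
      st <- kgasvd(prob$Q, M = m, J = k_sparse, iters = iters, seed = seed)
      rec <- ga_matmul(st$dictionary$atoms, st$codes)
      ps <- psnr_pair(Yr, ga_interleave(rec), peak = peak)
      rate <- mean(match_atoms(st$dictionary, prob$D_true) >= cos_cut,
                   na.rm = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(M = m, seed = seed, psnr = ps, recovery_rate = rate)
    }
  }
  out <- do.call(rbind, rows)
  if (plot) {
    agg <- stats::aggregate(psnr ~ M, data = out, FUN = mean)
    graphics::plot(agg$M, agg$psnr, type = "b", pch = 19,
                   xlab = "dictionary atoms M",
                   ylab = "reconstruction PSNR (dB)",
                   main = "K-GASVD: PSNR vs dictionary size")
  }
  out
}
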