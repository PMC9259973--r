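# K-GASVD: alternating GAOMP sparse coding and per-atom dictionary updates
# on GA-valued training data.
#
# The atom update takes the leading left singular vector of the restricted
# error matrix in its 4N x |Omega| component embedding, de-interleaves it
# into a unit-norm GA atom, and refits the atom's code row over Omega by
# least squares given that atom.  Because the de-interleaved atom is a
# projection onto GA-structured atoms (not the unconstrained real rank-1
# optimum), each candidate update is accepted only when it does not increase
# the fit error on Omega; the sweep is therefore non-increasing by
# construction, and on scalar-blade-only data the whole procedure reduces
# exactly to classical K-SVD.

#' Initialise a dictionary from training patches
#'
#' Samples `M` distinct nonzero training columns without replacement under
#' the seed and normalises each to unit GA Frobenius norm.
#'
#' @param P A `ga_patchset` or an N x K [ga_array] of training columns.
#' @param M Number of atoms (`M <=` number of usable columns).
#' @param seed Integer seed; fixed seed gives an identical dictionary.
#' @return A [ga_dictionary].
#' @export
init_dictionary <- function(P, M, seed = 0L) {
  V <- if (is_ga_array(P)) P else P$vectors
  stopifnot(is_ga_array(V), length(ga_dim(V)) == 2L)
  K <- ga_dim(V)[2L]
  norms <- sqrt(colSums(V$e0^2 + V$e1^2 + V$e2^2 + V$e12^2))
  usable <- which(norms > 0)
  if (M > K) stop("init_dictionary(): M (", M, ") exceeds the number of ",
                  "training columns (", K, ")")
  if (M > length(usable))
    stop("init_dictionary(): only ", length(usable),
         " nonzero training columns available for M = ", M)
  pick <- with_local_seed(seed, sample(usable, M))
  ga_dictionary(V[, pick, drop = FALSE], normalize = TRUE,
                meta = list(init = "sampled-columns", seed = as.integer(seed)))
}

# Dictionary refresh between iterations (standard K-SVD housekeeping): any
# atom that is a near-duplicate of a lower-indexed atom (embedding cosine >
# dup_cut) or that fewer than min_use columns used is replaced by the
# currently worst-represented training column.  Near-identical atoms are the
# signature of the local minima of the alternation — two atoms lock onto one
# generator while another generator goes unmodelled — and refreshing them is
# what lets the sweep escape.
.refresh_dictionary <- function(D, Ar, Rr, Yr, dup_cut = 0.99,
                                min_use = 4L) {
  M <- ga_dim(D)[2L]
  emb <- ga_interleave(D)                 # 4N x M component columns
  C <- abs(crossprod(emb))
  use <- integer(M)
  for (k in seq_len(M))
    use[k] <- sum(colSums(abs(Ar[4L * (k - 1L) + 1:4, , drop = FALSE])) > 0)
  col_res <- colSums(Rr^2)
  order_res <- order(col_res, decreasing = TRUE)
  next_col <- 1L
  for (k in seq_len(M)) {
    dup <- k > 1L && any(C[seq_len(k - 1L), k] > dup_cut)
    if (!dup && use[k] >= min_use) next
    u <- NULL
    while (next_col <= length(order_res)) {
      cand <- Yr[, order_res[next_col]]
      next_col <- next_col + 1L
      un <- sqrt(sum(cand^2))
      if (un > 1e-12) { u <- cand / un; break }
    }
    if (is.null(u)) break
    dnew <- ga_deinterleave(u)
    D$e0[, k] <- dnew$e0; D$e1[, k] <- dnew$e1
    D$e2[, k] <- dnew$e2; D$e12[, k] <- dnew$e12
    emb[, k] <- u
    C <- abs(crossprod(emb))
  }
  D
}

# One atom update on the embedded training state.  All matrices use the
# interleaved real layout of ga_interleave()/ga_embed().
# Returns list(D, Demb, Ar, Rr, changed).
.update_atom_embed <- function(k, D, Demb, Ar, Rr, Yr) {
  rows <- 4L * (k - 1L) + 1:4
  Arow <- Ar[rows, , drop = FALSE]
  omega <- which(colSums(abs(Arow)) > 0)
  if (length(omega) == 0L) {
    # unused atom: replace by the worst-represented training column
    j <- which.max(colSums(Rr^2))
    u <- Yr[, j]
    un <- sqrt(sum(u^2))
    if (un <= 1e-12) return(list(D = D, Demb = Demb, Ar = Ar, Rr = Rr,
                                 changed = FALSE))
    u <- u / un
    dnew <- ga_deinterleave(u)
    D$e0[, k] <- dnew$e0; D$e1[, k] <- dnew$e1
    D$e2[, k] <- dnew$e2; D$e12[, k] <- dnew$e12
    Demb[, rows] <- ga_embed(dnew)
    return(list(D = D, Demb = Demb, Ar = Ar, Rr = Rr, changed = TRUE))
  }
  Bk <- Demb[, rows, drop = FALSE]
  Ek <- Rr[, omega, drop = FALSE] + Bk %*% Arow[, omega, drop = FALSE]
  # leading left singular vector of Ek via the smaller Gram matrix
  u <- tryCatch({
    if (ncol(Ek) <= nrow(Ek)) {
      ev <- eigen(crossprod(Ek), symmetric = TRUE)
      w <- ev$vectors[, 1L]
      u <- as.vector(Ek %*% w)
      un <- sqrt(sum(u^2))
      if (un <= 1e-14) NULL else u / un
    } else {
      ev <- eigen(tcrossprod(Ek), symmetric = TRUE)
      ev$vectors[, 1L]
    }
  }, error = function(e) {
    message("update_atom(): SVD failed for atom ", k, " (", conditionMessage(e),
            "); atom left unchanged")
    NULL
  })
  if (is.null(u))
    return(list(D = D, Demb = Demb, Ar = Ar, Rr = Rr, changed = FALSE))
  u <- u * sign(u[which.max(abs(u))])        # deterministic sign
  dnew <- ga_deinterleave(u)                 # unit GA Frobenius norm
  Bnew <- ga_embed(dnew)                     # 4N x 4
  X <- tryCatch(solve(crossprod(Bnew), crossprod(Bnew, Ek)),
                error = function(e) qr.solve(Bnew, Ek))
  new_res2 <- sum((Ek - Bnew %*% X)^2)
  old_res2 <- sum(Rr[, omega]^2)
  if (new_res2 >= old_res2)                  # monotonicity safeguard
    return(list(D = D, Demb = Demb, Ar = Ar, Rr = Rr, changed = FALSE))
  D$e0[, k] <- dnew$e0; D$e1[, k] <- dnew$e1
  D$e2[, k] <- dnew$e2; D$e12[, k] <- dnew$e12
  Demb[, rows] <- Bnew
  Ar[rows, ] <- 0
  Ar[rows, omega] <- X
  Rr[, omega] <- Ek - Bnew %*% X
  list(D = D, Demb = Demb, Ar = Ar, Rr = Rr, changed = TRUE)
}

#' One K-GASVD atom update
#'
#' Functional form of the per-atom dictionary update: columns whose support
#' contains atom `k` define the restricted error matrix; its leading
#' singular direction (component embedding, de-interleaved) becomes the new
#' atom and the code row over those columns is refit by least squares.  An
#' unused atom is replaced by the worst-represented training column.  The
#' update is kept only if it does not increase the fit error.
#'
#' @param k Atom index.
#' @param state A list with `dictionary` (a [ga_dictionary]) and `codes`
#'   (an M x K [ga_array]), as returned by [kgasvd()].
#' @param Y The training data: a `ga_patchset` or N x K [ga_array].
#' @return The updated state (same structure, with refreshed
#'   `error_history` tail entry named `error`).
#' @export
update_atom <- function(k, state, Y) {
  V <- if (is_ga_array(Y)) Y else Y$vectors
  D <- state$dictionary$atoms
  Demb <- ga_embed(D)
  Ar <- ga_interleave(state$codes)
  Yr <- ga_interleave(V)
  Rr <- Yr - Demb %*% Ar
  up <- .update_atom_embed(as.integer(k), D, Demb, Ar, Rr, Yr)
  state$dictionary <- ga_dictionary(up$D, normalize = FALSE,
                                    meta = state$dictionary$meta)
  state$codes <- ga_deinterleave(up$Ar)
  state$error <- sqrt(mean(up$Rr^2))
  state
}

#' Learn a GA dictionary with K-GASVD
#'
#' Alternates [code_patchset()] (GAOMP sparse coding) with a full sweep of
#' per-atom updates, recording the root-mean-square reconstruction error
#' over all `4*N*K` real components once per completed iteration.
#'
#' @param P A `ga_patchset` or N x K [ga_array] of training columns.
#' @param M Number of atoms.
#' @param J Sparsity budget per column.
#' @param iters Number of coding/update iterations (`>= 1`).
#' @param seed Seed for the initial dictionary.
#' @param tol Relative residual tolerance passed to the coder.
#' @param verbose Print per-iteration error.
#' @return A `ga_train_state`: list with `dictionary`, `codes` (M x K
#'   [ga_array]), `iteration` and `error_history`.
#' @export
kgasvd <- function(P, M, J = 8L, iters = 20L, seed = 0L, tol = 1e-6,
                   verbose = FALSE) {
  V <- if (is_ga_array(P)) P else P$vectors
  stopifnot(is_ga_array(V), length(ga_dim(V)) == 2L)
  if (iters < 1L) stop("kgasvd(): iters must be >= 1")
  D <- init_dictionary(V, M, seed)
  Yr <- ga_interleave(V)
  history <- numeric(0L)
  Ar <- NULL
  Rr_prev <- NULL
  for (it in seq_len(iters)) {
    if (it > 1L)
      D <- ga_dictionary(.refresh_dictionary(D$atoms, Ar, Rr_prev, Yr),
                         normalize = FALSE, meta = D$meta)
    codes <- code_patchset(V, D, J = J, tol = tol)
    Ar <- ga_interleave(codes)
    Demb <- ga_embed(D$atoms)
    Rr <- Yr - Demb %*% Ar
    atoms <- D$atoms
    for (k in seq_len(M)) {
      up <- .update_atom_embed(k, atoms, Demb, Ar, Rr, Yr)
      atoms <- up$D; Demb <- up$Demb; Ar <- up$Ar; Rr <- up$Rr
    }
    D <- ga_dictionary(atoms, normalize = FALSE, meta = D$meta)
    Rr_prev <- Rr
    err <- sqrt(mean(Rr^2))
    history <- c(history, err)
    if (verbose)
      message(sprintf("kgasvd iter %d/%d: rms error %.6g", it, iters, err))
  }
  structure(list(dictionary = D, codes = ga_deinterleave(Ar),
                 iteration = iters, error_history = history),
            class = "ga_train_state")
}

#' @export
print.ga_train_state <- function(x, ...) {
  cat(sprintf(
    "<ga_train_state: %d atoms, %d iterations, final rms error %.6g>\n",
    dict_natoms(x$dictionary), x$iteration,
    x$error_history[length(x$error_history)]))
  invisible(x)
}

#' Save a GA dictionary to a single-file archive
#'
#' Stores the four component matrices (`E0`, `E1`, `E2`, `E12`) and the
#' metadata record; the round trip through [load_dictionary()] is bit-exact.
#'
#' @param D A [ga_dictionary].
#' @param path Destination file (conventionally `.gad`).
#' @return `path`, invisibly.
#' @export
save_dictionary <- function(D, path) {
  stopifnot(inherits(D, "ga_dictionary"))
  obj <- list(format = "gafuse-dictionary", version = 1L,
              E0 = D$atoms$e0, E1 = D$atoms$e1,
              E2 = D$atoms$e2, E12 = D$atoms$e12,
              meta = D$meta)
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  saveRDS(obj, tmp)
  if (!file.rename(tmp, path))
    stop("save_dictionary(): could not move output into place")
  invisible(path)
}

#' Load a GA dictionary archive
#' @param path File written by [save_dictionary()].
#' @return The [ga_dictionary].
#' @export
load_dictionary <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "gafuse-dictionary"))
    stop("load_dictionary(): ", path, " is not a gafuse dictionary archive")
  ga_dictionary(new_ga_array(obj$E0, obj$E1, obj$E2, obj$E12),
                normalize = FALSE, meta = obj$meta)
}
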