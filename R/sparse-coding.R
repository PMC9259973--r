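# GAOMP: greedy GA-valued orthogonal matching pursuit.
#
# Atom selection maximises the magnitude of the GA correlation
# c_m = sum_i gp(reverse(D[i,m]), r[i]); on the real embedding this is the
# Euclidean norm of the atom's 4-column correlation block, so the pursuit is
# a group-OMP with groups of four real columns and reduces to classical
# scalar OMP when every input lives in the scalar blade.

#' Construct a GA dictionary
#'
#' @param atoms A [ga_array] of shape N x M whose columns are the atoms.
#' @param normalize If `TRUE` (default) columns are scaled to unit GA
#'   Frobenius norm; if `FALSE` they must already be unit-norm to 1e-10.
#' @param meta Optional named list of provenance metadata (patch size,
#'   training settings, ...), kept through serialization.
#' @return A `ga_dictionary`: list with `atoms` and `meta`.
#' @export
ga_dictionary <- function(atoms, normalize = TRUE, meta = list()) {
  stopifnot(is_ga_array(atoms), length(ga_dim(atoms)) == 2L)
  norms <- sqrt(colSums(atoms$e0^2 + atoms$e1^2 + atoms$e2^2 + atoms$e12^2))
  if (any(norms == 0)) stop("ga_dictionary(): zero atom at column ",
                            which(norms == 0)[1L])
  if (normalize) {
    atoms <- new_ga_array(sweep(atoms$e0, 2L, norms, "/"),
                          sweep(atoms$e1, 2L, norms, "/"),
                          sweep(atoms$e2, 2L, norms, "/"),
                          sweep(atoms$e12, 2L, norms, "/"))
  } else if (any(abs(norms - 1) > 1e-10)) {
    stop("ga_dictionary(): atoms are not unit-norm (max deviation ",
         format(max(abs(norms - 1))), ")")
  }
  structure(list(atoms = atoms, meta = meta), class = "ga_dictionary")
}

#' @export
print.ga_dictionary <- function(x, ...) {
  d <- ga_dim(x$atoms)
  cat(sprintf("<ga_dictionary: %d atoms of GA length %d>\n", d[2L], d[1L]))
  invisible(x)
}

dict_natoms <- function(D) ga_dim(D$atoms)[2L]
dict_len <- function(D) ga_dim(D$atoms)[1L]

#' Sparse-code one GA signal with GAOMP
#'
#' Greedy pursuit: correlate the residual with every atom, select the atom
#' with the largest GA correlation magnitude (lowest index on ties), refit
#' all active coefficients by least squares on the real embedding, and stop
#' at `J` atoms or when the residual norm falls below `tol * ||q||`.
#'
#' @param q A [ga_array] of length N (the signal).
#' @param D A [ga_dictionary] with atoms of GA length N.
#' @param J Sparsity budget (maximum number of atoms, `>= 1`).
#' @param tol Relative residual tolerance (default `1e-6`).
#' @return A [ga_array] of length M with attributes `support` (selected atom
#'   indices, in selection order), `resid` (final residual norm) and
#'   `resid_history` (one residual norm per completed iteration).
#' @export
gaomp <- function(q, D, J = 8L, tol = 1e-6) {
  stopifnot(inherits(D, "ga_dictionary"), is_ga_array(q))
  if (length(ga_dim(q)) != 1L) stop("gaomp(): q must be a GA vector")
  if (length(q) != dict_len(D))
    stop("gaomp(): signal length ", length(q), " does not match dictionary ",
         "atom length ", dict_len(D))
  check_finite(q, "gaomp(): q")
  P <- list(vectors = ga_array(cbind(q$e0), cbind(q$e1), cbind(q$e2),
                               cbind(q$e12)))
  res <- gaomp_embed_cpp(ga_embed(D$atoms), ga_interleave(P$vectors),
                         as.integer(J), tol)
  a <- ga_deinterleave(res$coef[, 1L])
  attr(a, "support") <- res$support[seq_len(res$nsel[1L]), 1L]
  attr(a, "resid") <- res$resid[1L]
  rh <- res$resid_history[, 1L]
  attr(a, "resid_history") <- rh[!is.na(rh)]
  a
}

#' Sparse-code every column of a patch set
#'
#' Column `i` of the result is `gaomp(P$vectors[, i], D, J, tol)`; columns
#' are independent, so the output does not depend on evaluation order.
#'
#' @param P A `ga_patchset` (or any list with a `vectors` [ga_array]).
#' @param D A [ga_dictionary].
#' @param J,tol As in [gaomp()].
#' @return A [ga_array] of shape M x K with attributes `support` (J x K
#'   integer matrix of selected atoms, zero-padded), `nsel` (atoms used per
#'   column) and `resid` (final residual norms).
#' @export
code_patchset <- function(P, D, J = 8L, tol = 1e-6) {
  stopifnot(inherits(D, "ga_dictionary"))
  V <- if (is_ga_array(P)) P else P$vectors
  stopifnot(is_ga_array(V), length(ga_dim(V)) == 2L)
  if (ga_dim(V)[1L] != dict_len(D))
    stop("code_patchset(): patch length ", ga_dim(V)[1L],
         " does not match dictionary atom length ", dict_len(D))
  M <- dict_natoms(D); K <- ga_dim(V)[2L]
  if (K == 0L) {
    out <- ga_zeros(c(M, 0L))
    attr(out, "support") <- matrix(0L, J, 0L)
    attr(out, "nsel") <- integer(0L)
    attr(out, "resid") <- numeric(0L)
    return(out)
  }
  res <- gaomp_embed_cpp(ga_embed(D$atoms), ga_interleave(V),
                         as.integer(J), tol)
  A <- ga_deinterleave(res$coef)
  attr(A, "support") <- res$support
  attr(A, "nsel") <- as.integer(res$nsel)
  attr(A, "resid") <- as.numeric(res$resid)
  A
}
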