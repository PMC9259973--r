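# Arithmetic for the plane geometric algebra G2 = Cl(2,0).
#
# A multivector is a = e0 + e1*g1 + e2*g2 + e12*g12 with g1^2 = g2^2 = 1,
# g1 g2 = g12 = -g2 g1, g12^2 = -1.  A `ga_array` stores a whole array of
# multivectors as four co-indexed real arrays, one per basis blade, so all
# bulk operations vectorise over the shape.

new_ga_array <- function(e0, e1, e2, e12) {
  structure(list(e0 = e0, e1 = e1, e2 = e2, e12 = e12), class = "ga_array")
}

#' Create an array of G2 multivectors
#'
#' @param e0,e1,e2,e12 Real arrays of one common shape: the scalar, g1, g2
#'   and g12 components.  Scalars are recycled to the common shape.
#' @return A `ga_array` with four co-indexed component arrays.
#' @examples
#' a <- ga_array(0, 1, 2, 0)      # the vector g1 + 2 g2
#' gp(a, ga_basis$g1)
#' @export
ga_array <- function(e0 = 0, e1 = 0, e2 = 0, e12 = 0) {
  comp <- list(e0 = e0, e1 = e1, e2 = e2, e12 = e12)
  if (!all(vapply(comp, is.numeric, logical(1L))))
    stop("multivector components must be numeric")
  dims <- lapply(comp, function(x) if (is.null(dim(x))) length(x) else dim(x))
  lens <- vapply(comp, length, integer(1L))
  n <- max(lens)
  ref <- which(lens == n)[1L]
  comp <- lapply(comp, function(x) {
    if (length(x) == 1L && n > 1L) x <- rep(as.numeric(x), n)
    storage.mode(x) <- "double"
    dim(x) <- dim(comp[[ref]])
    x
  })
  if (length(unique(lapply(comp, function(x)
    if (is.null(dim(x))) length(x) else dim(x)))) != 1L)
    stop("multivector component arrays must share one shape")
  new_ga_array(comp$e0, comp$e1, comp$e2, comp$e12)
}

#' Construct a single multivector
#'
#' @inheritParams ga_array
#' @return A length-one `ga_array`.
#' @export
multivector <- function(e0 = 0, e1 = 0, e2 = 0, e12 = 0) {
  stopifnot(length(e0) == 1L, length(e1) == 1L,
            length(e2) == 1L, length(e12) == 1L)
  ga_array(as.numeric(e0), as.numeric(e1), as.numeric(e2), as.numeric(e12))
}

#' Basis blades of G2
#'
#' A list with the four basis elements `one`, `g1`, `g2`, `g12` as
#' length-one [ga_array] objects.
#' @export
ga_basis <- list(
  one = new_ga_array(1, 0, 0, 0),
  g1  = new_ga_array(0, 1, 0, 0),
  g2  = new_ga_array(0, 0, 1, 0),
  g12 = new_ga_array(0, 0, 0, 1)
)

#' Zero-filled multivector array
#' @param dim Shape (integer vector) of the result.
#' @return A `ga_array` of the given shape with all components zero.
#' @export
ga_zeros <- function(dim) {
  z <- array(0, dim = dim)
  new_ga_array(z, z, z, z)
}

is_ga_array <- function(x) inherits(x, "ga_array")

ga_dim <- function(x) {
  d <- dim(x$e0)
  if (is.null(d)) length(x$e0) else d
}

#' @export
dim.ga_array <- function(x) dim(x$e0)

#' @export
length.ga_array <- function(x) length(x$e0)

#' @export
`[.ga_array` <- function(x, ..., drop = TRUE) {
  new_ga_array(x$e0[..., drop = drop], x$e1[..., drop = drop],
               x$e2[..., drop = drop], x$e12[..., drop = drop])
}

#' @export
print.ga_array <- function(x, n = 6L, ...) {
  len <- length(x)
  d <- ga_dim(x)
  cat(sprintf("<ga_array: %s multivector(s), shape %s>\n",
              len, paste(d, collapse = "x")))
  show <- seq_len(min(n, len))
  for (i in show)
    cat(sprintf("  [%d] %+.6g %+.6g*g1 %+.6g*g2 %+.6g*g12\n",
                i, x$e0[i], x$e1[i], x$e2[i], x$e12[i]))
  if (len > n) cat(sprintf("  ... (%d more)\n", len - n))
  invisible(x)
}

#' @export
Ops.ga_array <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-")
      return(new_ga_array(-e1$e0, -e1$e1, -e1$e2, -e1$e12))
    if (.Generic == "+") return(e1)
    stop("unsupported unary operator for ga_array: ", .Generic)
  }
  both_ga <- is_ga_array(e1) && is_ga_array(e2)
  switch(.Generic,
    "+" = , "-" = {
      if (!both_ga) stop("can only add/subtract two ga_array objects; ",
                         "use ga_array() to lift scalars")
      f <- get(.Generic)
      new_ga_array(f(e1$e0, e2$e0), f(e1$e1, e2$e1),
                   f(e1$e2, e2$e2), f(e1$e12, e2$e12))
    },
    "*" = {
      if (both_ga)
        stop("'*' between two ga_array objects is ambiguous; use gp() for ",
             "the geometric product")
      s <- if (is_ga_array(e1)) e2 else e1
      g <- if (is_ga_array(e1)) e1 else e2
      new_ga_array(g$e0 * s, g$e1 * s, g$e2 * s, g$e12 * s)
    },
    "/" = {
      if (!is_ga_array(e1) || is_ga_array(e2))
        stop("only ga_array / numeric is supported")
      new_ga_array(e1$e0 / e2, e1$e1 / e2, e1$e2 / e2, e1$e12 / e2)
    },
    stop("unsupported operator for ga_array: ", .Generic)
  )
}

check_finite <- function(x, what) {
  if (!all(is.finite(x$e0)) || !all(is.finite(x$e1)) ||
      !all(is.finite(x$e2)) || !all(is.finite(x$e12)))
    stop(what, " contains non-finite multivector components")
  invisible(x)
}

#' Geometric product of multivectors
#'
#' Elementwise geometric (Clifford) product under the G2 table
#' `g1^2 = g2^2 = 1`, `g1 g2 = g12 = -g2 g1`, `g12^2 = -1`.  One argument may
#' be a single multivector, which is broadcast against the other.
#'
#' @param a,b `ga_array` objects of equal shape (or length one).
#' @return A `ga_array` holding the elementwise products `a*b`.
#' @export
gp <- function(a, b) {
  stopifnot(is_ga_array(a), is_ga_array(b))
  check_finite(a, "gp(): left operand")
  check_finite(b, "gp(): right operand")
  if (length(a) != length(b)) {
    if (length(a) == 1L) a <- ga_array(a$e0, a$e1, a$e2, a$e12 + 0 * b$e0)
    else if (length(b) == 1L) b <- ga_array(b$e0, b$e1, b$e2, b$e12 + 0 * a$e0)
    else stop("gp(): shape mismatch")
  }
  new_ga_array(
    a$e0 * b$e0  + a$e1 * b$e1  + a$e2 * b$e2  - a$e12 * b$e12,
    a$e0 * b$e1  + a$e1 * b$e0  - a$e2 * b$e12 + a$e12 * b$e2,
    a$e0 * b$e2  + a$e2 * b$e0  + a$e1 * b$e12 - a$e12 * b$e1,
    a$e0 * b$e12 + a$e12 * b$e0 + a$e1 * b$e2  - a$e2 * b$e1
  )
}

#' Reversion of a multivector array
#'
#' Reversion fixes grades 0 and 1 and negates the bivector blade, so
#' `gp(ga_reverse(a), a)` has scalar part equal to `ga_magnitude(a)^2` when
#' `a` is of vector grade.  It is the conjugation used by the GAOMP
#' correlation step.
#'
#' @param a A `ga_array`.
#' @return The reversed `ga_array`.
#' @export
ga_reverse <- function(a) {
  stopifnot(is_ga_array(a))
  new_ga_array(a$e0, a$e1, a$e2, -a$e12)
}

#' Multivector magnitude
#'
#' The Euclidean norm of the four-component coordinate vector,
#' `sqrt(e0^2 + e1^2 + e2^2 + e12^2)`, applied elementwise.
#'
#' @param a A `ga_array`.
#' @return A real array of the same shape.
#' @export
ga_magnitude <- function(a) {
  stopifnot(is_ga_array(a))
  sqrt(a$e0^2 + a$e1^2 + a$e2^2 + a$e12^2)
}

#' Frobenius norm of a multivector array
#'
#' Root-sum-square over every real component of every entry; the norm under
#' which dictionary atoms are normalised.
#' @param a A `ga_array`.
#' @return A single nonnegative real.
#' @export
ga_fnorm <- function(a) sqrt(sum(a$e0^2 + a$e1^2 + a$e2^2 + a$e12^2))

#' Real 4x4 matrix representation of a multivector
#'
#' The coefficient-matrix form of a G2 element: with `action = "right"`
#' (the default) the matrix of right multiplication on component columns,
#' so `ga_real_matrix(a) %*% v(b) = v(gp(b, a))` and consequently
#' `ga_real_matrix(a) %*% ga_real_matrix(b) = ga_real_matrix(gp(b, a))`
#' (an anti-homomorphism).  With `action = "left"` the matrix of left
#' multiplication, `L(a) %*% v(b) = v(gp(a, b))`, a homomorphism; the left
#' form is the block used by all embedded linear systems, because the sparse
#' model `q = D a` multiplies coefficients from the right.
#'
#' Component columns are ordered `(e0, e1, e2, e12)`.
#'
#' @param a A length-one `ga_array`.
#' @param action `"right"` or `"left"`.
#' @return A 4x4 real matrix.
#' @export
ga_real_matrix <- function(a, action = c("right", "left")) {
  stopifnot(is_ga_array(a), length(a) == 1L)
  action <- match.arg(action)
  e0 <- a$e0; e1 <- a$e1; e2 <- a$e2; e12 <- a$e12
  if (action == "right")
    matrix(c(e0,  e1,   e2, -e12,
             e1,  e0, -e12,   e2,
             e2, e12,   e0,  -e1,
             e12, e2,  -e1,   e0), 4L, 4L, byrow = TRUE)
  else
    matrix(c(e0,   e1,  e2, -e12,
             e1,   e0, e12,  -e2,
             e2, -e12,  e0,   e1,
             e12, -e2,  e1,   e0), 4L, 4L, byrow = TRUE)
}

# ---- real embeddings -------------------------------------------------------
# Interleaved layout: real row 4*(i-1)+c carries component c of GA entry i,
# with components ordered (e0, e1, e2, e12).

#' Interleave a multivector array into real columns
#'
#' A GA vector of length N becomes a real vector of length 4N; a GA N x K
#' matrix becomes a real 4N x K matrix.  Row `4*(i-1)+c` holds component `c`
#' (order e0, e1, e2, e12) of entry `i`.
#' @param x A `ga_array` of vector or matrix shape.
#' @return A real vector or matrix.
#' @export
ga_interleave <- function(x) {
  stopifnot(is_ga_array(x))
  d <- ga_dim(x)
  if (length(d) == 1L) {
    out <- rbind(as.vector(x$e0), as.vector(x$e1),
                 as.vector(x$e2), as.vector(x$e12))
    dim(out) <- NULL
    out
  } else if (length(d) == 2L) {
    out <- matrix(0, 4L * d[1L], d[2L])
    idx <- seq_len(d[1L])
    out[4L * idx - 3L, ] <- x$e0
    out[4L * idx - 2L, ] <- x$e1
    out[4L * idx - 1L, ] <- x$e2
    out[4L * idx, ] <- x$e12
    out
  } else stop("ga_interleave(): only vector or matrix shapes")
}

#' Rebuild a multivector array from interleaved real components
#' @param v A real vector of length 4N or a 4N x K matrix.
#' @return A `ga_array` of length N (or shape N x K).
#' @export
ga_deinterleave <- function(v) {
  if (is.matrix(v)) {
    stopifnot(nrow(v) %% 4L == 0L)
    idx <- seq_len(nrow(v) %/% 4L)
    new_ga_array(v[4L * idx - 3L, , drop = FALSE],
                 v[4L * idx - 2L, , drop = FALSE],
                 v[4L * idx - 1L, , drop = FALSE],
                 v[4L * idx, , drop = FALSE])
  } else {
    stopifnot(length(v) %% 4L == 0L)
    idx <- seq_len(length(v) %/% 4L)
    new_ga_array(v[4L * idx - 3L], v[4L * idx - 2L],
                 v[4L * idx - 1L], v[4L * idx])
  }
}

#' Real operator embedding of a GA matrix
#'
#' Expands a GA N x M matrix into the real 4N x 4M matrix whose (i, m) block
#' is the left-multiplication operator of entry (i, m), so that
#' `ga_embed(D) %*% ga_interleave(a)` equals `ga_interleave(ga_matmul(D, a))`.
#'
#' @param X A `ga_array` with matrix shape.
#' @return A real `4*nrow x 4*ncol` matrix.
#' @export
ga_embed <- function(X) {
  stopifnot(is_ga_array(X))
  d <- ga_dim(X)
  if (length(d) == 1L) { X <- ga_array(cbind(X$e0), cbind(X$e1),
                                       cbind(X$e2), cbind(X$e12))
                         d <- c(d, 1L) }
  stopifnot(length(d) == 2L)
  N <- d[1L]; M <- d[2L]
  A <- matrix(0, 4L * N, 4L * M)
  r1 <- seq(1L, 4L * N, by = 4L); r2 <- r1 + 1L; r3 <- r1 + 2L; r4 <- r1 + 3L
  c1 <- seq(1L, 4L * M, by = 4L); c2 <- c1 + 1L; c3 <- c1 + 2L; c4 <- c1 + 3L
  A[r1, c1] <- X$e0;  A[r1, c2] <- X$e1;   A[r1, c3] <- X$e2;  A[r1, c4] <- -X$e12
  A[r2, c1] <- X$e1;  A[r2, c2] <- X$e0;   A[r2, c3] <- X$e12; A[r2, c4] <- -X$e2
  A[r3, c1] <- X$e2;  A[r3, c2] <- -X$e12; A[r3, c3] <- X$e0;  A[r3, c4] <- X$e1
  A[r4, c1] <- X$e12; A[r4, c2] <- -X$e2;  A[r4, c3] <- X$e1;  A[r4, c4] <- X$e0
  A
}

#' GA matrix product
#'
#' Computes `Z[i, k] = sum_m gp(X[i, m], Y[m, k])` (or a matrix-vector
#' product when `Y` is a GA vector) through sixteen real BLAS products; the
#' result agrees with the real operator-embedding route to machine precision.
#'
#' @param X A `ga_array` of shape N x M.
#' @param Y A `ga_array` of shape M or M x K.
#' @return A `ga_array` of shape N (or N x K).
#' @export
ga_matmul <- function(X, Y) {
  stopifnot(is_ga_array(X), is_ga_array(Y))
  dx <- ga_dim(X); dy <- ga_dim(Y)
  if (length(dx) != 2L) stop("ga_matmul(): X must have matrix shape")
  vec_out <- length(dy) == 1L
  if (vec_out) dy <- c(dy, 1L)
  if (dx[2L] != dy[1L]) stop("ga_matmul(): inner dimensions disagree (",
                             dx[2L], " vs ", dy[1L], ")")
  m <- function(z) matrix(z, dy[1L], dy[2L])
  Y0 <- m(Y$e0); Y1 <- m(Y$e1); Y2 <- m(Y$e2); Y12 <- m(Y$e12)
  Z0  <- X$e0 %*% Y0 + X$e1 %*% Y1 + X$e2 %*% Y2 - X$e12 %*% Y12
  Z1  <- X$e1 %*% Y0 + X$e0 %*% Y1 + X$e12 %*% Y2 - X$e2 %*% Y12
  Z2  <- X$e2 %*% Y0 - X$e12 %*% Y1 + X$e0 %*% Y2 + X$e1 %*% Y12
  Z12 <- X$e12 %*% Y0 - X$e2 %*% Y1 + X$e1 %*% Y2 + X$e0 %*% Y12
  if (vec_out)
    new_ga_array(as.vector(Z0), as.vector(Z1), as.vector(Z2), as.vector(Z12))
  else new_ga_array(Z0, Z1, Z2, Z12)
}

#' GA least squares on the real embedding
#'
#' Solves `min_a || q - D_sub a ||` where the norm is the root-sum-square
#' over all 4N real components, by an SVD-based minimum-norm solve of the
#' 4N x 4k real operator embedding.  Rank-deficient embedded systems fall
#' back to the minimum-norm solution with a message.
#'
#' @param D_sub A `ga_array` of shape N x k (active atoms).
#' @param q A `ga_array` of length N.
#' @param tol Relative singular-value cutoff for rank detection.
#' @return A `ga_array` of length k with attribute `"residual"` (the
#'   embedded residual norm).
#' @export
ga_lstsq <- function(D_sub, q, tol = 1e-10) {
  stopifnot(is_ga_array(D_sub), is_ga_array(q))
  A <- ga_embed(D_sub)
  b <- ga_interleave(q)
  if (nrow(A) != length(b)) stop("ga_lstsq(): row dimensions disagree")
  if (nrow(A) < ncol(A)) stop("ga_lstsq(): underdetermined embedded system")
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d, 0)
  if (!any(keep)) {
    x <- rep(0, ncol(A))
  } else {
    if (!all(keep))
      message("ga_lstsq(): rank-deficient embedded system (rank ",
              sum(keep), " of ", ncol(A), "); minimum-norm solution used")
    x <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
    x <- as.vector(x)
  }
  out <- ga_deinterleave(x)
  attr(out, "residual") <- sqrt(sum((b - A %*% x)^2))
  out
}
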