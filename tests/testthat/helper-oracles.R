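# Independent oracles and shared test fixtures.

# --- 2x2 matrix representation of G2 ---------------------------------------
# Cl(2,0) is isomorphic to the algebra of real 2x2 matrices via
# g1 -> diag(1, -1), g2 -> antidiag(1, 1); multiplying 2x2 matrices and
# decomposing back is an oracle for the geometric product that shares no
# code with the package's component formulas.
oracle_g1 <- matrix(c(1, 0, 0, -1), 2L)
oracle_g2 <- matrix(c(0, 1, 1, 0), 2L)
oracle_g12 <- oracle_g1 %*% oracle_g2

oracle_to_mat <- function(a)
  a$e0 * diag(2L) + a$e1 * oracle_g1 + a$e2 * oracle_g2 + a$e12 * oracle_g12

oracle_from_mat <- function(X)
  multivector((X[1L, 1L] + X[2L, 2L]) / 2, (X[1L, 1L] - X[2L, 2L]) / 2,
              (X[1L, 2L] + X[2L, 1L]) / 2, (X[1L, 2L] - X[2L, 1L]) / 2)

oracle_gp <- function(a, b) oracle_from_mat(oracle_to_mat(a) %*% oracle_to_mat(b))

random_mv <- function() multivector(rnorm(1), rnorm(1), rnorm(1), rnorm(1))

# --- scalar OMP reference ---------------------------------------------------
# Classical orthogonal matching pursuit on plain real matrices, written
# directly from its definition (correlation / argmax / LS refit / residual);
# no shared code with the embedded group pursuit.
scalar_omp <- function(q, D, J, tol = 0) {
  r <- q
  sel <- integer(0L)
  x <- numeric(0L)
  qn <- sqrt(sum(q^2))
  for (it in seq_len(J)) {
    corr <- abs(drop(crossprod(D, r)))
    corr[sel] <- -Inf
    pick <- which.max(corr)          # which.max takes the lowest index on ties
    sel <- c(sel, pick)
    x <- qr.solve(D[, sel, drop = FALSE], q)
    r <- q - D[, sel, drop = FALSE] %*% x
    if (sqrt(sum(r^2)) <= tol * qn) break
  }
  list(support = sel, coef = drop(x), resid = sqrt(sum(r^2)))
}

# --- scalar K-SVD reference -------------------------------------------------
# Textbook K-SVD on plain real matrices: OMP coding, per-atom rank-1 SVD
# update with sigma*v codes, unused/duplicate/rare atoms replaced by the
# worst-represented column (the original reference implementation's
# housekeeping, mirrored so both algorithms solve the same problem).
scalar_ksvd <- function(Y, M, J, iters, init_idx) {
  D <- Y[, init_idx, drop = FALSE]
  D <- sweep(D, 2L, sqrt(colSums(D^2)), "/")
  A <- matrix(0, M, ncol(Y))
  for (it in seq_len(iters)) {
    if (it > 1L) {
      C <- abs(crossprod(D))
      use <- rowSums(A != 0)
      res <- colSums((Y - D %*% A)^2)
      ord <- order(res, decreasing = TRUE)
      nxt <- 1L
      for (k in seq_len(M)) {
        dup <- k > 1L && any(C[seq_len(k - 1L), k] > 0.99)
        if (!dup && use[k] >= 4L) next
        D[, k] <- Y[, ord[nxt]] / sqrt(sum(Y[, ord[nxt]]^2))
        nxt <- nxt + 1L
        C <- abs(crossprod(D))
      }
    }
    for (j in seq_len(ncol(Y))) {
      o <- scalar_omp(Y[, j], D, J, tol = 1e-6)
      A[, j] <- 0
      A[o$support, j] <- o$coef
    }
    for (k in seq_len(M)) {
      omega <- which(A[k, ] != 0)
      if (length(omega) == 0L) {
        res <- colSums((Y - D %*% A)^2)
        j <- which.max(res)
        D[, k] <- Y[, j] / sqrt(sum(Y[, j]^2))
        next
      }
      E <- Y[, omega, drop = FALSE] - D %*% A[, omega, drop = FALSE] +
        D[, k, drop = FALSE] %*% A[k, omega, drop = FALSE]
      sv <- svd(E, nu = 1L, nv = 1L)
      old <- sum((E - D[, k, drop = FALSE] %*% A[k, omega, drop = FALSE])^2)
      new <- sum((E - sv$d[1L] * sv$u %*% t(sv$v))^2)
      if (new >= old) next
      s <- sign(sv$u[which.max(abs(sv$u))])
      D[, k] <- s * sv$u
      A[k, omega] <- s * sv$d[1L] * sv$v
    }
  }
  list(D = D, A = A, err = sqrt(mean((Y - D %*% A)^2)))
}

# --- expectation helpers ----------------------------------------------------
expect_ga_equal <- function(a, b, tol = 1e-12) {
  err <- max(abs(a$e0 - b$e0), abs(a$e1 - b$e1),
             abs(a$e2 - b$e2), abs(a$e12 - b$e12))
  expect_lt(err, tol)
}

ga_from_scalar_mat <- function(X)
  ga_array(X, matrix(0, nrow(X), ncol(X)), matrix(0, nrow(X), ncol(X)),
           matrix(0, nrow(X), ncol(X)))

random_ga_mat <- function(n, m)
  ga_array(matrix(rnorm(n * m), n), matrix(rnorm(n * m), n),
           matrix(rnorm(n * m), n), matrix(rnorm(n * m), n))

random_ga_vec <- function(n)
  ga_array(rnorm(n), rnorm(n), rnorm(n), rnorm(n))
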