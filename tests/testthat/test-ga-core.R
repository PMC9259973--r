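# The G2 multiplication table, its matrix representation and the embedded
# linear algebra that everything downstream relies on.

test_that("geometric product reproduces the generator relations", {
  g1 <- ga_basis$g1; g2 <- ga_basis$g2; g12 <- ga_basis$g12; one <- ga_basis$one
  expect_ga_equal(gp(g1, g1), one)             # unit square
  expect_ga_equal(gp(g2, g2), one)
  expect_ga_equal(gp(g12, g12), -one)          # bivector squares to -1
  expect_ga_equal(gp(g1, g2), g12)
  expect_ga_equal(gp(g2, g1), -g12)            # anticommutation
  expect_ga_equal(gp(g1, g12), g2)
  expect_ga_equal(gp(g12, g1), -g2)
  expect_ga_equal(gp(g2, g12), -g1)
  expect_ga_equal(gp(g12, g2), g1)
  b <- multivector(0.3, -1.2, 4, 0.7)
  expect_ga_equal(gp(ga_basis$one, b), b)      # identity element
  # (g1 + g2) g1 = 1 - g12
  expect_ga_equal(gp(ga_array(0, 1, 1, 0), g1), ga_array(1, 0, 0, -1))
})

test_that("geometric product matches the 2x2 matrix-algebra oracle", {
  set.seed(11)
  for (i in 1:200) {
    a <- random_mv(); b <- random_mv()
    expect_ga_equal(gp(a, b), oracle_gp(a, b), tol = 1e-12)
  }
})

test_that("gp is bilinear, associative and rejects non-finite input", {
  set.seed(12)
  for (i in 1:50) {
    a <- random_mv(); b <- random_mv(); cc <- random_mv()
    s <- rnorm(1)
    expect_ga_equal(gp(a + b * s, cc), gp(a, cc) + gp(b, cc) * s, tol = 1e-12)
    expect_ga_equal(gp(gp(a, b), cc), gp(a, gp(b, cc)), tol = 1e-12)
  }
  expect_error(gp(multivector(NaN), random_mv()), "non-finite")
  expect_error(gp(random_mv(), multivector(Inf)), "non-finite")
})

test_that("reversion fixes grades 0 and 1 and flips the bivector", {
  expect_ga_equal(ga_reverse(ga_basis$g12), -ga_basis$g12)
  a <- ga_array(1, 1, 0, 0)
  expect_ga_equal(ga_reverse(a), a)
  # scalar part of rev(v) v is |v|^2 for a vector-grade element
  v <- ga_array(0, 1, 2, 0)
  expect_equal(gp(ga_reverse(v), v)$e0, 5)
})

test_that("magnitude is the 4-component Euclidean norm", {
  expect_equal(ga_magnitude(multivector(0, 0, 0, 0)), 0)
  expect_equal(ga_magnitude(ga_basis$g12), 1)
  expect_equal(ga_magnitude(ga_array(1, 1, 1, 1)), 2)
  # multiplicative on vector-grade pairs (|ab|^2 = (a.b)^2 + (a^b)^2) ...
  set.seed(13)
  for (i in 1:50) {
    a <- ga_array(0, rnorm(1), rnorm(1), 0)
    b <- ga_array(0, rnorm(1), rnorm(1), 0)
    expect_equal(ga_magnitude(gp(a, b)), ga_magnitude(a) * ga_magnitude(b),
                 tolerance = 1e-12)
  }
  # ... but NOT in general: 1 + g1 is a zero-divisor direction
  a <- ga_array(1, 1, 0, 0)
  expect_equal(ga_magnitude(gp(a, a)), 2 * sqrt(2))
  expect_false(isTRUE(all.equal(ga_magnitude(gp(a, a)), ga_magnitude(a)^2)))
})

test_that("the 4x4 representation has the stated entries and orientation", {
  expect_equal(ga_real_matrix(ga_basis$one), diag(4))
  expect_equal(ga_real_matrix(ga_basis$g1),
               matrix(c(0, 1, 0, 0,
                        1, 0, 0, 0,
                        0, 0, 0, -1,
                        0, 0, -1, 0), 4, 4, byrow = TRUE))
  # right-multiplication orientation: M(g1) M(g2) = M(gp(g2, g1)) = M(-g12)
  expect_equal(ga_real_matrix(ga_basis$g1) %*% ga_real_matrix(ga_basis$g2),
               ga_real_matrix(-ga_basis$g12))
})

test_that("the representation is a linear anti-homomorphism (1000 pairs)", {
  set.seed(14)
  worst <- 0
  for (i in 1:1000) {
    a <- random_mv(); b <- random_mv()
    worst <- max(worst,
      abs(ga_real_matrix(a) %*% ga_real_matrix(b) -
            ga_real_matrix(gp(b, a))),
      abs(ga_real_matrix(a) %*% ga_interleave(b) - ga_interleave(gp(b, a))))
    # left form is a homomorphism
    worst <- max(worst,
      abs(ga_real_matrix(a, "left") %*% ga_real_matrix(b, "left") -
            ga_real_matrix(gp(a, b), "left")))
  }
  expect_lt(worst, 1e-12)
  # linearity
  a <- random_mv(); b <- random_mv()
  expect_equal(ga_real_matrix(a * 2 + b * (-0.5)),
               2 * ga_real_matrix(a) - 0.5 * ga_real_matrix(b))
})

test_that("ga_matmul agrees with the operator-embedding route", {
  D1 <- ga_array(matrix(1, 1, 1), matrix(0, 1, 1), matrix(0, 1, 1),
                 matrix(0, 1, 1))
  v <- ga_array(0, 0, 1, 0)
  expect_ga_equal(ga_matmul(D1, v), v)              # identity 1x1 dictionary
  set.seed(15)
  D <- random_ga_mat(3, 2)
  a <- random_ga_vec(2)
  direct <- ga_matmul(D, a)
  # direct gp-sum, scalar loop
  manual <- ga_zeros(3)
  for (i in 1:3) for (m in 1:2) {
    p <- gp(D[i, m], a[m])
    manual$e0[i] <- manual$e0[i] + p$e0; manual$e1[i] <- manual$e1[i] + p$e1
    manual$e2[i] <- manual$e2[i] + p$e2; manual$e12[i] <- manual$e12[i] + p$e12
  }
  expect_ga_equal(direct, manual, tol = 1e-12)
  expect_equal(ga_interleave(direct),
               drop(ga_embed(D) %*% ga_interleave(a)), tolerance = 1e-12)
  z <- ga_zeros(2)
  expect_ga_equal(ga_matmul(D, z), ga_zeros(3))     # zero vector
  expect_error(ga_matmul(D, random_ga_vec(5)), "inner dimensions")
})

test_that("ga_lstsq solves exact systems and is Monte-Carlo optimal", {
  set.seed(16)
  d <- random_ga_vec(6)
  d <- d / ga_fnorm(d)
  Dm <- ga_array(cbind(d$e0), cbind(d$e1), cbind(d$e2), cbind(d$e12))
  cc <- random_mv()
  q <- ga_matmul(Dm, cc)
  sol <- ga_lstsq(Dm, q)
  expect_ga_equal(sol, cc, tol = 1e-10)
  expect_lt(attr(sol, "residual"), 1e-10)
  # q = 0 -> zero coefficients
  z <- ga_lstsq(Dm, ga_zeros(6))
  expect_equal(ga_fnorm(z), 0)
  # overdetermined random instance beats 100 random candidates
  D2 <- random_ga_mat(8, 3)
  q2 <- random_ga_vec(8)
  sol2 <- ga_lstsq(D2, q2)
  best <- attr(sol2, "residual")
  A <- ga_embed(D2); b <- ga_interleave(q2)
  for (i in 1:100) {
    cand <- ga_interleave(sol2) + rnorm(12, sd = 0.3)
    expect_gte(sqrt(sum((b - A %*% cand)^2)), best - 1e-10)
  }
})

test_that("interleave/deinterleave and indexing round-trip", {
  set.seed(17)
  x <- random_ga_mat(5, 4)
  expect_ga_equal(ga_deinterleave(ga_interleave(x)), x, tol = 0 + 1e-15)
  v <- random_ga_vec(7)
  expect_ga_equal(ga_deinterleave(ga_interleave(v)), v, tol = 1e-15)
  expect_equal(length(x[, 2]), 5L)
  expect_equal(x[2, 3]$e12, x$e12[2, 3])
})
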