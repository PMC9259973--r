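# K-GASVD: initialisation, the per-atom update, full training, and the
# archive round trip.

test_that("init_dictionary samples, normalises and is seed-deterministic", {
  set.seed(41)
  V <- random_ga_mat(10, 15)
  D1 <- init_dictionary(V, 8, seed = 7)
  D2 <- init_dictionary(V, 8, seed = 7)
  expect_identical(D1$atoms, D2$atoms)
  norms <- sqrt(colSums(D1$atoms$e0^2 + D1$atoms$e1^2 + D1$atoms$e2^2 +
                          D1$atoms$e12^2))
  expect_equal(norms, rep(1, 8), tolerance = 1e-10)
  # M = K gives a permutation of the normalised columns
  Dall <- init_dictionary(V, 15, seed = 1)
  Vn <- ga_interleave(ga_dictionary(V)$atoms)
  got <- ga_interleave(Dall$atoms)
  match_cols <- apply(abs(crossprod(got, Vn)), 1, max)
  expect_equal(match_cols, rep(1, 15), tolerance = 1e-12)
  expect_error(init_dictionary(V, 16, seed = 1), "exceeds")
})

test_that("update_atom replaces unused atoms by the worst column direction", {
  set.seed(42)
  V <- random_ga_mat(6, 12)
  # make column 4 dominate the residual
  V$e1[, 4] <- V$e1[, 4] * 50
  D <- init_dictionary(V, 3, seed = 2)
  state <- list(dictionary = D, codes = ga_zeros(c(3L, 12L)))
  st2 <- update_atom(1, state, V)
  d <- st2$dictionary$atoms[, 1]
  ref <- V[, 4] / ga_fnorm(V[, 4])
  expect_lt(min(ga_fnorm(d - ref), ga_fnorm(d + ref)), 1e-12)
  expect_equal(ga_fnorm(d), 1, tolerance = 1e-12)
})

test_that("update_atom leaves an exact factorisation at zero residual", {
  set.seed(43)
  pr <- make_sparse_problem(8, 10, 2, 40, seed = 43)
  state <- list(dictionary = pr$D_true,
                codes = code_patchset(pr$Q, pr$D_true, J = 2, tol = 1e-12))
  for (k in c(1L, 5L)) {
    state <- update_atom(k, state, pr$Q)
    expect_lt(state$error, 1e-10)
  }
})

test_that("a single-column rank-one error matrix yields that column's direction", {
  set.seed(44)
  # one training column used only by atom k: E_k is the column itself
  d_old <- random_ga_vec(6); d_old <- d_old / ga_fnorm(d_old)
  y <- random_ga_vec(6)
  D <- ga_dictionary(ga_array(cbind(d_old$e0), cbind(d_old$e1),
                              cbind(d_old$e2), cbind(d_old$e12)),
                     normalize = FALSE)
  codes <- ga_array(matrix(1e-3, 1, 1), matrix(0, 1, 1), matrix(0, 1, 1),
                    matrix(0, 1, 1))
  st <- update_atom(1, list(dictionary = D, codes = codes),
                    ga_array(cbind(y$e0), cbind(y$e1), cbind(y$e2),
                             cbind(y$e12)))
  u <- ga_interleave(st$dictionary$atoms[, 1])
  ref <- ga_interleave(y) / sqrt(sum(ga_interleave(y)^2))
  expect_lt(min(sqrt(sum((u - ref)^2)), sqrt(sum((u + ref)^2))), 1e-10)
})

test_that("kgasvd recovers a planted dictionary from scalar-gain data", {
  # M distinct atoms, each appearing in J=1 codes with random scalar gains
  pr <- make_sparse_problem(12, 16, 1, 320, seed = 45, coef_type = "scalar")
  st <- kgasvd(pr$Q, M = 16, J = 1, iters = 5, seed = 45)
  cos <- match_atoms(st$dictionary, pr$D_true)
  expect_gte(mean(cos >= 0.99), 0.99)
  expect_lte(max(diff(st$error_history)), 1e-8)
})

test_that("kgasvd records one error per iteration and keeps atoms unit-norm", {
  set.seed(46)
  V <- random_ga_mat(8, 60)
  st1 <- kgasvd(V, M = 10, J = 2, iters = 1, seed = 1)
  expect_length(st1$error_history, 1L)
  st <- kgasvd(V, M = 10, J = 2, iters = 6, seed = 1)
  expect_length(st$error_history, 6L)
  expect_lte(max(diff(st$error_history)), 1e-8)   # monotone on random data
  norms <- sqrt(colSums(st$dictionary$atoms$e0^2 + st$dictionary$atoms$e1^2 +
                          st$dictionary$atoms$e2^2 +
                          st$dictionary$atoms$e12^2))
  expect_equal(norms, rep(1, 10), tolerance = 1e-10)
  expect_error(kgasvd(V, M = 10, J = 2, iters = 0), "iters")
})

test_that("dictionary archives round-trip bit-exactly", {
  set.seed(47)
  D <- ga_dictionary(random_ga_mat(9, 5),
                     meta = list(patch_size = 3L, J = 2L, note = "fixture"))
  p <- tempfile(fileext = ".gad")
  save_dictionary(D, p)
  D2 <- load_dictionary(p)
  expect_identical(D2$atoms, D$atoms)
  expect_identical(D2$meta, D$meta)
  saveRDS(list(format = "other"), p)
  expect_error(load_dictionary(p), "not a gafuse dictionary")
})

test_that("the recovery experiment reports PSNR and recovery per grid point", {
  tab <- atom_recovery_experiment(N = 12L, M = c(6L, 12L), k_sparse = 1L,
                                  n_train = 240L, seeds = 5L, M_true = 12L,
                                  iters = 6L)
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("M", "seed", "psnr", "recovery_rate"))
  # recovery at the true dictionary size
  expect_gte(tab$recovery_rate[tab$M == 12L], 0.9)
  # PSNR non-decreasing in M
  expect_gte(tab$psnr[tab$M == 12L], tab$psnr[tab$M == 6L])
})
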