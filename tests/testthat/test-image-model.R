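# Encoding, patch extraction and overlap-averaged reconstruction.

test_that("encoding maps channels onto the non-scalar blades", {
  px <- array(c(0.2, 0.5, 0.9), c(1, 1, 3))
  # a 1x1 image is below no minimum; encode directly
  img <- encode_image(px)
  expect_equal(img$e0[1, 1], 0)
  expect_equal(img$e1[1, 1], 0.2)
  expect_equal(img$e2[1, 1], 0.5)
  expect_equal(img$e12[1, 1], 0.9)
  black <- encode_image(array(0, c(4, 4, 3)))
  expect_equal(ga_fnorm(black), 0)
  expect_error(encode_image(array(0, c(4, 4, 2))), "H x W x 3")
  expect_warning(encode_image(array(2, c(2, 2, 3))), "rescal")
})

test_that("decode inverts encode, clips, and audits scalar residue", {
  set.seed(21)
  X <- array(runif(5 * 7 * 3), c(5, 7, 3))
  expect_identical(decode_image(encode_image(X)), X)   # bit-level round trip
  img <- ga_array(matrix(0, 1, 1), matrix(1.5, 1, 1), matrix(-0.2, 1, 1),
                  matrix(0.5, 1, 1))
  expect_equal(as.vector(decode_image(img)), c(1, 0, 0.5))  # clipping
  quiet <- ga_array(matrix(0.001, 1, 1), matrix(0.2, 1, 1), matrix(0.5, 1, 1),
                    matrix(0.9, 1, 1))
  expect_no_message(decode_image(quiet, e0_tolerance = 0.01))
  expect_message(decode_image(quiet, e0_tolerance = 1e-4), "scalar residue")
})

test_that("patch extraction enumerates and flattens as documented", {
  set.seed(22)
  X <- array(runif(3 * 3 * 3), c(3, 3, 3))
  P <- extract_patches(encode_image(X), 2)
  expect_equal(nrow(P$positions), 4L)                  # (3-2+1)^2
  # positions row-major by corner
  expect_equal(P$positions, cbind(row = c(0L, 0L, 1L, 1L),
                                  col = c(0L, 1L, 0L, 1L)),
               ignore_attr = TRUE)
  # whole image as a single patch = column-major flatten
  P1 <- extract_patches(encode_image(X), 3)
  expect_equal(nrow(P1$positions), 1L)
  expect_equal(P1$vectors$e1[, 1], as.vector(X[, , 1]))
  # 4x4 distinct values, n = 2: patch with corner (1,1) [0-based] holds
  # pixels (1,1),(2,1),(1,2),(2,2) in column-major order
  V <- array(seq_len(16 * 3), c(4, 4, 3)) / 48
  Pv <- extract_patches(encode_image(V), 2)
  i <- which(Pv$positions[, 1] == 1L & Pv$positions[, 2] == 1L)
  expect_equal(Pv$vectors$e1[, i],
               c(V[2, 2, 1], V[3, 2, 1], V[2, 3, 1], V[3, 3, 1]))
  expect_error(extract_patches(encode_image(X), 5), "patch size")
})

test_that("reconstruction inverts extraction and averages overlaps", {
  set.seed(23)
  X <- array(runif(16 * 16 * 3), c(16, 16, 3))
  img <- encode_image(X)
  for (n in c(2L, 8L)) {
    rec <- reconstruct_image(extract_patches(img, n))
    expect_ga_equal(rec, img, tol = 1e-12)
  }
  # coverage counts for 3x3 image, n = 2: corners 1, edges 2, centre 4
  P <- extract_patches(encode_image(X[1:3, 1:3, ]), 2)
  expect_equal(patch_coverage(P),
               matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3))
  # centre pixel is the mean of its 4 patch copies: perturb one copy
  P2 <- extract_patches(encode_image(X[1:3, 1:3, ]), 2)
  v <- P2$vectors
  v$e1[4, 1] <- v$e1[4, 1] + 0.4      # entry (2,2) of the first patch
  P2$vectors <- v
  rec2 <- reconstruct_image(P2)
  expect_equal(rec2$e1[2, 2], X[2, 2, 1] + 0.1, tolerance = 1e-12)
  # step > 1 leaving uncovered pixels errors with the region named
  expect_error(reconstruct_image(extract_patches(img, 3, step = 5)),
               "covered by no patch")
  # step > 1 with full coverage still round-trips where coverage is exact
  rec3 <- reconstruct_image(extract_patches(img, 8, step = 4))
  expect_ga_equal(rec3, img, tol = 1e-12)
})

test_that("coverage map matches the analytic count", {
  img <- encode_image(array(0.5, c(10, 9, 3)))
  for (n in c(2L, 3L)) for (s in c(1L, 2L)) {
    P <- extract_patches(img, n, s)
    cov <- patch_coverage(P)
    # analytic: number of grid corners r in seq(1,H-n+1,s) with r <= i < r+n
    H <- 10L; W <- 9L
    rows <- seq.int(1L, H - n + 1L, s); cols <- seq.int(1L, W - n + 1L, s)
    ana <- outer(vapply(seq_len(H), function(i)
                   sum(rows <= i & i < rows + n), integer(1)),
                 vapply(seq_len(W), function(j)
                   sum(cols <= j & j < cols + n), integer(1)))
    expect_equal(cov, ana, ignore_attr = TRUE)
    expect_equal(sum(cov), nrow(P$positions) * n^2)
  }
})

test_that("PNG and TIFF round trips preserve unit-range images", {
  set.seed(24)
  X <- array(runif(8 * 8 * 3), c(8, 8, 3))
  X8 <- round(X * 255) / 255
  p <- tempfile(fileext = ".png")
  write_image(X8, p)
  expect_equal(read_image(p), X8, tolerance = 1e-9)
  t <- tempfile(fileext = ".tiff")
  write_image(X, t)
  expect_equal(read_image(t), X, tolerance = 1e-4)   # 16-bit quantisation
  g <- tempfile(fileext = ".png")
  png::writePNG(X[, , 1], g)
  expect_message(Y <- read_image(g), "grayscale")
  expect_equal(Y[, , 1], Y[, , 3])
  expect_error(read_image(tempfile(fileext = ".png")), "no such file")
})
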