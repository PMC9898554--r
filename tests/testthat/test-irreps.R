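# O(3) algebra: real spherical harmonics, Wigner D, Wigner 3j, tensor products.

test_that("real spherical harmonics match closed forms and normalization", {
  u <- c(0, 0, 1)
  y <- sph_harmonics(3, u)
  # l = 0 block is the same constant for every direction
  set.seed(1)
  for (k in 1:5) {
    v <- rnorm(3)
    expect_equal(sph_harmonics(0, v)$blocks[[1]][1, 1], y$blocks[[1]][1, 1])
  }
  # l = 1 block at z is sqrt(3) * (y, z, x) = (0, sqrt(3), 0)
  expect_equal(as.numeric(y$blocks[[2]]), c(0, sqrt(3), 0), tolerance = 1e-12)
  set.seed(2)
  for (k in 1:5) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    yy <- sph_harmonics(4, v)
    expect_equal(as.numeric(yy$blocks[[2]]), sqrt(3) * c(v[2], v[3], v[1]),
                 tolerance = 1e-12)
    # component normalization: squared block norm 2l+1 on unit input
    expect_equal(sapply(yy$blocks, function(b) sum(b^2)), 2 * (0:4) + 1,
                 tolerance = 1e-12)
    # polynomial (monomial) form agrees with the angular evaluation
    for (l in 0:4)
      expect_lt(max(abs(allegror:::.sph_poly_eval(l, matrix(v, 1, 3))$Y -
                          yy$blocks[[l + 1]])), 1e-12)
  }
  # non-unit inputs are normalized; zero vector rejected
  expect_equal(ba_components(sph_harmonics(2, c(0, 0, 2.5))),
               ba_components(sph_harmonics(2, c(0, 0, 1))))
  expect_error(sph_harmonics(2, c(0, 0, 0)), "zero vector")
})

test_that("harmonics are equivariant under the numerical Wigner-D oracle", {
  set.seed(3)
  for (k in 1:10) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    rot <- random_rotation(inversion_prob = 0.3)
    y_rot <- sph_harmonics(4, as.numeric(allegror:::rot_apply_vec(rot, u)))
    y_D <- apply_rotation(sph_harmonics(4, u), rot)
    expect_lt(max(abs(ba_components(y_rot) - ba_components(y_D))), 1e-10)
  }
})

test_that("wigner_D satisfies the composition property and parity action", {
  expect_equal(wigner_D(0, random_rotation()), matrix(1, 1, 1))
  set.seed(4)
  worst <- 0
  for (k in 1:100) {
    r1 <- random_rotation(); r2 <- random_rotation()
    r12 <- rotation_op(r1$R %*% r2$R)
    for (l in 1:4)
      worst <- max(worst, max(abs(wigner_D(l, r12) -
                                    wigner_D(l, r1) %*% wigner_D(l, r2))))
  }
  expect_lt(worst, 1e-9)
  # D(1, R) is R in the (y, z, x) component order
  r <- random_rotation()
  P <- matrix(0, 3, 3); P[cbind(1:3, c(2, 3, 1))] <- 1
  expect_lt(max(abs(wigner_D(1, r) - P %*% r$R %*% t(P))), 1e-10)
  # inversion: odd blocks negate, even blocks unchanged
  inv <- rotation_op(diag(3), inversion = TRUE)
  lay <- irrep_layout(c(1, 1), c(1, 1), c(-1, 1))
  x <- block_array(lay, list(matrix(1:3, 1), matrix(4:6, 1)))
  xi <- apply_rotation(x, inv)
  expect_equal(xi$blocks[[1]], -x$blocks[[1]])
  expect_equal(xi$blocks[[2]], x$blocks[[2]])
})

test_that("wigner_3j reproduces scalar, dot and cross couplings", {
  expect_equal(as.numeric(wigner_3j(0, 0, 0)), 1)
  # (1,1,0): proportional to the Euclidean dot product
  C <- wigner_3j(1, 1, 0)
  set.seed(5)
  a <- rnorm(3); b <- rnorm(3)
  va <- c(a[2], a[3], a[1]); vb <- c(b[2], b[3], b[1])  # (y,z,x) order
  z <- sum(C[, , 1] * outer(va, vb))
  expect_equal(z, sum(a * b) / sqrt(3), tolerance = 1e-10)
  # (1,1,1): proportional to the cross product (up to sign/constant)
  C <- wigner_3j(1, 1, 1)
  cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  cr_yzx <- c(cr[2], cr[3], cr[1])
  z <- sapply(1:3, function(mo) sum(C[, , mo] * outer(va, vb)))
  ratio <- z / cr_yzx
  expect_lt(max(abs(ratio - ratio[1])), 1e-10)
  expect_equal(abs(ratio[1]), 1 / sqrt(2), tolerance = 1e-10)
  # selection-rule violation is an explicit error
  expect_error(wigner_3j(1, 2, 4), "invalid path")
})

test_that("wigner_3j slices are orthonormal for all l <= 4", {
  worst <- 0
  for (l1 in 0:4) for (l2 in 0:4) for (l3 in abs(l1 - l2):min(4, l1 + l2)) {
    C <- wigner_3j(l1, l2, l3)
    d3 <- dim(C)[3]
    G <- sapply(1:d3, function(m) sapply(1:d3, function(mp)
      sum(C[, , m] * C[, , mp])))
    worst <- max(worst, max(abs(G - diag(d3))))
  }
  expect_lt(worst, 1e-10)
})

test_that("enumerate_paths respects selection rules, caps, and ordering", {
  s <- irrep_layout(1, 0, 1)
  p <- enumerate_paths(s, s, 2)
  expect_equal(nrow(p), 1)
  expect_equal(unlist(p[1, c("l1", "l2", "l_out", "p_out")]),
               c(l1 = 0, l2 = 0, l_out = 0, p_out = 1))
  v <- irrep_layout(1, 1, -1)
  p <- enumerate_paths(v, v, 2)
  expect_equal(p$l_out, c(0, 1, 2))
  expect_equal(p$p_out, c(1, 1, 1))
  expect_equal(nrow(enumerate_paths(v, v, 0)), 1)
  # every path satisfies the rules; parity lands in p1*p2
  lay <- irrep_layout(c(2, 2, 2), c(0, 1, 2), c(1, -1, 1))
  p <- enumerate_paths(lay, lay, 3)
  expect_true(all(p$l_out >= abs(p$l1 - p$l2) & p$l_out <= p$l1 + p$l2))
  expect_true(all(p$l_out <= 3))
  expect_true(all(p$p_out == p$p1 * p$p2))
  # restricted mode only emits outputs already present in layout1
  pr <- enumerate_paths(lay, lay, 3, mode = "restricted")
  expect_true(all(paste(pr$l_out, pr$p_out) %in% paste(lay$ell, lay$parity)))
  # deterministic lexicographic ordering
  key <- order(p$l1, p$p1, p$l2, p$p2, p$l_out, p$p_out, p$i1, p$i2)
  expect_equal(key, seq_len(nrow(p)))
})

test_that("tensor_product is bilinear, channelwise, and equivariant", {
  s <- irrep_layout(1, 0, 1)
  x <- block_array(s, list(matrix(3, 1, 1)))
  y <- block_array(s, list(matrix(-2, 1, 1)))
  tp <- tensor_product(x, y, enumerate_paths(s, s, 0))
  expect_equal(tp$blocks[[1]][1, 1], -6)  # 0e x 0e is plain multiplication
  # 1o x 1o -> 0e proportional to the dot product
  v <- irrep_layout(1, 1, -1)
  a <- rnorm(3); b <- rnorm(3)
  xa <- block_array(v, list(matrix(c(a[2], a[3], a[1]), 1)))
  xb <- block_array(v, list(matrix(c(b[2], b[3], b[1]), 1)))
  p0 <- enumerate_paths(v, v, 0)
  expect_equal(tensor_product(xa, xb, p0)$blocks[[1]][1, 1],
               sum(a * b) / sqrt(3), tolerance = 1e-10)
  # bilinearity: zero input gives zero output
  x0 <- block_array(v, list(matrix(0, 1, 3)))
  expect_equal(tensor_product(x0, xb, p0)$blocks[[1]][1, 1], 0)
  # equivariance with random rotations/inversions, multi-channel
  set.seed(6)
  lay <- irrep_layout(c(2, 2), c(1, 2), c(-1, 1))
  paths <- enumerate_paths(lay, lay, 3)
  for (k in 1:10) {
    x <- block_array(lay, list(matrix(rnorm(6), 2), matrix(rnorm(10), 2)))
    y <- block_array(lay, list(matrix(rnorm(6), 2), matrix(rnorm(10), 2)))
    rot <- random_rotation(inversion_prob = 0.5)
    t1 <- apply_rotation(tensor_product(x, y, paths), rot)
    t2 <- tensor_product(apply_rotation(x, rot), apply_rotation(y, rot), paths)
    expect_lt(max(abs(ba_components(t1) - ba_components(t2))), 1e-10)
  }
  # structural parity bookkeeping on the output layout
  out <- tensor_product(block_array(lay, list(matrix(rnorm(6), 2), matrix(rnorm(10), 2))),
                        block_array(lay, list(matrix(rnorm(6), 2), matrix(rnorm(10), 2))),
                        paths)
  expect_equal(out$layout$parity, paths$p_out)
  expect_equal(out$layout$ell, paths$l_out)
})
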