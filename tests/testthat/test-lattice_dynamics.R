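# Projection operators, mass factors, dynamical matrices, supercell
# covariances, TLS partition and ADPs.

test_that("projection matrix matches the small-rotation linearization", {
  expect_equal(projection_matrix(c(0, 0, 0)), cbind(diag(3), matrix(0, 3, 3)))
  # point at (0,0,1), small rotation eps about x: u = (0, -eps, 0)
  A <- projection_matrix(c(0, 0, 1))
  eps <- 1e-3
  u_lin <- as.numeric(A %*% c(0, 0, 0, eps, 0, 0))
  th <- eps
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  u_rot <- as.numeric(R %*% c(0, 0, 1) - c(0, 0, 1))
  expect_equal(u_lin, c(0, -eps, 0))
  expect_lt(max(abs(u_lin - u_rot)), 1e-6)
  # symbolic row/column pattern
  x <- c(2, -3, 5)
  A <- projection_matrix(x)
  expect_equal(A[, 4:6], rbind(c(0, x[3], -x[2]),
                               c(-x[3], 0, x[1]),
                               c(x[2], -x[1], 0)))
})

test_that("mass factor equals the assembled generalized mass matrix", {
  toy <- toy_p1()
  mf <- mass_factor(toy$crystal)
  g <- toy$crystal$groups[[1]]
  xyz <- sweep(as.matrix(g$atoms[, c("x", "y", "z")]), 2, g$origin)
  M <- matrix(0, 6, 6)
  for (j in seq_len(nrow(xyz))) {
    A <- projection_matrix(xyz[j, ])
    M <- M + g$masses[j] * t(A) %*% A
  }
  L <- mf$L[[1]]
  expect_lt(max(abs(L %*% t(L) - M)) / max(abs(M)), 1e-10)
  expect_true(all(abs(L[upper.tri(L)]) < 1e-12)) # lower triangular
  # homogeneity: scaling masses by c scales L by sqrt(c)
  cr2 <- toy$crystal
  cr2$groups[[1]]$masses <- 4 * g$masses
  mf2 <- mass_factor(cr2)
  expect_equal(mf2$L[[1]], 2 * L, tolerance = 1e-10)
})

test_that("mass factor rejects degenerate bodies", {
  uc <- unit_cell(20, 20, 20)
  asu <- data.frame(element = "C", x = c(5, 6, 7), y = c(5, 5, 5),
                    z = c(5, 5, 5)) # collinear
  cr <- expand_to_unit_cell(asu, uc)
  expect_error(mass_factor(cr), "singular")
  # single atom: translational dof = 3 works
  cr1 <- expand_to_unit_cell(asu[1, ], uc)
  expect_silent(mass_factor(cr1, dof = 3))
  expect_error(mass_factor(cr1, dof = 6), "singular")
})

test_that("dynamical matrix is Hermitian with time-reversal symmetry", {
  model <- toy_p1_model()
  k <- c(0.21, -0.37, 0.11)
  d1 <- dynamical_matrix(model, k)
  d2 <- dynamical_matrix(model, -k)
  expect_lt(max(abs(d1$D - Conj(t(d1$D)))), 1e-10)
  expect_lt(max(abs(d1$D - Conj(d2$D))), 1e-10)
  expect_true(all(d1$values > -1e-8 * max(d1$values)))
  # zero springs give a zero matrix
  m0 <- set_params(model, rep(0, nrow(model$params)),
                   rep(0, nrow(model$params)))
  expect_lt(max(abs(dynamical_matrix(m0, k)$D)), 1e-14)
})

test_that("diatomic chain reproduces the textbook dispersion", {
  # two point bodies per cell on a line, Gaussian springs to nearest
  # neighbors; acoustic/optical branches of the 1D diatomic chain:
  # omega^2 = gamma (1/m1 + 1/m2) +- gamma sqrt((1/m1+1/m2)^2
  #           - 4 sin^2(pi k) / (m1 m2))
  uc <- unit_cell(13, 30, 30)
  asu <- data.frame(element = c("C", "O"), x = c(0, 6.5), y = c(5, 5),
                    z = c(5, 5), chain = c("A", "B"))
  cr <- expand_to_unit_cell(asu, uc)
  ct <- find_contacts(cr, cutoff = 6.5)
  ct <- ct[abs(ct$len - 6.5) < 1e-9, ] # the two axial nearest-neighbor springs
  expect_identical(nrow(ct), 2L)
  ids <- rep(1L, nrow(ct))
  gamma <- 2.3
  pp <- spring_parameter_set(ids, gamma, 0, level = "global")
  model <- build_enm(cr, ct, pp, ids, dof = 3)
  m1 <- element_property("C", "mass"); m2 <- element_property("O", "mass")
  for (kx in c(0.1, 0.25, 0.5)) {
    ed <- dynamical_matrix(model, c(kx, 0, 0))
    got <- sort(ed$values[ed$values > 1e-9])
    s <- 1 / m1 + 1 / m2
    disc <- sqrt(s^2 - 4 * sin(pi * kx)^2 / (m1 * m2))
    expected <- sort(c(gamma * (s - disc), gamma * (s + disc)))
    # transverse displacements are unrestrained by these two springs
    # (Gaussian springs also restore them: they give degenerate copies)
    expect_equal(got[c(1, length(got))], expected, tolerance = 1e-8)
  }
})

test_that("B/V-K covariance equals brute-force supercell inversion", {
  model <- toy_p1_model()
  for (nc in list(c(2, 2, 1), c(3, 2, 1))) {
    vc <- vcov_supercell(model, nc)
    bf <- brute_force_vcov(model, nc)
    expect_lt(max(abs(vc$blocks - bf$blocks)), 1e-8)
  }
  om <- toy_ortho_model()
  vc <- vcov_supercell(om, c(2, 2, 1))
  bf <- brute_force_vcov(om, c(2, 2, 1))
  expect_lt(max(abs(vc$blocks - bf$blocks)), 1e-8)
})

test_that("covariance linearity, symmetry, and zero-mode structure", {
  model <- toy_p1_model()
  vc1 <- vcov_supercell(model, c(2, 2, 2), kBT = 1)
  vc2 <- vcov_supercell(model, c(2, 2, 2), kBT = 2)
  expect_equal(vc2$blocks, 2 * vc1$blocks, tolerance = 1e-12)
  B0 <- vcov_block(vc1, c(0, 0, 0))
  expect_equal(B0, t(B0), tolerance = 1e-10)
  expect_gte(min(eigen(B0, symmetric = TRUE)$values), -1e-12)
  # exactly three zero modes at the zone center, none elsewhere
  ed0 <- dynamical_matrix(model, c(0, 0, 0))
  nzero <- sum(abs(ed0$values) < 1e-8 * max(ed0$values))
  expect_identical(nzero, 3L)
  V0 <- ed0$vectors[, abs(ed0$values) < 1e-8 * max(ed0$values)]
  # zero-mode eigenvectors span rigid supercell translations: in the
  # mass-weighted frame these are L^T (t, 0) for the three unit vectors
  L <- mass_factor(model$crystal)$L[[1]]
  for (i in 1:3) {
    v <- t(L) %*% c(as.numeric(diag(3)[, i]), 0, 0, 0)
    v <- v / sqrt(sum(v^2))
    proj <- V0 %*% (Conj(t(V0)) %*% v)
    expect_lt(max(Mod(proj - v)), 1e-8)
  }
  edk <- dynamical_matrix(model, c(0.5, 0, 0))
  expect_gt(min(edk$values), 1e-8 * max(edk$values))
})

test_that("covariance decays and the supercell center of mass is fixed", {
  model <- toy_p1_model()
  nc <- c(4, 1, 1)
  vc <- vcov_supercell(model, nc)
  # sum over all offsets of the translational covariance must vanish:
  # the supercell's center of mass does not move
  S <- matrix(0, 3, 3)
  for (n in 0:(nc[1] - 1)) S <- S + vcov_block(vc, c(n, 0, 0))[1:3, 1:3]
  expect_lt(max(abs(S)), 1e-10)
  # short-distance correlation positive, long-distance anti-correlated
  tr1 <- sum(diag(vcov_block(vc, c(1, 0, 0))[1:3, 1:3]))
  tr2 <- sum(diag(vcov_block(vc, c(2, 0, 0))[1:3, 1:3]))
  expect_gt(tr1, tr2)
})

test_that("any factor with L L^T = M yields identical observables", {
  toy <- toy_p1()
  model <- toy_p1_model()
  vc <- vcov_supercell(model, c(2, 1, 1))
  # rebuild with an eigendecomposition-based (non-Cholesky) mass factor
  model2 <- model
  g <- toy$crystal$groups[[1]]
  M <- model$mass$L[[1]] %*% t(model$mass$L[[1]])
  e <- eigen(M, symmetric = TRUE)
  Lalt <- e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors) # sqrt(M)
  model2$mass$L[[1]] <- Lalt
  model2$mass$Linv[[1]] <- solve(Lalt)
  vc2 <- vcov_supercell(model2, c(2, 1, 1))
  expect_equal(vc$blocks, vc2$blocks, tolerance = 1e-8)
})

test_that("TLS partition and ADP projection are consistent", {
  model <- toy_p1_model()
  vc <- vcov_supercell(model, c(2, 2, 2))
  tls <- tls_from_vcov(vc, 1)
  B <- vcov_block(vc, c(0, 0, 0), 1, 1)
  expect_equal(tls$T, B[1:3, 1:3])
  expect_equal(tls$L, B[4:6, 4:6])
  expect_equal(tls$S, B[4:6, 1:3])
  expect_gte(min(eigen(tls$T, symmetric = TRUE)$values), -1e-12)
  expect_gte(min(eigen(tls$L, symmetric = TRUE)$values), -1e-12)
  # identity covariance partitions trivially
  vcI <- vc
  vcI$blocks[, , 1, 1, 1] <- diag(6)
  tlsI <- tls_from_vcov(vcI, 1)
  expect_equal(tlsI$T, diag(3)); expect_equal(tlsI$L, diag(3))
  expect_equal(tlsI$S, matrix(0, 3, 3))

  adps <- adps_from_vcov(model$crystal, vc)
  expect_equal(b_equivalent(diag(3)), 8 * pi^2, tolerance = 1e-12)
  # an atom placed at the group origin has U = T exactly
  cr2 <- model$crystal
  cr2$groups[[1]]$atoms <- rbind(cr2$groups[[1]]$atoms[1, ],
                                 cr2$groups[[1]]$atoms)
  cr2$groups[[1]]$atoms[1, c("x", "y", "z")] <- cr2$groups[[1]]$origin
  a2 <- adps_from_vcov(cr2, vc)
  U1 <- vec_to_sym_test(as.numeric(a2[1, c("u11", "u22", "u33",
                                           "u12", "u13", "u23")]))
  expect_equal(U1, tls$T, tolerance = 1e-12)
})

test_that("ADPs match a Monte-Carlo displacement covariance", {
  model <- toy_p1_model()
  vc <- vcov_supercell(model, c(2, 2, 1))
  W <- vcov_block(vc, c(0, 0, 0), 1, 1)
  g <- model$crystal$groups[[1]]
  x <- as.numeric(g$atoms[3, c("x", "y", "z")]) - g$origin
  A <- projection_matrix(x)
  U <- A %*% W %*% t(A)
  # sample generalized displacements with covariance W and accumulate u u^T
  set.seed(7)
  e <- eigen(W, symmetric = TRUE)
  half <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  n <- 40000
  wsamp <- half %*% matrix(stats::rnorm(6 * n), 6, n)
  u <- A %*% wsamp
  Umc <- (u %*% t(u)) / n
  expect_lt(max(abs(Umc - U)) / max(abs(U)), 0.05)
})

test_that("center-of-mass joint-ADPs are symmetrized translational blocks", {
  model <- toy_p1_model()
  vc <- vcov_supercell(model, c(2, 2, 1))
  jt <- com_joint_adps(vc)
  tls <- tls_from_vcov(vc, 1)
  z <- jt[jt$n1 == 0 & jt$n2 == 0 & jt$n3 == 0 & jt$ki == 1 & jt$kj == 1, ]
  expect_equal(vec_to_sym_test(as.numeric(z[1, c("v11", "v22", "v33",
                                                 "v12", "v13", "v23")])),
               tls$T, tolerance = 1e-12)
  # symmetrization is idempotent: every V is symmetric by construction,
  # and matches the brute-force covariance blocks
  bf <- brute_force_vcov(model, c(2, 2, 1))
  r <- jt[jt$n1 == 1 & jt$n2 == 0 & jt$n3 == 0 & jt$ki == 1 & jt$kj == 1, ]
  B <- vcov_block(bf, c(-1, 0, 0), 1, 1)[1:3, 1:3]
  expect_equal(vec_to_sym_test(as.numeric(r[1, c("v11", "v22", "v33",
                                                 "v12", "v13", "v23")])),
               (B + t(B)) / 2, tolerance = 1e-8)
})

test_that("equipartition: mode sampling converges to the Eq.-3 covariance", {
  model <- toy_p1_model()
  nc <- c(2, 1, 1)
  vc <- vcov_supercell(model, nc)
  # sample via the brute-force supercell modes (independent path) and
  # compare the zero-offset block
  bf <- brute_force_vcov(model, nc)
  expect_lt(max(abs(vcov_block(vc, 0) - vcov_block(bf, 0))), 1e-8)
})
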