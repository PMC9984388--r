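# 3D-delta-PDF computation, Patterson origin peak, joint-ADP deconvolution
# and validation metrics.

test_that("delta-PDF of a single cosine is a pair of lattice-node peaks", {
  cell <- unit_cell(13, 13.5, 14, 88, 92, 95, "P1")
  map <- voxel_map(cell, subdiv = 3, hmax = 4)
  h <- map_hgrid(map)
  map$I <- array(2 * cos(2 * pi * h[, 1]), map$dims)
  map$measured[] <- TRUE; map$sigma[] <- 0
  pdf <- compute_delta_pdf(map, res_cutoff = 0.5, assume_variational = TRUE,
                           oversample_r = 1)
  vals <- pdf$values
  node <- pdf$dims[1] / map$subdiv[1] # index offset of t = (1,0,0)
  peak_pos <- abs(vals[node + 1, 1, 1])
  expect_gt(peak_pos, 0.9 * max(abs(vals)))
  # everything away from +-(1,0,0) is zero
  vals[node + 1, 1, 1] <- 0
  vals[pdf$dims[1] - node + 1, 1, 1] <- 0
  expect_lt(max(abs(vals)), 1e-8 * peak_pos)
  # all-zero map gives an all-zero delta-PDF
  map0 <- map; map0$I[] <- 0
  expect_equal(max(abs(compute_delta_pdf(map0, 0.5, TRUE)$values)), 0)
})

test_that("Patterson map is centrosymmetric with its maximum at the origin", {
  toy <- toy_p1()
  br <- bragg_intensities(toy$crystal, hmax = 6, res_cutoff = 2.2)
  patt <- patterson_map(br, toy$cell, hmax = 8, res_cutoff = 2.2)
  v <- patt$values
  n <- dim(v)
  rev_idx <- lapply(1:3, function(i) c(1, n[i]:2))
  expect_lt(max(abs(v - v[rev_idx[[1]], rev_idx[[2]], rev_idx[[3]]])),
            1e-8 * max(abs(v)))
  expect_equal(which.max(v), 1L) # origin at index (1,1,1)
})

test_that("single-atom Patterson peak matches the Gaussian autocorrelation", {
  uc <- unit_cell(16, 16, 16)
  sig <- 0.7
  asu <- data.frame(element = "C", x = 8, y = 8, z = 8, sigma = sig)
  cr <- expand_to_unit_cell(asu, uc)
  br <- bragg_intensities(cr, hmax = 7)
  patt <- patterson_map(br, uc, hmax = 8)
  # autocorrelation of a Z-electron Gaussian: width sqrt(2) sigma; compare
  # shape along an axis (band-limitation affects the absolute scale)
  r <- (0:4) * 16 / dim(patt$values)[1]
  got <- patt$values[1:5, 1, 1]
  expected <- exp(-r^2 / (4 * sig^2))
  expect_lt(max(abs(got / got[1] - expected)), 0.03)
})

test_that("peak crop applies the spherical mask", {
  toy <- toy_p1()
  br <- bragg_intensities(toy$crystal, hmax = 6, res_cutoff = 2.2)
  patt <- patterson_map(br, toy$cell, hmax = 8, res_cutoff = 2.2)
  crop <- latticevibes:::crop_peak(patt, c(0, 0, 0), d = 3)
  rn <- sqrt(rowSums(crop$r^2))
  expect_true(all(crop$values[rn >= 3] == 0))
  expect_true(any(crop$values[rn < 3] != 0))
})

test_that("deconvolution inverts the forward convolution model exactly", {
  # criterion: build the peak by convolution with known V (in reciprocal
  # space: Y = X * (q.Vq)), then deconvolve; recovery < 1% per component
  toy <- toy_p1()
  br <- bragg_intensities(toy$crystal, hmax = 6, res_cutoff = 2.2)
  patt <- patterson_map(br, toy$cell, hmax = 8, res_cutoff = 2.2)
  crop <- latticevibes:::crop_peak(patt, c(0, 0, 0), d = 3)
  crop$recip <- toy$cell$recip
  X <- crop$values # masked Patterson peak
  V <- matrix(c(0.05, 0.01, 0, 0.01, 0.08, 0.02, 0, 0.02, 0.11), 3, 3)
  # forward model in reciprocal space on the crop grid
  nc <- crop$dims
  Xf <- stats::fft(X, inverse = TRUE)
  freq <- lapply(1:3, function(i) {
    j <- 0:(nc[i] - 1); jw <- ifelse(j > nc[i] / 2, j - nc[i], j)
    jw / (nc[i] * crop$step_cells[i])
  })
  hh <- as.matrix(expand.grid(freq[[1]], freq[[2]], freq[[3]]))
  q <- hh %*% t(toy$cell$recip)
  qVq <- rowSums((q %*% V) * q)
  Yf <- Xf * array(qVq, nc)
  peak <- Re(stats::fft(Yf)) / prod(nc)
  crop2 <- crop
  crop2$values <- peak # already masked through X
  dec <- deconvolve_joint_adp(crop2, X, exclusion = 5, res_cutoff = 2.2)
  expect_lt(max(abs(dec$V - V)), 0.01 * sum(diag(V)) / 3)
  # zero peak gives a zero joint-ADP
  crop0 <- crop; crop0$values[] <- 0
  dec0 <- deconvolve_joint_adp(crop0, X, exclusion = 5, res_cutoff = 2.2)
  expect_lt(max(abs(dec0$V)), 1e-12)
  # linearity: V-hat of a sum of peaks is the sum of V-hats
  V2 <- diag(c(0.02, 0.03, 0.01))
  qV2q <- rowSums((q %*% V2) * q)
  peak2 <- Re(stats::fft(Xf * array(qV2q, nc))) / prod(nc)
  crop3 <- crop; crop3$values <- peak + peak2
  dec3 <- deconvolve_joint_adp(crop3, X, exclusion = 5, res_cutoff = 2.2)
  expect_equal(dec3$V, dec$V + V2, tolerance = 1e-6)
})

test_that("full-pipeline recovery on a translational toy crystal", {
  fx <- toy_surrogate()
  map <- simulate_halo_map(fx$model, subdiv = 5, hmax = 6)
  br <- bragg_intensities(fx$toy$crystal, hmax = 6, res_cutoff = 2.2)
  dv <- discoball(map, br, d = 3, exclusion = 5, res_cutoff = 2.2,
                  assume_variational = TRUE, oversample_r = 2)
  vc <- vcov_supercell(fx$model, c(5, 5, 5))
  eff <- unwrap_offsets(effective_joint_adp(com_joint_adps(vc)), c(5, 5, 5))
  v <- validate_model(dv, eff)
  expect_gt(v$r_total, 0.99)
  expect_gt(v$r_aniso, 0.95)
  expect_lt(abs(v$slope - 1), 0.1)
})

test_that("effective joint-ADP averages the per-group diagonal blocks", {
  om <- toy_ortho_model()
  vc <- vcov_supercell(om, c(2, 2, 1))
  jt <- com_joint_adps(vc)
  eff <- effective_joint_adp(jt)
  # hand-average for a chosen offset
  sub <- jt[jt$n1 == 1 & jt$n2 == 0 & jt$n3 == 0 & jt$ki == jt$kj, ]
  expect_identical(nrow(sub), 4L)
  hand <- colMeans(sub[, c("v11", "v22", "v33", "v12", "v13", "v23")])
  got <- eff[eff$n1 == 1 & eff$n2 == 0 & eff$n3 == 0, ]
  expect_equal(as.numeric(got[, c("v11", "v22", "v33", "v12", "v13",
                                  "v23")]),
               as.numeric(hand), tolerance = 1e-12)
  # K = 1 is the identity map
  m1 <- toy_p1_model()
  vc1 <- vcov_supercell(m1, c(2, 1, 1))
  jt1 <- com_joint_adps(vc1)
  eff1 <- effective_joint_adp(jt1)
  expect_equal(eff1$v11, jt1$v11[jt1$ki == 1 & jt1$kj == 1])
})

test_that("split_adp produces a traceless anisotropic part", {
  s <- split_adp(diag(3))
  expect_equal(s$total, 3)
  expect_equal(s$aniso, matrix(0, 3, 3))
  s2 <- split_adp(diag(c(2, 1, 0)))
  expect_equal(s2$total, 3)
  expect_equal(s2$aniso, diag(c(1, 0, -1)))
  set.seed(5)
  for (i in 1:10) {
    A <- matrix(stats::rnorm(9), 3, 3); V <- (A + t(A)) / 2
    expect_lt(abs(sum(diag(split_adp(V)$aniso))), 1e-12)
  }
})

test_that("validate_model metrics behave on constructed sets", {
  df <- data.frame(n1 = 0:3, n2 = 0, n3 = 0,
                   v11 = c(0.3, 0.1, 0.05, 0.01),
                   v22 = c(0.2, 0.12, 0.03, 0.02),
                   v33 = c(0.25, 0.09, 0.04, 0.015),
                   v12 = c(0.01, 0.005, 0, 0), v13 = 0, v23 = 0)
  v <- validate_model(df, df)
  expect_equal(v$r_total, 1)
  expect_equal(v$slope, 1, tolerance = 1e-12)
  expect_equal(v$intercept, 0, tolerance = 1e-12)
  expect_equal(v$r_aniso, 1)
  shifted <- df
  shifted[, c("v11", "v22", "v33")] <- df[, c("v11", "v22", "v33")] + 0.05
  v2 <- validate_model(shifted, df)
  expect_equal(v2$r_total, 1)
  expect_equal(v2$intercept, 0.15, tolerance = 1e-12)
  expect_equal(v2$slope, 1, tolerance = 1e-12)
})
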