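# Isotropic/variational splitting, missing-voxel filling, robust
# Savitzky-Golay regridding, target maps, shell statistics.

radial_map <- function(profile = function(s) exp(-40 * s^2), subdiv = 3,
                       hmax = 4) {
  cell <- unit_cell(13, 13.5, 14, 88, 92, 95, "P1")
  map <- voxel_map(cell, subdiv, hmax)
  s <- latticevibes:::map_qnorm(map) / (2 * pi)
  map$I <- array(profile(as.numeric(s)), map$dims)
  map$sigma[] <- 0.01
  map$measured[] <- TRUE
  map
}

test_that("split_isotropic removes radial signal and is additive", {
  map <- radial_map()
  sp <- split_isotropic(map)
  expect_lt(max(abs(sp$map$I)), 0.02 * max(map$I))
  # adding a radial profile to a structured map leaves variational intact
  model <- toy_p1_model()
  halo <- simulate_halo_map(model, subdiv = 3, hmax = 4)
  halo$sigma[] <- 0.01
  v1 <- split_isotropic(halo)$map$I
  halo2 <- halo
  s <- latticevibes:::map_qnorm(halo) / (2 * pi)
  halo2$I <- halo$I + array(50 * exp(-30 * as.numeric(s)^2), halo$dims)
  v2 <- split_isotropic(halo2)$map$I
  expect_lt(max(abs(v1 - v2)), 0.02 * diff(range(halo$I)))
  # synthetic radial + halo: the recovered profile difference matches the
  # injected radial generator (the halo's own isotropic part cancels)
  prof1 <- split_isotropic(halo)$profile
  prof2 <- split_isotropic(halo2)$profile
  truth <- 50 * exp(-30 * prof2$s^2)
  resid <- (prof2$mean - prof1$mean) - truth
  expect_lt(stats::median(abs(resid)) / 50, 0.01)
})

test_that("fill_missing fills from face neighbors until convergence", {
  map <- radial_map(function(s) rep(3.3, length(s)))
  # single missing voxel in a constant map gets the constant
  m1 <- map; m1$measured[5, 5, 5] <- FALSE; m1$I[5, 5, 5] <- NA
  f1 <- fill_missing(m1)
  expect_equal(f1$I[5, 5, 5], 3.3)
  expect_true(all(f1$measured))
  # fully missing map: nothing fillable, all flagged
  m2 <- map; m2$measured[] <- FALSE
  f2 <- fill_missing(m2)
  expect_identical(attr(f2, "n_unfilled"), length(m2$I))
  # checkerboard missing pattern converges to the explicit oracle
  m3 <- radial_map()
  idx <- which(array(TRUE, m3$dims))
  ai <- arrayInd(idx, m3$dims)
  chk <- (rowSums(ai) %% 2) == 0
  m3$measured[idx[chk]] <- FALSE
  m3$I[idx[chk]] <- NA
  f3 <- fill_missing(m3)
  expect_true(all(f3$measured))
  # oracle: one explicit pass fills every checkerboard hole (all six
  # neighbors of a missing voxel are measured)
  oracle <- m3$I
  d <- m3$dims
  for (v in idx[chk]) {
    a <- arrayInd(v, d)
    nb <- c()
    for (ax in 1:3) for (dd in c(-1, 1)) {
      p <- a; p[ax] <- p[ax] + dd
      if (p[ax] >= 1 && p[ax] <= d[ax]) nb <- c(nb, m3$I[p[1], p[2], p[3]])
    }
    oracle[a[1], a[2], a[3]] <- mean(nb, na.rm = TRUE)
  }
  expect_equal(f3$I, oracle, tolerance = 1e-12)
})

test_that("fill and split commute with uniform intensity scaling", {
  m <- radial_map()
  m$measured[3, 3, 3] <- FALSE; m$I[3, 3, 3] <- NA
  f1 <- fill_missing(m)
  m2 <- m; m2$I <- 5 * m$I
  f2 <- fill_missing(m2)
  expect_equal(f2$I, 5 * f1$I, tolerance = 1e-12)
  v1 <- split_isotropic(f1)$map$I
  v2 <- split_isotropic(f2)$map$I
  expect_equal(v2, 5 * v1, tolerance = 1e-6)
})

test_that("bisquare weight matches its defining branches", {
  expect_equal(bisquare_weight(0, 1), 1)
  expect_equal(bisquare_weight(6, 1), 0)
  expect_equal(bisquare_weight(-7, 1), 0)
  r <- 2.4; m <- 1.1
  expect_equal(bisquare_weight(r, m), (1 - (r / (6 * m))^2)^2)
  expect_true(all(bisquare_weight(seq(-10, 10, 0.5), 1) >= 0))
  expect_true(all(bisquare_weight(seq(-10, 10, 0.5), 1) <= 1))
})

test_that("robust regrid reproduces band-limited data and rejects outliers", {
  cell <- unit_cell(13, 13.5, 14, 88, 92, 95, "P1")
  map <- voxel_map(cell, 3, 4)
  h <- latticevibes:::map_hgrid(map)
  q <- q_cartesian(cell, h)
  f <- exp(-rowSums(q^2) / 6) * (1 + 0.3 * sin(3 * q[, 1]))
  map$I <- array(f, map$dims)
  map$sigma[] <- 0.01
  map$measured[] <- TRUE
  tg <- robust_savgol_regrid(map, c(1, 1, 1))
  htar <- latticevibes:::map_hgrid(tg)
  qtar <- q_cartesian(cell, htar)
  ftar <- exp(-rowSums(qtar^2) / 6) * (1 + 0.3 * sin(3 * qtar[, 1]))
  ok <- as.logical(tg$measured)
  err <- abs(as.numeric(tg$I)[ok] - ftar[ok]) / diff(range(f))
  expect_lt(max(err), 0.005)
  expect_true(all(is.finite(as.numeric(tg$sigma)[ok])))
  # one gross outlier changes the result by < 0.1%
  m2 <- map
  m2$I[14, 14, 14] <- m2$I[14, 14, 14] + 100
  tg2 <- robust_savgol_regrid(m2, c(1, 1, 1))
  both <- ok & as.logical(tg2$measured)
  expect_lt(max(abs(as.numeric(tg2$I)[both] - as.numeric(tg$I)[both])) /
              diff(range(f)), 0.001)
  # sparse neighborhoods are flagged missing
  m3 <- map
  m3$measured[] <- FALSE
  m3$measured[1:3, 1:3, 1:3] <- TRUE
  tg3 <- robust_savgol_regrid(m3, c(1, 1, 1))
  expect_false(all(tg3$measured))
})

test_that("build_target_map is linear in the experimental map", {
  model <- toy_p1_model()
  map <- simulate_halo_map(model, subdiv = 3, hmax = 3)
  map$sigma[] <- 0.02
  z <- map; z$I[] <- 0; z$sigma[] <- 0.02
  t_map <- build_target_map(map, model, c(1, 1, 1), robust = FALSE)
  t_zero <- build_target_map(z, model, c(1, 1, 1), robust = FALSE)
  # zero experimental map: target = (k = 0 lattice term) - regrid(lattice)
  ext <- simulate_halo_map(model, subdiv = 1, hmax = 3)
  ok <- as.logical(t_zero$measured)
  # linearity: target(map) - target(zero) = regrid(map)
  lat <- simulate_halo_map(model, subdiv = 3, hmax = 3)
  internal <- map; internal$I <- map$I - lat$I
  direct <- robust_savgol_regrid(internal, c(1, 1, 1), robust = FALSE)
  zero_int <- z; zero_int$I <- z$I - lat$I
  direct0 <- robust_savgol_regrid(zero_int, c(1, 1, 1), robust = FALSE)
  expect_equal(t_map$I[ok] - t_zero$I[ok], direct$I[ok] - direct0$I[ok],
               tolerance = 1e-8)
  expect_equal(t_zero$I[ok], direct0$I[ok] + ext$I[ok], tolerance = 1e-8)
})

test_that("shell statistics: self-correlation and negation", {
  model <- toy_p1_model()
  map <- simulate_halo_map(model, subdiv = 3, hmax = 4)
  map$sigma[] <- 0.01
  st <- shell_stats(map, map)
  good <- !st$flagged & is.finite(st$cc)
  expect_true(all(abs(st$cc[good] - 1) < 1e-10))
  neg <- map; neg$I <- -map$I
  st2 <- shell_stats(map, neg)
  good2 <- !st2$flagged & is.finite(st2$cc)
  expect_true(all(abs(st2$cc[good2] + 1) < 1e-10))
  expect_true(all(st$sd_a >= 0, na.rm = TRUE))
  expect_true(all(diff(st$s_mid) > 0))
})

test_that("shell CC of noisy copies matches the attenuation model", {
  model <- toy_p1_model()
  map <- simulate_halo_map(model, subdiv = 3, hmax = 4)
  map$sigma[] <- 0
  sp <- split_isotropic(map)
  sig <- 0.5 * stats::sd(sp$map$I)
  a <- make_noisy_map(map, sigma0 = sig, seed = 21)
  b <- make_noisy_map(map, sigma0 = sig, seed = 22)
  st <- shell_stats(a, b, bin_width = 0.1)
  big <- which(st$n > 300)
  # CC between two noisy copies ~ Var(signal)/(Var(signal) + sigma^2)
  v <- split_isotropic(map, 0.1)$map$I
  s <- latticevibes:::map_qnorm(map) / (2 * pi)
  for (i in big) {
    sel <- floor(as.numeric(s) / 0.1) == round(st$s_mid[i] / 0.1 - 0.5)
    expected <- stats::var(as.numeric(v)[sel]) /
      (stats::var(as.numeric(v)[sel]) + sig^2)
    expect_lt(abs(st$cc[i] - expected), 0.15)
  }
})
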