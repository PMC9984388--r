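# Robust error-weighted Savitzky-Golay regridding of diffuse maps and
# target-map assembly for comparison with fixed-supercell (MD) simulations.

#' Bisquare re-weighting factor
#'
#' `w = (1 - (r / (6 m))^2)^2` for `|r| < 6 m` and 0 otherwise, where `m`
#' is the median absolute deviation of the inverse-sigma-weighted
#' residuals.
#'
#' @param r residuals (inverse-sigma weighted).
#' @param m median absolute deviation of the residuals.
#' @return weights in `[0, 1]`.
#' @export
bisquare_weight <- function(r, m) {
  if (m <= 0) return(rep(1, length(r)))
  w <- (1 - (r / (6 * m))^2)^2
  w[abs(r) >= 6 * m] <- 0
  w
}

# second-order polynomial design in the scaled offsets
quad_design <- function(dx) {
  cbind(1, dx,
        dx[, 1]^2, dx[, 2]^2, dx[, 3]^2,
        dx[, 1] * dx[, 2], dx[, 1] * dx[, 3], dx[, 2] * dx[, 3])
}

#' Robust error-weighted Savitzky-Golay regridding
#'
#' Interpolates a diffuse map onto a coarser target grid. For every target
#' voxel, parent voxels inside a spherical neighborhood of radius
#' `(3 v_t / (4 pi))^(1/3)` (v_t the target voxel volume in reciprocal
#' space) are fit by a second-order polynomial with inverse-variance
#' weights, and the polynomial is evaluated at the target point with
#' propagated sigma. A second pass re-weights each parent voxel by the
#' bisquare factor of its residual (computed by cubic interpolation of the
#' first-pass result back to the parent grid) and repeats the fit, making
#' the filter robust to outliers.
#'
#' @param map parent `lv_map` (with `sigma` set).
#' @param subdiv_target target subdivisions per reciprocal-lattice point
#'   (length 3, odd).
#' @param min_voxels neighborhoods with fewer usable parent voxels are
#'   flagged missing.
#' @param robust perform the bisquare second pass (default TRUE).
#' @return target `lv_map` with `I`, `sigma` and `measured`.
#' @export
robust_savgol_regrid <- function(map, subdiv_target = c(1, 1, 1),
                                 min_voxels = 10, robust = TRUE) {
  target <- voxel_map(map$cell, subdiv_target, map$hmax)
  hpar <- map_hgrid(map)
  qpar <- q_cartesian(map$cell, hpar)
  ok <- as.logical(map$measured) & is.finite(as.numeric(map$I))
  Ip <- as.numeric(map$I)
  sp <- pmax(as.numeric(map$sigma), 1e-12)
  htar <- map_hgrid(target)
  qtar <- q_cartesian(map$cell, htar)
  # target voxel volume in reciprocal space and the neighborhood radius
  vt <- abs(det(map$cell$recip)) / prod(subdiv_target)
  rcut <- (3 * vt / (4 * pi))^(1 / 3)
  run_pass <- function(wextra) {
    vals <- rep(NA_real_, nrow(htar))
    sigs <- rep(NA_real_, nrow(htar))
    for (i in seq_len(nrow(htar))) {
      d2 <- (qpar[, 1] - qtar[i, 1])^2 + (qpar[, 2] - qtar[i, 2])^2 +
        (qpar[, 3] - qtar[i, 3])^2
      nb <- which(d2 <= rcut^2 & ok & wextra > 0)
      if (length(nb) < min_voxels) next
      dx <- sweep(qpar[nb, , drop = FALSE], 2, qtar[i, ]) / rcut
      X <- quad_design(dx)
      w <- wextra[nb] / sp[nb]^2
      XtW <- t(X * w)
      M <- XtW %*% X
      cf <- tryCatch(solve(M, XtW %*% Ip[nb]), error = function(e) NULL)
      if (is.null(cf)) next
      vals[i] <- cf[1]
      Minv <- tryCatch(solve(M), error = function(e) NULL)
      if (!is.null(Minv)) sigs[i] <- sqrt(pmax(Minv[1, 1], 0))
    }
    list(vals = vals, sigs = sigs)
  }
  p1 <- run_pass(rep(1, length(Ip)))
  if (robust) {
    # residuals on the parent grid via cubic interpolation of pass 1
    tvals <- array(p1$vals, target$dims)
    filled <- tvals
    if (anyNA(filled)) {
      tmp <- target; tmp$I <- tvals
      tmp$measured <- array(is.finite(tvals), target$dims)
      tmp <- fill_missing(tmp)
      filled <- tmp$I
      filled[is.na(filled)] <- 0
    }
    idx <- sweep(sweep(hpar, 2, map$hmax, "+"), 2, subdiv_target, "*")
    pred <- interp_tricubic(filled, idx)
    r <- (Ip - pred) / sp
    r[!ok] <- NA
    m <- stats::median(abs(r[ok]))
    w2 <- rep(0, length(Ip))
    w2[ok] <- bisquare_weight(r[ok], m)
    p2 <- run_pass(w2)
  } else p2 <- p1
  target$I <- array(p2$vals, target$dims)
  target$sigma <- array(p2$sigs, target$dims)
  target$measured <- array(is.finite(p2$vals), target$dims)
  target
}

#' Build a target diffuse map for comparison with a fixed-supercell model
#'
#' Subtracts the full-supercell lattice simulation from the experimental
#' map, regrids the internal-motion residual onto the (coarser) grid of the
#' comparison supercell with the robust Savitzky-Golay filter, and adds
#' back the one-phonon scattering at the wavevectors allowed by that
#' supercell (k = 0 only, for a single unit cell).
#'
#' @param map experimental `lv_map`.
#' @param model refined `lv_enm` lattice model.
#' @param subdiv_md target subdivisions (the comparison supercell's
#'   reciprocal sampling; `c(1,1,1)` for a single unit cell).
#' @param kBT temperature scale used for the simulations.
#' @param sf structure-factor route (see [one_phonon_intensity()]).
#' @param robust see [robust_savgol_regrid()].
#' @return target `lv_map` on the coarse grid, with propagated sigma.
#' @export
build_target_map <- function(map, model, subdiv_md = c(1, 1, 1), kBT = 1,
                             sf = "atoms", robust = TRUE) {
  lat <- simulate_halo_map(model, subdiv = map$subdiv, hmax = map$hmax,
                           kBT = kBT, sf = sf)
  internal <- subtract_lattice(map, lat)$map
  target <- robust_savgol_regrid(internal, subdiv_md, robust = robust)
  ext <- simulate_halo_map(model, subdiv = subdiv_md, hmax = map$hmax,
                           kBT = kBT, sf = sf)
  target$I <- target$I + ext$I
  target
}
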