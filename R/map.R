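# Voxelized reciprocal-space maps on subdivided Miller-index grids, and the
# shared map utilities: isotropic/variational splitting, missing-voxel
# filling, and resolution-shell statistics.

#' Create an empty diffuse-scattering voxel map
#'
#' The grid samples fractional Miller indices `h` from `-hmax` to `hmax` in
#' steps of `1/subdiv` along each axis, so grid centers coincide with
#' integer Miller indices. Subdivisions must be odd so that every voxel is
#' associated with a reciprocal-lattice point.
#'
#' @param cell an [unit_cell()].
#' @param subdiv integer odd subdivisions per reciprocal-lattice point
#'   (length 3, recycled).
#' @param hmax maximum integer Miller index per axis (length 3, recycled).
#' @return object of class `lv_map` with `I`, `sigma` and `measured` arrays
#'   of dimension `2*hmax*subdiv + 1`.
#' @export
voxel_map <- function(cell, subdiv = 3, hmax = 4) {
  subdiv <- as.integer(rep_len(subdiv, 3))
  hmax <- as.integer(rep_len(hmax, 3))
  if (any(subdiv %% 2 == 0)) stop("subdivisions must be odd")
  n <- 2L * hmax * subdiv + 1L
  structure(list(cell = cell, subdiv = subdiv, hmax = hmax, dims = n,
                 I = array(NA_real_, n), sigma = array(NA_real_, n),
                 measured = array(FALSE, n)),
            class = "lv_map")
}

#' @export
print.lv_map <- function(x, ...) {
  cat(sprintf("<lv_map> %dx%dx%d voxels, subdiv (%s), hmax (%s), %.1f%% measured\n",
              x$dims[1], x$dims[2], x$dims[3],
              paste(x$subdiv, collapse = ","), paste(x$hmax, collapse = ","),
              100 * mean(x$measured)))
  invisible(x)
}

# fractional Miller index along each axis
map_axes <- function(map) {
  lapply(1:3, function(i) {
    (seq_len(map$dims[i]) - 1L - map$hmax[i] * map$subdiv[i]) / map$subdiv[i]
  })
}

# nvox x 3 matrix of fractional Miller indices in array order
map_hgrid <- function(map) {
  ax <- map_axes(map)
  as.matrix(expand.grid(h = ax[[1]], k = ax[[2]], l = ax[[3]]))
}

# |q| in 1/A and scattering-vector magnitude s = 1/d in 1/A per voxel
map_qnorm <- function(map) {
  h <- map_hgrid(map)
  q <- map$cell$recip %*% t(h)
  array(sqrt(colSums(q^2)), map$dims)
}

#' Split a map into its isotropic profile and variational component
#'
#' Fits a smooth one-dimensional interpolant (resolution-binned means joined
#' by a smoothing spline) to intensity versus scattering-vector magnitude
#' and subtracts it, leaving the variational (anisotropic) intensity.
#'
#' @param map an `lv_map` with measured intensities.
#' @param bin_width resolution-bin width in 1/A (of s = 1/d).
#' @return list with `profile` (data.frame `s`, `mean`), `iso` (array of the
#'   interpolant per voxel) and `map` (the variational `lv_map`).
#' @export
split_isotropic <- function(map, bin_width = 0.02) {
  s <- map_qnorm(map) / (2 * pi)
  ok <- map$measured & is.finite(map$I)
  if (!any(ok)) stop("map has no measured voxels")
  bins <- floor(s[ok] / bin_width)
  mu <- tapply(map$I[ok], bins, mean)
  sc <- (as.numeric(names(mu)) + 0.5) * bin_width
  iso_fun <- if (length(mu) >= 8) {
    fit <- stats::smooth.spline(sc, as.numeric(mu))
    function(x) stats::predict(fit, x)$y
  } else {
    stats::approxfun(sc, as.numeric(mu), rule = 2)
  }
  iso <- array(iso_fun(as.numeric(s)), map$dims)
  out <- map
  out$I <- map$I - iso
  list(profile = data.frame(s = sc, mean = as.numeric(mu)), iso = iso,
       map = out)
}

#' Fill missing voxels from face-neighbor means
#'
#' Each missing voxel is replaced by the mean of its (up to six) measured
#' face neighbors; the pass is iterated until no fillable voxel remains.
#' Voxels that can never be reached stay flagged as missing.
#'
#' @param map an `lv_map`.
#' @param max_iter safety cap on the number of passes.
#' @return the filled `lv_map` (filled voxels are marked measured; an
#'   attribute `n_unfilled` reports the number of voxels left missing).
#' @export
fill_missing <- function(map, max_iter = 1000) {
  I <- map$I
  meas <- map$measured & is.finite(I)
  I[!meas] <- NA_real_
  for (iter in seq_len(max_iter)) {
    if (all(meas)) break
    vals <- array(0, dim(I)); cnt <- array(0L, dim(I))
    for (ax in 1:3) for (dir in c(-1L, 1L)) {
      sh <- shift_array(I, ax, dir)
      good <- !is.na(sh)
      vals[good] <- vals[good] + sh[good]
      cnt <- cnt + good
    }
    fill <- !meas & cnt > 0
    if (!any(fill)) break
    I[fill] <- vals[fill] / cnt[fill]
    meas <- meas | fill
  }
  map$I <- I
  map$measured <- meas
  attr(map, "n_unfilled") <- sum(!meas)
  map
}

# shift a 3d array by one voxel along an axis, padding with NA
shift_array <- function(a, axis, dir) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- idx; dst <- idx
  if (dir > 0) { src[[axis]] <- 1:(d[axis] - 1); dst[[axis]] <- 2:d[axis] }
  else { src[[axis]] <- 2:d[axis]; dst[[axis]] <- 1:(d[axis] - 1) }
  out <- array(NA_real_, d)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Resolution-shell statistics for one or two maps
#'
#' Mean intensity of `map_a` per shell, and (after subtracting each map's
#' isotropic profile) the standard deviation of the variational intensity
#' and, when `map_b` is given, the Pearson correlation between the two
#' variational maps per shell. Shells with fewer than `min_count` voxels are
#' flagged.
#'
#' @param map_a,map_b `lv_map`s on the same grid (`map_b` optional).
#' @param bin_width shell width in 1/A.
#' @param min_count minimum voxels per shell.
#' @return data.frame with `s_mid`, `n`, `mean_a`, `sd_a`, `sd_b`, `cc`,
#'   `flagged`.
#' @export
shell_stats <- function(map_a, map_b = NULL, bin_width = 0.02,
                        min_count = 5) {
  s <- map_qnorm(map_a) / (2 * pi)
  va <- split_isotropic(map_a, bin_width)$map$I
  ok <- map_a$measured & is.finite(map_a$I)
  vb <- NULL
  if (!is.null(map_b)) {
    stopifnot(all(dim(map_b$I) == dim(map_a$I)))
    vb <- split_isotropic(map_b, bin_width)$map$I
    ok <- ok & map_b$measured & is.finite(map_b$I)
  }
  bins <- floor(as.numeric(s)[ok] / bin_width)
  ub <- sort(unique(bins))
  out <- data.frame(s_mid = (ub + 0.5) * bin_width, n = NA_integer_,
                    mean_a = NA_real_, sd_a = NA_real_, sd_b = NA_real_,
                    cc = NA_real_)
  Ia <- map_a$I[ok]; Va <- va[ok]
  Vb <- if (!is.null(vb)) vb[ok] else NULL
  for (i in seq_along(ub)) {
    sel <- bins == ub[i]
    out$n[i] <- sum(sel)
    out$mean_a[i] <- mean(Ia[sel])
    out$sd_a[i] <- stats::sd(Va[sel])
    if (!is.null(Vb)) {
      out$sd_b[i] <- stats::sd(Vb[sel])
      if (sum(sel) >= 2 && stats::sd(Va[sel]) > 0 && stats::sd(Vb[sel]) > 0)
        out$cc[i] <- stats::cor(Va[sel], Vb[sel])
    }
  }
  out$flagged <- out$n < min_count
  out
}
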