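# Tricubic (separable Catmull-Rom) interpolation on periodic 3D grids.
# Shared by the oversampled molecular transform, the Patterson-peak
# regridding, and the Savitzky-Golay residual pass.

# Catmull-Rom weights for fractional position t in [0, 1)
cr_weights <- function(t) {
  cbind((-t^3 + 2 * t^2 - t) / 2,
        (3 * t^3 - 5 * t^2 + 2) / 2,
        (-3 * t^3 + 4 * t^2 + t) / 2,
        (t^3 - t^2) / 2)
}

#' Tricubic interpolation on a periodic grid
#'
#' Separable Catmull-Rom interpolation of a (real or complex) 3D array at
#' arbitrary fractional indices, with periodic wrapping.
#'
#' @param arr 3D array (numeric or complex).
#' @param x n x 3 matrix of 0-based fractional voxel indices.
#' @return vector of interpolated values (complex when `arr` is complex).
#' @export
interp_tricubic <- function(arr, x) {
  x <- rbind_h(x)
  d <- dim(arr)
  i0 <- floor(x)
  tf <- x - i0
  w1 <- cr_weights(tf[, 1]); w2 <- cr_weights(tf[, 2]); w3 <- cr_weights(tf[, 3])
  out <- if (is.complex(arr)) complex(nrow(x)) else numeric(nrow(x))
  for (a in 0:3) {
    ia <- ((i0[, 1] + a - 1) %% d[1]) + 1
    for (b in 0:3) {
      ib <- ((i0[, 2] + b - 1) %% d[2]) + 1
      wab <- w1[, a + 1] * w2[, b + 1]
      for (cc in 0:3) {
        ic <- ((i0[, 3] + cc - 1) %% d[3]) + 1
        lin <- ia + d[1] * (ib - 1) + d[1] * d[2] * (ic - 1)
        out <- out + wab * w3[, cc + 1] * arr[lin]
      }
    }
  }
  out
}
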