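# Model-free estimation of inter-protein joint-ADPs: the variational
# diffuse map is Fourier-transformed to the 3D-delta-PDF, whose sharp peaks
# at lattice nodes are deconvolved against the Patterson origin peak by
# linear least squares in reciprocal space.

#' Compute the 3D-delta-PDF of a diffuse map
#'
#' The (variational) diffuse map is truncated to a resolution cutoff,
#' missing voxels are zero-filled, Friedel symmetry is completed, and the
#' map is FFT'd to real space. One edge plane per axis is dropped before the
#' FFT so that the periodic real-space grid contains every unit-cell
#' translation vector exactly.
#'
#' @param map an `lv_map`. Unless `assume_variational = TRUE`, the
#'   isotropic component is removed first via [split_isotropic()].
#' @param res_cutoff resolution truncation in Angstroms (default 1.6).
#' @param assume_variational set `TRUE` when the map is already variational
#'   (e.g. a pure one-phonon simulation).
#' @param oversample_r reciprocal zero-padding factor; values > 1 refine the
#'   real-space grid below the Nyquist step of the data band, which sharpens
#'   the spherical peak masks and suppresses aliasing in the deconvolution.
#' @return object of class `lv_pdf`: `values` (real array, origin at index
#'   1), `cell`, `subdiv`, `dims`, `step_cells` (grid step per axis in
#'   fractional unit cells).
#' @export
compute_delta_pdf <- function(map, res_cutoff = 1.6,
                              assume_variational = FALSE, oversample_r = 2) {
  if (!assume_variational) map <- split_isotropic(map)$map
  I <- map$I
  I[!map$measured | !is.finite(I)] <- 0
  s <- map_qnorm(map) / (2 * pi)
  I[s > 1 / res_cutoff] <- 0
  # drop the first plane along each axis: the grid then covers (-H, H] and
  # the number of samples per axis is an exact multiple of the subdivision
  I <- I[-1, -1, -1, drop = FALSE]
  n <- dim(I)
  # circularly shift so h = 0 comes first
  ctr <- map$hmax * map$subdiv # index of h = 0 after dropping one plane
  sh <- lapply(1:3, function(i)
    (((seq_len(n[i]) - 1 + (ctr[i] - 1)) %% n[i]) + 1))
  I <- I[sh[[1]], sh[[2]], sh[[3]]]
  # Friedel completion on the periodic grid (h -> -h modulo the grid period)
  # guarantees an exactly real transform
  rev_idx <- lapply(1:3, function(i) c(1, n[i]:2))
  I <- (I + I[rev_idx[[1]], rev_idx[[2]], rev_idx[[3]]]) / 2
  if (oversample_r > 1) {
    I <- zero_pad_reciprocal(I, as.integer(round(oversample_r * n)))
    n <- dim(I)
  }
  # P(t) = sum_h I(h) exp(-2 pi i h.t) * (voxel measure 1/prod(subdiv))
  P <- stats::fft(I) / prod(map$subdiv)
  if (max(abs(Im(P))) > 1e-8 * max(abs(Re(P)), 1e-300))
    stop("delta-PDF has unexpectedly large imaginary part")
  structure(list(values = Re(P), cell = map$cell, subdiv = map$subdiv,
                 dims = n, step_cells = map$subdiv / n),
            class = "lv_pdf")
}

# zero-pad a reciprocal-space array stored origin-first (DFT layout) to
# larger dimensions, preserving the frequency content; the Nyquist plane of
# an even-length axis is split half-and-half between +n/2 and -n/2 so that
# Friedel symmetry (realness of the transform) is preserved
zero_pad_reciprocal <- function(I, nnew) {
  for (ax in 1:3) {
    n <- dim(I)[ax]
    if (nnew[ax] == n) next
    stopifnot(nnew[ax] > n)
    d2 <- dim(I); d2[ax] <- nnew[ax]
    out <- array(0, d2)
    j <- 0:(n - 1)
    f <- ifelse(j > n / 2, j - n, j)
    src <- slice_index(dim(I), ax, j + 1)
    dst <- slice_index(d2, ax, ((f %% nnew[ax]) + nnew[ax]) %% nnew[ax] + 1)
    out[dst] <- I[src]
    if (n %% 2 == 0) {
      ny <- n / 2
      pos <- slice_index(d2, ax, ny + 1)
      neg <- slice_index(d2, ax, nnew[ax] - ny + 1)
      half <- I[slice_index(dim(I), ax, ny + 1)] / 2
      out[pos] <- half
      out[neg] <- half
    }
    I <- out
  }
  I
}

# logical/array index for assigning a set of planes along one axis
slice_index <- function(dims, ax, planes) {
  idx <- lapply(dims, seq_len)
  idx[[ax]] <- planes
  as.matrix(expand.grid(idx))
}

#' Bragg intensities of a crystal model
#'
#' `I(h) = |F_cell(q_h)|^2` with the cell structure factor summed over all
#' rigid groups (Gaussian atomic form factors). Optionally attenuated by
#' the lattice-disorder Debye-Waller factor implied by a model covariance.
#'
#' @param crystal an `lv_crystal`.
#' @param hmax integer Miller-index range per axis.
#' @param res_cutoff optional resolution truncation (Angstroms).
#' @return data.frame `h`, `k`, `l`, `I`, `d` (the origin reflection is
#'   excluded).
#' @export
bragg_intensities <- function(crystal, hmax = 8, res_cutoff = NULL) {
  hmax <- as.integer(rep_len(hmax, 3))
  hh <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                              l = -hmax[3]:hmax[3]))
  hh <- hh[rowSums(hh != 0) > 0, , drop = FALSE]
  d <- d_spacing(crystal$cell, hh)
  if (!is.null(res_cutoff)) {
    keep <- d >= res_cutoff
    hh <- hh[keep, , drop = FALSE]; d <- d[keep]
  }
  q <- q_cartesian(crystal$cell, hh)
  Fc <- complex(nrow(hh))
  qn2 <- rowSums(q^2)
  for (g in crystal$groups) {
    xyz <- as.matrix(g$atoms[, c("x", "y", "z")])
    zs <- g$atoms$occ * element_property(g$atoms$element, "z")
    sig <- if (!is.null(g$atoms$sigma)) g$atoms$sigma else rep(0.9, nrow(xyz))
    ff <- exp(-outer(qn2, sig^2) / 2) * matrix(zs, nrow(hh), length(zs),
                                               byrow = TRUE)
    Fc <- Fc + rowSums(ff * exp(1i * (q %*% t(xyz))))
  }
  data.frame(h = hh[, 1], k = hh[, 2], l = hh[, 3], I = Mod(Fc)^2, d = d)
}

#' Patterson map from Bragg intensities
#'
#' `P(r) = sum_h I(h) exp(-2 pi i h.r)` on a fractional grid over one unit
#' cell. The origin reflection is excluded (any constant offset is handled
#' by the low-resolution exclusion of the deconvolution).
#'
#' @param bragg data.frame `h`, `k`, `l`, `I`.
#' @param cell an [unit_cell()].
#' @param hmax grid half-extent (defaults to the data range).
#' @param res_cutoff optional resolution truncation, to match the band of
#'   the delta-PDF.
#' @return `lv_pdf`-like object (`subdiv = 1`, field of view one cell).
#' @export
patterson_map <- function(bragg, cell, hmax = NULL, res_cutoff = NULL) {
  if (is.null(hmax)) hmax <- max(abs(as.matrix(bragg[, c("h", "k", "l")])))
  hmax <- as.integer(rep_len(hmax, 3))
  if (!is.null(res_cutoff)) {
    d <- d_spacing(cell, as.matrix(bragg[, c("h", "k", "l")]))
    bragg <- bragg[d >= res_cutoff, , drop = FALSE]
  }
  n <- 2L * hmax
  A <- array(0, n)
  for (r in seq_len(nrow(bragg))) {
    h <- c(bragg$h[r], bragg$k[r], bragg$l[r])
    if (any(abs(h) > hmax) || all(h == 0)) next
    i <- ((h %% n) + n) %% n + 1
    A[i[1], i[2], i[3]] <- A[i[1], i[2], i[3]] + bragg$I[r]
    j <- (((-h) %% n) + n) %% n + 1
    if (!all(i == j)) A[j[1], j[2], j[3]] <- A[j[1], j[2], j[3]] + bragg$I[r]
  }
  # symmetric duplicates were added twice
  A <- A / 2
  A[1, 1, 1] <- 0
  P <- stats::fft(A)
  structure(list(values = Re(P), cell = cell, subdiv = c(1L, 1L, 1L),
                 dims = n, step_cells = 1 / n),
            class = "lv_pdf")
}

# crop a cube around a lattice node of an lv_pdf and apply a spherical mask
# of radius d (Angstroms); returns values, local Cartesian coordinates and
# the crop dimensions
crop_peak <- function(pdf, node = c(0, 0, 0), d = 4) {
  cell <- pdf$cell
  step_len <- sqrt(colSums(cell$ortho^2)) * pdf$step_cells
  half <- pmin(pmax(2L, as.integer(ceiling(d / step_len)) + 1L),
               pdf$dims %/% 2 - 1L)
  ctr <- as.numeric(node) / pdf$step_cells
  if (max(abs(ctr - round(ctr))) > 1e-9)
    stop("lattice node does not fall on the delta-PDF grid")
  ctr <- as.integer(round(ctr))
  idx <- lapply(1:3, function(i)
    (((ctr[i] - half[i]):(ctr[i] + half[i])) %% pdf$dims[i]) + 1)
  vals <- pdf$values[idx[[1]], idx[[2]], idx[[3]]]
  off <- as.matrix(expand.grid(a = -half[1]:half[1], b = -half[2]:half[2],
                               cc = -half[3]:half[3]))
  tloc <- sweep(off, 2, pdf$step_cells, "*")
  rloc <- t(cell$ortho %*% t(tloc))
  mask <- sqrt(rowSums(rloc^2)) < d
  vals[!mask] <- 0
  list(values = vals, r = rloc, dims = dim(vals), half = half,
       step_cells = pdf$step_cells, mask = array(mask, dim(vals)))
}

# interpolate the Patterson origin peak onto the crop grid of a delta-PDF
# peak and apply the same spherical mask
patterson_on_crop <- function(patt, crop, d = 4) {
  tloc <- crop$r # Cartesian; convert to fractional cells
  tf <- t(patt$cell$frac %*% t(tloc))
  idx <- sweep(tf, 2, patt$step_cells, "/")
  vals <- interp_tricubic(patt$values, idx)
  vals[!as.logical(crop$mask)] <- 0
  array(vals, crop$dims)
}

#' Deconvolve one delta-PDF lattice peak into a joint-ADP
#'
#' Inverse-FFTs the masked peak (`Y`) and the masked Patterson origin peak
#' (`X`) on the crop grid and solves the ordinary least squares problem
#' `Y(q) ~ X(q) * (q . V q)` for the six unique components of `V`,
#' excluding reciprocal samples with d-spacing larger than `exclusion`.
#'
#' @param crop masked peak region from `crop_peak`.
#' @param patt_crop masked Patterson on the same grid (`patterson_on_crop`).
#' @param exclusion low-resolution exclusion in Angstroms (default 5).
#' @param res_cutoff high-resolution limit of the sample domain (Angstroms);
#'   the peak-function model only holds inside the data band, so samples
#'   beyond it (mask ringing) are excluded.
#' @return list with `V` (3x3 symmetric, A^2), `residual` (norm), `cond`
#'   (condition number of the design), `n_samples`.
#' @export
deconvolve_joint_adp <- function(crop, patt_crop, exclusion = 5,
                                 res_cutoff = 1.6) {
  nc <- crop$dims
  Y <- stats::fft(crop$values, inverse = TRUE)
  X <- stats::fft(patt_crop, inverse = TRUE)
  # reciprocal samples of the crop grid, fractional Miller units
  freq <- lapply(1:3, function(i) {
    j <- 0:(nc[i] - 1)
    jw <- ifelse(j > nc[i] / 2, j - nc[i], j)
    jw / (nc[i] * crop$step_cells[i])
  })
  hh <- as.matrix(expand.grid(freq[[1]], freq[[2]], freq[[3]]))
  if (is.null(crop$recip)) stop("crop must carry the reciprocal basis (crop$recip)")
  q <- hh %*% t(crop$recip)
  qn <- sqrt(rowSums(q^2))
  keep <- qn >= 2 * pi / exclusion & qn <= 2 * pi / res_cutoff
  if (sum(keep) < 6) stop("fewer than 6 usable reciprocal samples")
  B <- cbind(q[keep, 1]^2, q[keep, 2]^2, q[keep, 3]^2,
             2 * q[keep, 1] * q[keep, 2], 2 * q[keep, 1] * q[keep, 3],
             2 * q[keep, 2] * q[keep, 3])
  Xk <- as.vector(X)[keep]
  Yk <- as.vector(Y)[keep]
  A <- rbind(Re(Xk) * B, Im(Xk) * B)
  y <- c(Re(Yk), Im(Yk))
  sv <- svd(A, nu = 0, nv = 0)$d
  cond <- sv[1] / max(sv[6], .Machine$double.eps)
  fit <- qr.solve(A, y)
  V <- matrix(c(fit[1], fit[4], fit[5],
                fit[4], fit[2], fit[6],
                fit[5], fit[6], fit[3]), 3, 3)
  list(V = V, residual = sqrt(sum((y - A %*% fit)^2)), cond = cond,
       n_samples = sum(keep))
}

#' Model-free joint-ADP estimation for a set of lattice nodes
#'
#' Full DISCOBALL driver: computes the 3D-delta-PDF of the map, the
#' Patterson origin peak from the Bragg list (band-matched to the map), and
#' deconvolves each requested lattice-node peak.
#'
#' @param map an `lv_map` of diffuse intensities.
#' @param bragg Bragg intensity table (`h,k,l,I`).
#' @param nodes integer matrix of lattice nodes (rows); default all nodes in
#'   the delta-PDF field of view.
#' @param d spherical peak-mask radius (Angstroms, default 4).
#' @param exclusion low-resolution exclusion (Angstroms, default 5).
#' @param res_cutoff resolution truncation (Angstroms).
#' @param assume_variational passed to [compute_delta_pdf()].
#' @return data.frame of class `lv_jadp`: `n1,n2,n3`, `v11..v23`, `total`,
#'   `resid`, `cond`.
#' @export
discoball <- function(map, bragg, nodes = NULL, d = 4, exclusion = 5,
                      res_cutoff = 1.6, assume_variational = FALSE,
                      oversample_r = 2) {
  pdf <- compute_delta_pdf(map, res_cutoff, assume_variational, oversample_r)
  # band-match the Patterson to the delta-PDF: same resolution truncation
  # and the same Miller-index box, so the deconvolution ratio is unbiased;
  # the doubled grid extent zero-pads the Patterson to a matching fine grid
  inbox <- abs(bragg$h) <= map$hmax[1] & abs(bragg$k) <= map$hmax[2] &
    abs(bragg$l) <= map$hmax[3]
  patt <- patterson_map(bragg[inbox, , drop = FALSE], map$cell,
                        hmax = 2L * pmax(map$hmax, 2L),
                        res_cutoff = res_cutoff)
  if (is.null(nodes)) {
    rng <- lapply(1:3, function(i) {
      m <- map$subdiv[i] %/% 2
      (-m):m
    })
    nodes <- as.matrix(expand.grid(n1 = rng[[1]], n2 = rng[[2]],
                                   n3 = rng[[3]]))
  }
  nodes <- rbind_h(nodes)
  out <- list()
  for (r in seq_len(nrow(nodes))) {
    crop <- crop_peak(pdf, nodes[r, ], d)
    crop$recip <- map$cell$recip
    pc <- patterson_on_crop(patt, crop, d)
    dec <- deconvolve_joint_adp(crop, pc, exclusion, res_cutoff)
    out[[r]] <- data.frame(n1 = nodes[r, 1], n2 = nodes[r, 2],
                           n3 = nodes[r, 3],
                           v11 = dec$V[1, 1], v22 = dec$V[2, 2],
                           v33 = dec$V[3, 3], v12 = dec$V[1, 2],
                           v13 = dec$V[1, 3], v23 = dec$V[2, 3],
                           total = sum(diag(dec$V)), resid = dec$residual,
                           cond = dec$cond)
  }
  out <- do.call(rbind, out)
  class(out) <- c("lv_jadp", "data.frame")
  out
}

#' Effective joint-ADP of a symmetric model
#'
#' Averages the per-group diagonal joint-ADPs over the K rigid groups for
#' each cell offset, giving the single effective covariance comparable with
#' the model-free deconvolution.
#'
#' @param jadps an `lv_jadp` table from [com_joint_adps()] (with `ki`,
#'   `kj`).
#' @return data.frame with one row per offset: `n1,n2,n3`, `v11..v23`,
#'   `total`.
#' @export
effective_joint_adp <- function(jadps) {
  diagonal <- jadps[jadps$ki == jadps$kj, , drop = FALSE]
  key <- paste(diagonal$n1, diagonal$n2, diagonal$n3, sep = ",")
  cols <- c("v11", "v22", "v33", "v12", "v13", "v23")
  out <- do.call(rbind, lapply(unique(key), function(k) {
    sub <- diagonal[key == k, , drop = FALSE]
    v <- colMeans(sub[cols])
    data.frame(n1 = sub$n1[1], n2 = sub$n2[1], n3 = sub$n3[1],
               v11 = v[1], v22 = v[2], v33 = v[3], v12 = v[4], v13 = v[5],
               v23 = v[6], total = v[1] + v[2] + v[3])
  }))
  rownames(out) <- NULL
  out
}

#' Split a joint-ADP into total and anisotropic parts
#'
#' @param V 3x3 symmetric matrix.
#' @return list with `total` (trace) and `aniso` (traceless residual
#'   `V - I * total / 3`).
#' @export
split_adp <- function(V) {
  tot <- sum(diag(V))
  list(total = tot, aniso = V - diag(3) * tot / 3)
}

#' Compare two sets of joint-ADPs
#'
#' Pairs joint-ADPs by cell offset; fits an affine line (intercept allowed)
#' to the total covariances and reports the Pearson correlation of the
#' totals and of the pooled anisotropic components.
#'
#' @param est,ref data.frames with columns `n1,n2,n3`, `v11..v23` (e.g.
#'   [discoball()] output and [effective_joint_adp()] of a model).
#' @return list with `slope`, `intercept`, `r_total`, `r_aniso`, `n_pairs`.
#' @export
validate_model <- function(est, ref) {
  keyA <- paste(est$n1, est$n2, est$n3, sep = ",")
  keyB <- paste(ref$n1, ref$n2, ref$n3, sep = ",")
  common <- intersect(keyA, keyB)
  if (length(common) < 2) stop("fewer than 2 matching offsets")
  ia <- match(common, keyA); ib <- match(common, keyB)
  cols <- c("v11", "v22", "v33", "v12", "v13", "v23")
  totA <- rowSums(est[ia, c("v11", "v22", "v33")])
  totB <- rowSums(ref[ib, c("v11", "v22", "v33")])
  fit <- stats::lm(totA ~ totB)
  anA <- anB <- NULL
  for (i in seq_along(common)) {
    sa <- split_adp(vec_to_sym(as.numeric(est[ia[i], cols])))
    sb <- split_adp(vec_to_sym(as.numeric(ref[ib[i], cols])))
    anA <- c(anA, sym_to_vec(sa$aniso))
    anB <- c(anB, sym_to_vec(sb$aniso))
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_total = if (stats::sd(totA) > 0 && stats::sd(totB) > 0)
         stats::cor(totA, totB) else NA_real_,
       r_aniso = if (stats::sd(anA) > 0 && stats::sd(anB) > 0)
         stats::cor(anA, anB) else NA_real_,
       n_pairs = length(common))
}
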