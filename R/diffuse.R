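# One-phonon diffuse scattering: rigid-group electron densities, oversampled
# molecular transforms, one-phonon structure factors, and halo intensities.
#
# Fourier convention throughout: F(q) = integral rho(r) exp(+i q.r) dr, with
# q in 1/A including the factor 2*pi (q = recip %*% h for fractional Miller
# index h).

#' Real-space electron density of the unit cell
#'
#' Synthetic path: Gaussian pseudo-atoms (amplitude Z, width `sigma` per
#' atom) summed on a fractional grid over the unit cell with periodic
#' wrapping. Optionally the mean density of the bulk-solvent region (voxels
#' farther than `solvent_radius` from any atom) is subtracted from the whole
#' map; by Babinet's principle this leaves all intensities unchanged except
#' at q = 0.
#'
#' @param crystal an `lv_crystal`.
#' @param spacing target grid spacing in Angstroms.
#' @param subtract_solvent logical.
#' @param solvent_radius bulk-solvent distance threshold (Angstroms).
#' @return object of class `lv_density`: `rho` (3D array), `cell`, `dims`.
#' @export
density_from_model <- function(crystal, spacing = 0.5,
                               subtract_solvent = TRUE, solvent_radius = 3) {
  cell <- crystal$cell
  edges <- c(cell$a, cell$b, cell$c)
  dims <- pmax(8L, as.integer(ceiling(edges / spacing)))
  rho <- array(0, dims)
  steps <- edges / dims # approximate Cartesian step per axis
  dmin <- array(Inf, dims)
  ax <- lapply(1:3, function(i) (seq_len(dims[i]) - 1) / dims[i])
  for (g in crystal$groups) {
    xyz <- as.matrix(g$atoms[, c("x", "y", "z")])
    zs <- g$atoms$occ * element_property(g$atoms$element, "z")
    sig <- if (!is.null(g$atoms$sigma)) g$atoms$sigma else rep(0.9, nrow(xyz))
    for (j in seq_len(nrow(xyz))) {
      fr <- as.numeric(cell$frac %*% xyz[j, ])
      half <- pmin(dims %/% 2, ceiling(4 * sig[j] / steps))
      ctr <- round(fr * dims)
      ii <- lapply(1:3, function(i) (ctr[i] - half[i]):(ctr[i] + half[i]))
      gf <- as.matrix(expand.grid(a = ii[[1]], b = ii[[2]], cc = ii[[3]]))
      tfr <- sweep(gf, 2, dims, "/")
      dx <- cell$ortho %*% (t(tfr) - fr)
      r2 <- colSums(dx^2)
      amp <- zs[j] / ((2 * pi)^1.5 * sig[j]^3) * exp(-r2 / (2 * sig[j]^2))
      iw <- cbind(((gf[, 1]) %% dims[1]) + 1, ((gf[, 2]) %% dims[2]) + 1,
                  ((gf[, 3]) %% dims[3]) + 1)
      lin <- iw[, 1] + dims[1] * (iw[, 2] - 1) + dims[1] * dims[2] * (iw[, 3] - 1)
      rho[lin] <- rho[lin] + amp
      dmin[lin] <- pmin(dmin[lin], sqrt(r2))
    }
  }
  if (subtract_solvent) {
    solv <- dmin > solvent_radius
    if (any(solv)) rho <- rho - mean(rho[solv])
  }
  structure(list(rho = rho, cell = cell, dims = dims), class = "lv_density")
}

#' Unit-cell density by Fourier synthesis from structure-factor amplitudes
#'
#' Experimental-path analogue of [density_from_model()]: given a list of
#' Bragg reflections with amplitudes and phases (e.g. measured |F| with
#' model phases), synthesizes `rho(r) = (1/V) sum_h F_h exp(-i q_h . r)` on
#' a fractional grid. Friedel mates are generated automatically.
#'
#' @param cell an [unit_cell()].
#' @param fobs data.frame with columns `h`, `k`, `l`, `f` (amplitude,
#'   electrons) and `phi` (phase, degrees).
#' @param dims grid dimensions (length 3).
#' @return an `lv_density`.
#' @export
density_from_amplitudes <- function(cell, fobs, dims = c(32, 32, 32)) {
  dims <- as.integer(rep_len(dims, 3))
  Fc <- array(0 + 0i, dims)
  put <- function(h, val) {
    i <- ((h %% dims) + dims) %% dims + 1
    Fc[i[1], i[2], i[3]] <<- val
  }
  for (r in seq_len(nrow(fobs))) {
    h <- c(fobs$h[r], fobs$k[r], fobs$l[r])
    v <- fobs$f[r] * exp(1i * fobs$phi[r] * pi / 180)
    put(h, v)
    put(-h, Conj(v))
  }
  # rho(t) = (1/V) sum_h F_h exp(-2 pi i h.t): forward fft convention
  rho <- Re(stats::fft(Fc)) / cell$volume
  structure(list(rho = rho, cell = cell, dims = dims), class = "lv_density")
}

#' Partition the unit-cell density into rigid-group densities
#'
#' Builds hard nearest-group masks (1 inside the region closest to a group's
#' atoms, 0 outside), blurs them with a Gaussian of B-factor `blur_B` to
#' produce soft masks (which still sum to 1 everywhere), and multiplies each
#' soft mask into the cell density.
#'
#' @param dens an `lv_density` for the unit cell.
#' @param crystal the `lv_crystal` defining the groups.
#' @param blur_B Gaussian blur B-factor in A^2 (0 keeps the hard masks).
#' @return list of `lv_group_density` objects, one per group: fields `rho`
#'   (array on the cell grid), `origin` (group origin, Angstroms), `cell`,
#'   `dims`.
#' @export
partition_density <- function(dens, crystal, blur_B = 50) {
  cell <- dens$cell
  dims <- dens$dims
  ax <- lapply(1:3, function(i) (seq_len(dims[i]) - 1) / dims[i])
  tfr <- as.matrix(expand.grid(a = ax[[1]], b = ax[[2]], cc = ax[[3]]))
  nvox <- nrow(tfr)
  dmin <- matrix(Inf, nvox, crystal$K)
  for (g in seq_len(crystal$K)) {
    xyz <- as.matrix(crystal$groups[[g]]$atoms[, c("x", "y", "z")])
    xf <- t(cell$frac %*% t(xyz))
    for (j in seq_len(nrow(xf))) {
      d <- tfr - matrix(xf[j, ], nvox, 3, byrow = TRUE)
      d <- d - round(d) # periodic minimum image in fractional space
      dx <- cell$ortho %*% t(d)
      dmin[, g] <- pmin(dmin[, g], colSums(dx^2))
    }
  }
  nearest <- max.col(-dmin, ties.method = "first")
  out <- vector("list", crystal$K)
  qgrid <- NULL
  if (blur_B > 0) {
    hfreq <- lapply(1:3, function(i) {
      j <- 0:(dims[i] - 1)
      ifelse(j > dims[i] / 2, j - dims[i], j) * dims[i] / dims[i]
    })
    hh <- as.matrix(expand.grid(hfreq[[1]], hfreq[[2]], hfreq[[3]]))
    q <- cell$recip %*% t(hh)
    qgrid <- array(colSums(q^2), dims)
  }
  for (g in seq_len(crystal$K)) {
    hard <- array(as.numeric(nearest == g), dims)
    soft <- if (blur_B > 0) {
      ker <- exp(-blur_B * qgrid / (16 * pi^2))
      Re(stats::fft(stats::fft(hard) * ker, inverse = TRUE)) / prod(dims)
    } else hard
    out[[g]] <- structure(list(rho = soft * dens$rho,
                               origin = crystal$groups[[g]]$origin,
                               cell = cell, dims = dims),
                          class = "lv_group_density")
  }
  out
}

#' Oversampled molecular transform of a rigid-group density
#'
#' Shifts the group density to the array origin, crops to its bounding box,
#' zero-pads to `oversample` times the maximum dimension, and FFTs. The
#' result can be evaluated at arbitrary q by tricubic interpolation of the
#' real and imaginary parts, with a phase factor undoing the origin shift.
#' Transforms of the three coordinate-weighted densities `(r - o) rho` are
#' prepared alongside for the rotational part of the one-phonon structure
#' factor.
#'
#' @param gd an `lv_group_density` from [partition_density()].
#' @param oversample padding factor (default 4).
#' @param mask_tol densities below `mask_tol * max` define the bounding box.
#' @return object of class `lv_moltrans` with functions `eval(q)` (complex
#'   molecular transform) and `eval_vec(q)` (n x 3 complex matrix of the
#'   coordinate-weighted transforms).
#' @export
molecular_transform <- function(gd, oversample = 4, mask_tol = 1e-6) {
  cell <- gd$cell
  dims <- gd$dims
  ofr <- as.numeric(cell$frac %*% gd$origin)
  # circularly shift so the voxel containing the group origin sits at the
  # array center, making the subsequent crop wrap-free
  oc <- round(ofr * dims)
  ctr <- dims %/% 2 + 1L
  sh <- lapply(1:3, function(i)
    (((seq_len(dims[i]) - 1 + (oc[i] - ctr[i] + 1)) %% dims[i]) + 1))
  rho <- gd$rho[sh[[1]], sh[[2]], sh[[3]]]
  # bounding box of significant density around the center
  amax <- max(abs(rho))
  keep <- which(abs(rho) > mask_tol * amax, arr.ind = TRUE)
  half <- pmax(2L, apply(abs(sweep(keep, 2, ctr)), 2, max))
  half <- pmin(half, ctr - 1L, dims - ctr)
  box <- lapply(1:3, function(i) (ctr[i] - half[i]):(ctr[i] + half[i]))
  sub <- rho[box[[1]], box[[2]], box[[3]]]
  nb <- dim(sub)
  np <- oversample * max(nb)
  np <- as.integer(rep(np, 3))
  # fractional coordinates of the sub-box voxels relative to the origin voxel
  r0_idx <- -(half) # first voxel of the box relative to the origin voxel
  step_frac <- 1 / dims
  # place the box into the padded array with the origin voxel at index 1
  # (cyclic): the transform is then smooth and interpolable
  dst <- lapply(1:3, function(i) ((0:(nb[i] - 1) + r0_idx[i]) %% np[i]) + 1)
  pad <- array(0, np)
  pad[dst[[1]], dst[[2]], dst[[3]]] <- sub
  dv <- cell$volume / prod(dims)
  Fgrid <- stats::fft(pad, inverse = TRUE) * dv
  # coordinate-weighted grids (r - o) rho in the same box frame
  bi <- lapply(1:3, function(i) (r0_idx[i] + 0:(nb[i] - 1)) * step_frac[i])
  bf <- as.matrix(expand.grid(bi[[1]], bi[[2]], bi[[3]]))
  rel <- t(cell$ortho %*% t(bf)) # Cartesian, relative to origin *voxel*
  dvox <- as.numeric(cell$ortho %*% ((oc / dims) - ofr)) # voxel - true origin
  rel <- sweep(rel, 2, -dvox) # relative to the true group origin
  Fvec <- vector("list", 3)
  for (m in 1:3) {
    w <- array(0, np)
    w[dst[[1]], dst[[2]], dst[[3]]] <- sub * array(rel[, m], nb)
    Fvec[[m]] <- stats::fft(w, inverse = TRUE) * dv
  }
  origin_voxel_cart <- as.numeric(cell$ortho %*% (oc / dims))
  freq_step <- 1 / (np * step_frac) # reciprocal fractional units per DFT bin
  nyq <- freq_step * np / 2
  to_index <- function(q) {
    q <- rbind_h(q)
    hf <- t(t(cell$ortho) %*% t(q)) / (2 * pi) # fractional Miller of q
    if (any(abs(hf) > matrix(nyq, nrow(hf), 3, byrow = TRUE) + 1e-9))
      stop("requested q beyond the transform grid Nyquist limit")
    list(idx = sweep(hf, 2, freq_step, "/"), q = q)
  }
  evalF <- function(q) {
    # DFT phases are relative to the origin voxel; the phase factor restores
    # absolute coordinates, undoing the origin shift
    ti <- to_index(q)
    phase <- exp(1i * as.numeric(ti$q %*% origin_voxel_cart))
    interp_tricubic(Fgrid, ti$idx) * phase
  }
  evalVec <- function(q) {
    ti <- to_index(q)
    phase <- exp(1i * as.numeric(ti$q %*% origin_voxel_cart))
    sapply(1:3, function(m) interp_tricubic(Fvec[[m]], ti$idx) * phase)
  }
  structure(list(eval = evalF, eval_vec = evalVec,
                 origin = gd$origin, nyquist = nyq),
            class = "lv_moltrans")
}

#' One-phonon structure factors from molecular transforms
#'
#' Assembles, for each rigid group, the complex 6-vector
#' `G_k(q) = [ q F_k(q) ; -q x F{(r - o_k) rho_k}(q) ]` and concatenates
#' over groups.
#'
#' @param transforms list of `lv_moltrans`, one per group.
#' @param q n x 3 matrix of Cartesian scattering vectors (1/A).
#' @return n x (6 K) complex matrix.
#' @export
one_phonon_sf <- function(transforms, q) {
  q <- rbind_h(q)
  K <- length(transforms)
  G <- matrix(0 + 0i, nrow(q), 6 * K)
  for (g in seq_len(K)) {
    Fq <- transforms[[g]]$eval(q)
    M <- transforms[[g]]$eval_vec(q)
    cr <- cbind(q[, 2] * M[, 3] - q[, 3] * M[, 2],
                q[, 3] * M[, 1] - q[, 1] * M[, 3],
                q[, 1] * M[, 2] - q[, 2] * M[, 1])
    G[, (6 * g - 5):(6 * g)] <- cbind(q * Fq, -cr)
  }
  G
}

#' One-phonon structure factors by direct atomic summation
#'
#' Analytic route for Gaussian (pseudo-)atoms: the group transform and its
#' coordinate-weighted companions are sums over atoms with Gaussian form
#' factors, so no density grid is needed. Exact up to the form-factor model;
#' used as the default in simulations and as the oracle for the grid route.
#'
#' @param crystal an `lv_crystal` whose atoms carry a `sigma` column
#'   (Gaussian width, Angstroms).
#' @param q n x 3 matrix of Cartesian scattering vectors (1/A).
#' @param dof 6 or 3 (translational-only bodies).
#' @return n x (dof K) complex matrix.
#' @export
one_phonon_sf_atoms <- function(crystal, q, dof = 6) {
  q <- rbind_h(q)
  nq <- nrow(q)
  qn2 <- rowSums(q^2)
  G <- matrix(0 + 0i, nq, dof * crystal$K)
  for (g in seq_len(crystal$K)) {
    gr <- crystal$groups[[g]]
    xyz <- as.matrix(gr$atoms[, c("x", "y", "z")])
    rel <- sweep(xyz, 2, gr$origin)
    zs <- gr$atoms$occ * element_property(gr$atoms$element, "z")
    sig <- if (!is.null(gr$atoms$sigma)) gr$atoms$sigma else rep(0.9, nrow(xyz))
    ff <- exp(-outer(qn2, sig^2) / 2) * matrix(zs, nq, length(zs), byrow = TRUE)
    ph <- exp(1i * (q %*% t(xyz)))
    fph <- ff * ph
    Fq <- rowSums(fph)
    if (dof == 3) {
      G[, (3 * g - 2):(3 * g)] <- q * Fq
    } else {
      M <- fph %*% rel # i sigma^2 q term drops out of the cross product
      cr <- cbind(q[, 2] * M[, 3] - q[, 3] * M[, 2],
                  q[, 3] * M[, 1] - q[, 1] * M[, 3],
                  q[, 1] * M[, 2] - q[, 2] * M[, 1])
      G[, (6 * g - 5):(6 * g)] <- cbind(q * Fq, -cr)
    }
  }
  G
}

# decompose fractional Miller indices into the nearest reciprocal-lattice
# point g and the wavevector k = g - h, validating that k lies on the
# supercell grid
halo_decompose <- function(h, supercell, tol = 1e-8) {
  h <- rbind_h(h)
  g <- round(h)
  k <- g - h
  kn <- sweep(k, 2, supercell, "*")
  if (max(abs(kn - round(kn))) > tol)
    stop("wavevector not on the supercell grid; one-phonon scattering is defined only at satellite points")
  list(g = g, k = k)
}

#' One-phonon diffuse intensity at fractional Miller indices
#'
#' Evaluates `I(q = g_h - k) = kBT G(q) (L^-T D+(k) L^-1) G^dagger(q)` for
#' every supplied voxel position. `h` must decompose into an integer Miller
#' index and a wavevector on the supercell grid.
#'
#' @param model an `lv_enm`.
#' @param h n x 3 fractional Miller indices.
#' @param supercell supercell dimensions defining the allowed wavevectors.
#' @param kBT temperature scale.
#' @param sf structure-factor route: `"atoms"` (analytic Gaussian-atom sums)
#'   or a list of `lv_moltrans` objects (grid route).
#' @return numeric intensity vector (electron units per unit cell).
#' @export
one_phonon_intensity <- function(model, h, supercell = c(8, 8, 8), kBT = 1,
                                 sf = "atoms") {
  h <- rbind_h(h)
  hd <- halo_decompose(h, supercell)
  q <- q_cartesian(model$crystal$cell, h)
  G <- if (identical(sf, "atoms"))
    one_phonon_sf_atoms(model$crystal, q, model$dof)
  else one_phonon_sf(sf, q)
  I <- numeric(nrow(h))
  kkey <- apply(round(sweep(hd$k, 2, supercell, "*")), 1, paste, collapse = ",")
  for (key in unique(kkey)) {
    rows <- which(kkey == key)
    Ck <- covariance_kernel(model, hd$k[rows[1], ])
    Gr <- G[rows, , drop = FALSE]
    I[rows] <- kBT * Re(rowSums((Gr %*% Ck) * Conj(Gr)))
  }
  I
}

#' Simulate a one-phonon diffuse halo map
#'
#' Evaluates the one-phonon intensity at every voxel of a subdivided
#' Miller-index grid; the supercell equals the grid subdivision so that
#' every voxel is an allowed satellite point. Voxels at integer h (k = 0)
#' use the pseudo-inverse convention (rigid supercell translations
#' removed).
#'
#' @param model an `lv_enm`.
#' @param subdiv,hmax grid specification (see [voxel_map()]).
#' @param kBT temperature scale.
#' @param sf structure-factor route (see [one_phonon_intensity()]).
#' @return an `lv_map` with simulated intensities (sigma 0, all measured).
#' @export
simulate_halo_map <- function(model, subdiv = 3, hmax = 4, kBT = 1,
                              sf = "atoms") {
  map <- voxel_map(model$crystal$cell, subdiv, hmax)
  h <- map_hgrid(map)
  I <- one_phonon_intensity(model, h, supercell = map$subdiv, kBT = kBT,
                            sf = sf)
  map$I <- array(I, map$dims)
  map$sigma <- array(0, map$dims)
  map$measured <- array(TRUE, map$dims)
  map
}
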