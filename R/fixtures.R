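# Synthetic fixtures: deterministic toy crystals with known spring
# networks, brute-force supercell covariance and Monte-Carlo scattering
# oracles, and noisy-map generation. These make every stage of the
# workflow testable without external data.

#' Specification of a toy crystal
#'
#' @param spacegroup `"P1"` (triclinic-like, one body) or `"P212121"`
#'   (orthorhombic, four symmetry-related bodies).
#' @param natoms pseudo-atoms per rigid body (>= 5 for a well-conditioned
#'   inertia tensor).
#' @param radius body radius in Angstroms.
#' @param jitter coordinate jitter (Angstroms) applied to the ideal vertex
#'   positions; makes the geometry generic.
#' @param cutoff contact-search cutoff (Angstroms).
#' @param gamma_g,gamma_p true spring constants (kBT/A^2); recycled over
#'   interface classes so distinct interfaces get distinct constants.
#' @param sigma_atom Gaussian form-factor width of the pseudo-atoms
#'   (Angstroms).
#' @param seed RNG seed; the seed fully determines the fixture.
#' @return a list of class `lv_toyspec`.
#' @export
toy_crystal_spec <- function(spacegroup = c("P1", "P212121"), natoms = 9,
                             radius = 5.0, jitter = 0.25, cutoff = 6.2,
                             gamma_g = c(2, 2.8, 3.6, 4.4, 5.2, 6, 6.8,
                                         7.6, 8.4, 9.2, 10, 10.8),
                             gamma_p = 0,
                             sigma_atom = 0.8, seed = 1) {
  spacegroup <- match.arg(spacegroup)
  structure(list(spacegroup = spacegroup, natoms = natoms, radius = radius,
                 jitter = jitter, cutoff = cutoff, gamma_g = gamma_g,
                 gamma_p = gamma_p, sigma_atom = sigma_atom, seed = seed),
            class = "lv_toyspec")
}

#' Build a toy crystal with a known spring network
#'
#' Generates a deterministic rigid-body crystal (pseudo-atoms with Gaussian
#' form factors), finds contacts, groups springs by interface class and
#' assigns the true spring constants from the spec.
#'
#' @param spec a [toy_crystal_spec()].
#' @return list with `crystal`, `contacts`, `ids` (interface class per
#'   contact), `params` (truth `lv_springs`), `spec`, `cell`.
#' @export
make_toy_crystal <- function(spec = toy_crystal_spec()) {
  set.seed(spec$seed)
  cell <- if (spec$spacegroup == "P1") {
    unit_cell(13, 13.5, 14, 88, 92, 95, spacegroup = "P1")
  } else {
    unit_cell(17, 19, 21, 90, 90, 90, spacegroup = "P212121")
  }
  # body: center plus near-axis vertices, jittered
  dirs <- rbind(c(0, 0, 0),
                c(1, 0, 0), c(-1, 0, 0),
                c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1),
                c(1, 1, 1) / sqrt(3), c(-1, 1, -1) / sqrt(3))
  n <- min(spec$natoms, nrow(dirs))
  xyz <- dirs[seq_len(n), , drop = FALSE] * spec$radius +
    matrix(stats::rnorm(3 * n, sd = spec$jitter), n, 3)
  com_frac <- if (spec$spacegroup == "P1") c(0.5, 0.5, 0.5) else
    c(0.13, 0.10, 0.12)
  com <- as.numeric(cell$ortho %*% com_frac)
  xyz <- sweep(xyz, 2, com - colMeans(xyz), "+")
  asu <- data.frame(element = "X", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    occ = 1, b = 0, resid = seq_len(n), chain = "A",
                    sigma = spec$sigma_atom)
  crystal <- expand_to_unit_cell(asu, cell)
  contacts <- find_contacts(crystal, cutoff = spec$cutoff)
  if (nrow(contacts) == 0) stop("toy crystal has no contacts; increase cutoff")
  ids <- group_springs(contacts, crystal, level = "interface")
  params <- spring_parameter_set(ids, gamma_g = spec$gamma_g,
                                 gamma_p = spec$gamma_p, level = "interface")
  list(crystal = crystal, contacts = contacts, ids = ids, params = params,
       spec = spec, cell = cell)
}

# index helper for the full-supercell generalized coordinate vector:
# cells enumerated in the same order as expand.grid over (0:N1-1, ...)
supercell_index <- function(nc, K, dof) {
  N <- prod(nc)
  cells <- as.matrix(expand.grid(c1 = 0:(nc[1] - 1), c2 = 0:(nc[2] - 1),
                                 c3 = 0:(nc[3] - 1)))
  cell_id <- function(cvec) {
    cw <- ((cvec %% nc) + nc) %% nc
    1L + cw[1] + nc[1] * (cw[2] + nc[2] * cw[3])
  }
  idx <- function(g, l) (((l - 1L) * K + (g - 1L)) * dof + 1L):(((l - 1L) * K + g) * dof)
  list(N = N, cells = cells, cell_id = cell_id, idx = idx)
}

# assemble the full generalized supercell Hessian (real, size dof*K*N)
supercell_hessian <- function(model, nc) {
  K <- model$K; dof <- model$dof
  si <- supercell_index(nc, K, dof)
  dN <- dof * K * si$N
  H <- matrix(0, dN, dN)
  for (l in seq_len(si$N)) {
    cvec <- as.integer(si$cells[l, ])
    for (tm in model$terms) {
      gg <- model$params$gamma_g[tm$pid]
      gp <- model$params$gamma_p[tm$pid]
      Kaa <- gg * tm$Gaa + gp * tm$Paa
      Kbb <- gg * tm$Gbb + gp * tm$Pbb
      Kab <- gg * tm$Gab + gp * tm$Pab
      lp <- si$cell_id(cvec + tm$n)
      ia <- si$idx(tm$gi, l); ib <- si$idx(tm$gj, lp)
      H[ia, ia] <- H[ia, ia] + Kaa
      H[ib, ib] <- H[ib, ib] + Kbb
      H[ia, ib] <- H[ia, ib] - Kab
      H[ib, ia] <- H[ib, ia] - t(Kab)
    }
  }
  (H + t(H)) / 2
}

# mass-reduced eigendecomposition of the supercell Hessian; returns the
# pieces shared by the brute-force covariance and the MC sampler
supercell_modes <- function(model, nc, zero_tol = 1e-8) {
  K <- model$K; dof <- model$dof
  si <- supercell_index(nc, K, dof)
  H <- supercell_hessian(model, nc)
  Linv1 <- blockdiag(model$mass$Linv)
  Linv <- blockdiag(rep(list(Linv1), si$N))
  D <- Linv %*% H %*% t(Linv)
  D <- (D + t(D)) / 2
  e <- eigen(D, symmetric = TRUE)
  vmax <- max(abs(e$values))
  zero <- abs(e$values) < zero_tol * vmax
  if (sum(zero) != 3)
    stop(sprintf("supercell Hessian has %d zero modes; expected 3 (rigid translations)",
                 sum(zero)))
  if (any(e$values < -zero_tol * vmax))
    stop("unstable toy network: negative supercell eigenvalue")
  list(si = si, e = e, zero = zero, Linv = Linv)
}

#' Brute-force supercell covariance (oracle)
#'
#' Assembles the full generalized Hessian of the N1 x N2 x N3 supercell,
#' mass-reduces it, projects out the three rigid-translation modes via the
#' pseudo-inverse, and scales by kBT. Independent of the per-wavevector
#' Born/Von-Karman path; used to validate [vcov_supercell()].
#'
#' @param model an `lv_enm`.
#' @param supercell integer N1, N2, N3.
#' @param kBT temperature scale.
#' @return an `lv_vcov` with the same layout as [vcov_supercell()].
#' @export
brute_force_vcov <- function(model, supercell = c(2, 2, 1), kBT = 1) {
  nc <- as.integer(supercell)
  sm <- supercell_modes(model, nc)
  inv <- ifelse(sm$zero, 0, 1 / sm$e$values)
  Cov <- t(sm$Linv) %*% (sm$e$vectors %*% (inv * t(sm$e$vectors))) %*% sm$Linv
  Cov <- kBT * (Cov + t(Cov)) / 2
  d <- model$dof * model$K
  blocks <- array(0, c(d, d, nc[1], nc[2], nc[3]))
  for (c1 in 0:(nc[1] - 1)) for (c2 in 0:(nc[2] - 1)) for (c3 in 0:(nc[3] - 1)) {
    l <- sm$si$cell_id(c(c1, c2, c3))
    rows <- ((l - 1) * d + 1):(l * d)
    cols <- 1:d # cell (0,0,0) is the first cell in the enumeration
    blocks[, , c1 + 1, c2 + 1, c3 + 1] <- Cov[rows, cols]
  }
  structure(list(blocks = blocks, supercell = nc, kBT = kBT, K = model$K,
                 dof = model$dof),
            class = "lv_vcov")
}

#' Monte-Carlo harmonic-ensemble diffuse scattering (oracle)
#'
#' Samples generalized displacements from the supercell normal modes
#' (variance kBT/omega^2 per mode, rigid translations excluded), displaces
#' every atom, accumulates structure factors over the whole supercell, and
#' returns the variance of the structure factor per unit cell, divided by
#' the squared amplitude scale. Converges to the one-phonon intensity as the
#' amplitude scale tends to zero.
#'
#' @param model an `lv_enm`.
#' @param supercell integer N1, N2, N3; the q points must be satellite
#'   points of this supercell.
#' @param q matrix (n x 3) of Cartesian scattering vectors (1/A).
#' @param n_samples number of Monte-Carlo samples.
#' @param amplitude_scale factor multiplying the sampled displacements
#'   (intensities are divided by its square).
#' @param kBT temperature scale.
#' @param seed RNG seed.
#' @return numeric vector of intensities (electron units per unit cell).
#' @export
mc_sample_diffuse <- function(model, supercell, q, n_samples = 200,
                              amplitude_scale = 0.1, kBT = 1, seed = 1) {
  set.seed(seed)
  nc <- as.integer(supercell)
  q <- rbind_h(q)
  if (amplitude_scale == 0) return(numeric(nrow(q))) # no motion, no diffuse
  sm <- supercell_modes(model, nc)
  crystal <- model$crystal
  sdvec <- ifelse(sm$zero, 0, sqrt(kBT / pmax(sm$e$values, .Machine$double.eps)))
  Wmap <- t(sm$Linv) %*% sm$e$vectors # maps mode amplitudes to w
  # static atomic data over the supercell
  at <- list()
  for (l in seq_len(sm$si$N)) {
    Rl <- as.numeric(crystal$cell$ortho %*% as.numeric(sm$si$cells[l, ]))
    for (g in seq_len(crystal$K)) {
      gr <- crystal$groups[[g]]
      xyz <- as.matrix(gr$atoms[, c("x", "y", "z")])
      at[[length(at) + 1L]] <- list(
        l = l, g = g, xyz = sweep(xyz, 2, Rl, "+"),
        rel = sweep(xyz, 2, gr$origin),
        f0 = gr$atoms$occ * element_property(gr$atoms$element, "z"),
        sigma = if (!is.null(gr$atoms$sigma)) gr$atoms$sigma else
          rep(0.8, nrow(xyz)))
    }
  }
  nq <- nrow(q)
  qn2 <- rowSums(q^2)
  Fsum <- complex(nq); F2sum <- numeric(nq)
  dof <- model$dof
  for (s in seq_len(n_samples)) {
    zmode <- stats::rnorm(length(sdvec)) * sdvec
    w <- as.numeric(Wmap %*% zmode)
    Fq <- complex(nq)
    for (a in at) {
      iw <- (((a$l - 1) * crystal$K + (a$g - 1)) * dof + 1):(((a$l - 1) * crystal$K + a$g) * dof)
      wg <- w[iw]
      if (dof == 6) {
        u <- matrix(wg[1:3], nrow(a$rel), 3, byrow = TRUE) +
          cbind(wg[5] * a$rel[, 3] - wg[6] * a$rel[, 2],
                wg[6] * a$rel[, 1] - wg[4] * a$rel[, 3],
                wg[4] * a$rel[, 2] - wg[5] * a$rel[, 1])
      } else {
        u <- matrix(wg, nrow(a$rel), 3, byrow = TRUE)
      }
      pos <- a$xyz + amplitude_scale * u
      ff <- outer(qn2, a$sigma^2, function(qq, ss) exp(-ss * qq / 2)) *
        matrix(a$f0, nq, length(a$f0), byrow = TRUE)
      ph <- exp(1i * (q %*% t(pos)))
      Fq <- Fq + rowSums(ff * ph)
    }
    Fsum <- Fsum + Fq
    F2sum <- F2sum + Mod(Fq)^2
  }
  Fbar <- Fsum / n_samples
  (F2sum / n_samples - Mod(Fbar)^2) / (sm$si$N * amplitude_scale^2)
}

#' Add Gaussian noise to a voxel map
#'
#' Per-voxel sigma is `sigma0 + frac * |I|`; the sigma used is recorded in
#' the map.
#'
#' @param map an `lv_map`.
#' @param sigma0 constant noise level (electron units).
#' @param frac intensity-proportional noise fraction.
#' @param seed RNG seed.
#' @return the noisy `lv_map`.
#' @export
make_noisy_map <- function(map, sigma0 = 0, frac = 0, seed = 1) {
  set.seed(seed)
  sig <- sigma0 + frac * abs(map$I)
  noisy <- map$I + array(stats::rnorm(length(map$I)), dim(map$I)) * sig
  map$I <- noisy
  map$sigma <- sig
  map
}
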