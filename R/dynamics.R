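# Born/Von-Karman lattice dynamics for the rigid-body elastic network:
# generalized-coordinate projection, mass factors, dynamical matrices,
# supercell covariances, TLS matrices and atomic displacement parameters.

#' Projection from generalized rigid-body coordinates to Cartesian
#'
#' For a point at position `x` relative to the group origin, returns the
#' linear operator mapping the six generalized coordinates (three
#' translations followed by three infinitesimal rotations) to the Cartesian
#' displacement: `u = t + omega x x` (cross product), i.e.
#' \preformatted{
#'   [ 1 0 0    0   x3  -x2 ]
#'   [ 0 1 0  -x3    0   x1 ]
#'   [ 0 0 1   x2  -x1    0 ]
#' }
#' With `dof = 3` only the translational identity block is returned (point
#' bodies).
#'
#' @param x 3-vector, Angstroms, position relative to the group origin.
#' @param dof 6 (rigid body) or 3 (point body).
#' @return 3 x dof matrix.
#' @export
projection_matrix <- function(x, dof = 6) {
  stopifnot(all(is.finite(x)), dof %in% c(3, 6))
  if (dof == 3) return(diag(3))
  cbind(diag(3), rbind(c(0, x[3], -x[2]),
                       c(-x[3], 0, x[1]),
                       c(x[2], -x[1], 0)))
}

#' Lower-triangular factor of the generalized mass matrix
#'
#' For each rigid group the 6x6 generalized mass matrix
#' `M = sum_j m_j A(x_j)^T A(x_j)` is assembled and factored as `M = L L^T`
#' with `L` lower triangular (Cholesky). Any factor with `L L^T = M` gives
#' identical observables; Cholesky is used as a convention. Block-diagonal
#' over groups.
#'
#' @param crystal an `lv_crystal`.
#' @param dof 6 or 3 (see [projection_matrix()]).
#' @return list with `L`, `Linv` (lists of per-group dof x dof matrices).
#' @export
mass_factor <- function(crystal, dof = 6) {
  L <- vector("list", crystal$K)
  Linv <- vector("list", crystal$K)
  for (k in seq_len(crystal$K)) {
    g <- crystal$groups[[k]]
    xyz <- sweep(as.matrix(g$atoms[, c("x", "y", "z")]), 2, g$origin)
    M <- matrix(0, dof, dof)
    for (j in seq_len(nrow(xyz))) {
      A <- projection_matrix(xyz[j, ], dof)
      M <- M + g$masses[j] * crossprod(A)
    }
    R <- tryCatch(chol(M), error = function(e)
      stop("singular generalized mass matrix for group ", k,
           " (collinear or degenerate body); perturb coordinates or use dof = 3"))
    L[[k]] <- t(R)
    Linv[[k]] <- solve(L[[k]])
  }
  list(L = L, Linv = Linv, dof = dof)
}

#' Build an elastic network model ready for lattice dynamics
#'
#' Precomputes, per contact aggregated by (group pair, cell offset,
#' parameter group), the generalized force-constant blocks for the Gaussian
#' and parallel spring components, so that the Fourier-transformed Hessian
#' for any parameter values is a cheap linear combination.
#'
#' @param crystal an `lv_crystal`.
#' @param contacts output of [find_contacts()].
#' @param params an `lv_springs` parameter table (see
#'   [spring_parameter_set()]).
#' @param ids parameter-group id per contact, as returned by
#'   [group_springs()] at the level matching `params`.
#' @param dof 6 (rigid bodies) or 3 (point bodies).
#' @param kBT energy scale; spring constants are in units of kBT/A^2, so
#'   only the product enters any observable.
#' @return object of class `lv_enm`.
#' @export
build_enm <- function(crystal, contacts, params, ids, dof = 6, kBT = 1) {
  stopifnot(nrow(contacts) > 0, length(ids) == nrow(contacts))
  mf <- mass_factor(crystal, dof)
  terms <- list()
  key_of <- paste(contacts$gi, contacts$gj, contacts$n1, contacts$n2,
                  contacts$n3, ids, sep = ",")
  for (key in unique(key_of)) {
    rows <- which(key_of == key)
    c1 <- contacts[rows[1], ]
    gi <- c1$gi; gj <- c1$gj
    n <- c(c1$n1, c1$n2, c1$n3)
    pid <- ids[rows[1]]
    zero <- matrix(0, dof, dof)
    Gaa <- zero; Gbb <- zero; Gab <- zero   # Gaussian component
    Paa <- zero; Pbb <- zero; Pab <- zero   # parallel component
    for (r in rows) {
      cc <- contacts[r, ]
      xa <- as.numeric(crystal$groups[[gi]]$atoms[cc$ai, c("x", "y", "z")]) -
        crystal$groups[[gi]]$origin
      xb <- as.numeric(crystal$groups[[gj]]$atoms[cc$aj, c("x", "y", "z")]) -
        crystal$groups[[gj]]$origin
      Aa <- projection_matrix(xa, dof)
      Ab <- projection_matrix(xb, dof)
      u <- c(cc$ux, cc$uy, cc$uz)
      Pu <- u %o% u
      Gaa <- Gaa + crossprod(Aa); Gbb <- Gbb + crossprod(Ab)
      Gab <- Gab + t(Aa) %*% Ab
      Paa <- Paa + t(Aa) %*% Pu %*% Aa; Pbb <- Pbb + t(Ab) %*% Pu %*% Ab
      Pab <- Pab + t(Aa) %*% Pu %*% Ab
    }
    terms[[length(terms) + 1L]] <- list(
      gi = gi, gj = gj, n = n, pid = pid,
      Gaa = Gaa, Gbb = Gbb, Gab = Gab, Paa = Paa, Pbb = Pbb, Pab = Pab)
  }
  structure(list(crystal = crystal, contacts = contacts, ids = ids,
                 params = params, terms = terms, mass = mf, dof = dof,
                 K = crystal$K, kBT = kBT),
            class = "lv_enm")
}

#' Replace the spring parameter values of a model
#'
#' @param model an `lv_enm`.
#' @param gamma_g,gamma_p vectors over parameter groups.
#' @return the updated model.
#' @export
set_params <- function(model, gamma_g, gamma_p = NULL) {
  np <- nrow(model$params)
  model$params$gamma_g <- rep_len(gamma_g, np)
  if (!is.null(gamma_p)) model$params$gamma_p <- rep_len(gamma_p, np)
  if (any(model$params$gamma_g < 0) || any(model$params$gamma_p < 0))
    stop("spring stiffness must be >= 0")
  model
}

# Fourier-transformed generalized Hessian Phi(k); k is fractional
# (reciprocal-lattice units); phase exp(2 pi i k . n) for the partner offset
hessian_fourier <- function(model, k) {
  d <- model$dof; K <- model$K
  Phi <- matrix(0 + 0i, d * K, d * K)
  idx <- function(g) ((g - 1) * d + 1):(g * d)
  for (tm in model$terms) {
    gg <- model$params$gamma_g[tm$pid]
    gp <- model$params$gamma_p[tm$pid]
    Kaa <- gg * tm$Gaa + gp * tm$Paa
    Kbb <- gg * tm$Gbb + gp * tm$Pbb
    Kab <- gg * tm$Gab + gp * tm$Pab
    ph <- exp(2i * pi * sum(k * tm$n))
    ia <- idx(tm$gi); ib <- idx(tm$gj)
    Phi[ia, ia] <- Phi[ia, ia] + Kaa
    Phi[ib, ib] <- Phi[ib, ib] + Kbb
    Phi[ia, ib] <- Phi[ia, ib] - Kab * ph
    Phi[ib, ia] <- Phi[ib, ia] - t(Kab) * Conj(ph)
  }
  Phi
}

#' Dynamical matrix at a wavevector
#'
#' Mass-reduced Fourier-transformed Hessian `D(k) = L^-1 Phi(k) L^-T`,
#' Hermitian. `k` is given in fractional reciprocal coordinates and is
#' wrapped into the first Brillouin zone.
#'
#' @param model an `lv_enm`.
#' @param k length-3 fractional wavevector.
#' @return list with `D` (Hermitian complex matrix), `values` (eigenvalues,
#'   decreasing), `vectors`, and `k` (wrapped).
#' @export
dynamical_matrix <- function(model, k) {
  k <- k - round(k) # wrap to first Brillouin zone
  Phi <- hessian_fourier(model, k)
  Linv <- blockdiag(model$mass$Linv)
  D <- Linv %*% Phi %*% t(Linv)
  D <- (D + Conj(t(D))) / 2
  e <- eigen(D, symmetric = TRUE)
  list(D = D, values = e$values, vectors = e$vectors, k = k)
}

blockdiag <- function(blocks) {
  d <- nrow(blocks[[1]]); K <- length(blocks)
  M <- matrix(0, d * K, d * K)
  for (g in seq_len(K)) {
    i <- ((g - 1) * d + 1):(g * d)
    M[i, i] <- blocks[[g]]
  }
  M
}

# pseudo-inverse of the dynamical matrix in the mass-weighted frame,
# returned already transformed to the covariance frame:
# C(k) = L^-T D+(k) L^-1.  At k = 0 exactly three numerically-zero modes
# (rigid supercell translations) must be present and are removed.
covariance_kernel <- function(model, k, zero_tol = 1e-8) {
  ed <- dynamical_matrix(model, k)
  vals <- ed$values
  vmax <- max(abs(vals))
  at_gamma <- all(abs(ed$k) < 1e-12)
  if (vmax == 0) {
    # a translation-only (dof = 3, K = 1) network has only acoustic modes
    # at the zone center: D(0) = 0 and the pseudo-inverse is zero
    if (at_gamma && length(vals) == 3) return(matrix(0, 3, 3))
    stop("dynamical matrix is identically zero (no springs?)")
  }
  zero <- abs(vals) < zero_tol * vmax
  if (at_gamma) {
    if (sum(zero) != 3)
      stop(sprintf("expected exactly 3 zero modes at k = 0, found %d (unstable or disconnected network)",
                   sum(zero)))
  } else {
    if (any(zero) || any(vals < -zero_tol * vmax))
      stop(sprintf("unstable network: non-positive eigenvalue at k = (%g, %g, %g), mode %d",
                   ed$k[1], ed$k[2], ed$k[3], which(zero | vals < 0)[1]))
  }
  inv <- ifelse(zero, 0, 1 / vals)
  Dp <- ed$vectors %*% (inv * Conj(t(ed$vectors)))
  Linv <- blockdiag(model$mass$Linv)
  t(Linv) %*% Dp %*% Linv
}

#' Generalized-coordinate covariance over a periodic supercell
#'
#' Solves the lattice-dynamics problem at the wavevectors allowed by an
#' N1 x N2 x N3 supercell (k = (n1/N1, n2/N2, n3/N3), fractional) and
#' accumulates the covariance of generalized coordinates
#' `<w_l w_l'^T> = N^-1 kBT sum_k exp(2 pi i k.(l - l')) L^-T D+(k) L^-1`,
#' indexed by the cell offset `n = l - l'`. The three zero-frequency modes at
#' k = 0 (rigid supercell translations) are removed via the pseudo-inverse.
#'
#' @param model an `lv_enm`.
#' @param supercell integer vector N1, N2, N3 (all >= 1).
#' @param kBT temperature scale (dimensionless; see [build_enm()]).
#' @return object of class `lv_vcov`: `blocks` is a real array of dimension
#'   `(dof*K, dof*K, N1, N2, N3)`; `blocks[, , i1, i2, i3]` is the covariance
#'   between a cell and the cell offset `(i1-1, i2-1, i3-1)` (periodic).
#' @export
vcov_supercell <- function(model, supercell = c(8, 8, 8), kBT = 1) {
  nc <- as.integer(supercell)
  stopifnot(length(nc) == 3, all(nc >= 1))
  d <- model$dof * model$K
  N <- prod(nc)
  kgrid <- as.matrix(expand.grid(n1 = 0:(nc[1] - 1), n2 = 0:(nc[2] - 1),
                                 n3 = 0:(nc[3] - 1)))
  kfrac <- sweep(kgrid, 2, nc, "/")
  Cks <- array(0 + 0i, c(d, d, N))
  for (i in seq_len(N)) {
    Cks[, , i] <- covariance_kernel(model, kfrac[i, ])
  }
  blocks <- array(0, c(d, d, nc[1], nc[2], nc[3]))
  for (j in seq_len(N)) {
    n <- kgrid[j, ]
    ph <- exp(2i * pi * as.numeric(kfrac %*% n))
    B <- matrix(0 + 0i, d, d)
    for (i in seq_len(N)) B <- B + ph[i] * Cks[, , i]
    B <- B * (kBT / N)
    if (max(abs(Im(B))) > 1e-8 * max(1, max(abs(Re(B)))))
      stop("covariance block has unexpectedly large imaginary part")
    blocks[, , n[1] + 1, n[2] + 1, n[3] + 1] <- Re(B)
  }
  structure(list(blocks = blocks, supercell = nc, kBT = kBT, K = model$K,
                 dof = model$dof),
            class = "lv_vcov")
}

#' Extract a covariance block by cell offset (and optionally group pair)
#'
#' @param vc an `lv_vcov`.
#' @param n integer cell offset (wrapped periodically).
#' @param ki,kj optional group indices; when given, the dof x dof sub-block
#'   for the pair is returned.
#' @return matrix.
#' @export
vcov_block <- function(vc, n = c(0, 0, 0), ki = NULL, kj = NULL) {
  nw <- ((as.integer(n) %% vc$supercell) + vc$supercell) %% vc$supercell
  B <- vc$blocks[, , nw[1] + 1, nw[2] + 1, nw[3] + 1]
  if (is.null(ki)) return(B)
  d <- vc$dof
  ii <- ((ki - 1) * d + 1):(ki * d)
  jj <- ((kj - 1) * d + 1):(kj * d)
  B[ii, jj, drop = FALSE]
}

#' TLS matrices of one rigid group
#'
#' Partitions the zero-offset diagonal 6x6 covariance block of group `kappa`
#' into the translation (T), libration (L) and screw (S) matrices of TLS
#' refinement: the block is `[[T, S^T], [S, L]]`. Units: T in A^2, L in
#' rad^2, S in A rad.
#'
#' @param vc an `lv_vcov` with `dof = 6`.
#' @param kappa group index.
#' @return list with `T`, `L`, `S`, `origin_block` (the full 6x6 block).
#' @export
tls_from_vcov <- function(vc, kappa = 1) {
  stopifnot(vc$dof == 6)
  B <- vcov_block(vc, c(0, 0, 0), kappa, kappa)
  list(T = B[1:3, 1:3], L = B[4:6, 4:6], S = B[4:6, 1:3], origin_block = B)
}

#' Per-atom anisotropic displacement parameters from the lattice model
#'
#' `U_jk = A_jk <w_k w_k^T> A_jk^T`; the equivalent isotropic B-factor is
#' `B = 8 pi^2 trace(U) / 3`. Atoms at the group origin have `U = T`
#' exactly.
#'
#' @param crystal the `lv_crystal` the covariance was computed for.
#' @param vc an `lv_vcov`.
#' @return data.frame with one row per atom of every group: group index,
#'   atom index, the six unique U components (A^2) and `b_iso` (A^2).
#' @export
adps_from_vcov <- function(crystal, vc) {
  out <- list()
  for (k in seq_len(crystal$K)) {
    g <- crystal$groups[[k]]
    W <- vcov_block(vc, c(0, 0, 0), k, k)
    xyz <- sweep(as.matrix(g$atoms[, c("x", "y", "z")]), 2, g$origin)
    for (j in seq_len(nrow(xyz))) {
      A <- projection_matrix(xyz[j, ], vc$dof)
      U <- A %*% W %*% t(A)
      out[[length(out) + 1L]] <- data.frame(
        group = k, atom = j,
        u11 = U[1, 1], u22 = U[2, 2], u33 = U[3, 3],
        u12 = U[1, 2], u13 = U[1, 3], u23 = U[2, 3],
        b_iso = 8 * pi^2 * sum(diag(U)) / 3)
    }
  }
  do.call(rbind, out)
}

#' Equivalent isotropic B-factor of an ADP matrix
#'
#' @param U 3x3 symmetric displacement covariance (A^2).
#' @return `8 pi^2 trace(U) / 3` in A^2.
#' @export
b_equivalent <- function(U) 8 * pi^2 * sum(diag(U)) / 3

#' Center-of-mass joint-ADPs for all pairs of rigid bodies
#'
#' Projects the generalized covariance onto the Cartesian displacement at
#' each group's center of mass (the translational sub-block, since
#' `A(0) = [I | 0]`) and symmetrizes over the pair:
#' `V = (U_(kl,k'l') + U_(k'l',kl)) / 2`, indexed by the cell offset
#' `n = l' - l`.
#'
#' @param vc an `lv_vcov`.
#' @param offsets optional integer matrix (rows = offsets) to restrict the
#'   output; default all supercell offsets.
#' @return data.frame of class `lv_jadp`: columns `n1,n2,n3`, `ki`, `kj`,
#'   `v11,v22,v33,v12,v13,v23` (A^2).
#' @export
com_joint_adps <- function(vc, offsets = NULL) {
  if (is.null(offsets)) {
    offsets <- as.matrix(expand.grid(n1 = 0:(vc$supercell[1] - 1),
                                     n2 = 0:(vc$supercell[2] - 1),
                                     n3 = 0:(vc$supercell[3] - 1)))
  }
  offsets <- rbind_h(offsets)
  out <- list()
  for (r in seq_len(nrow(offsets))) {
    n <- as.integer(offsets[r, ])
    for (ki in seq_len(vc$K)) {
      for (kj in seq_len(vc$K)) {
        # <w_(k,l) w_(k',l')^T> with l' - l = n is the block at offset -n
        # in the (l - l') indexing used by vcov_supercell; translational
        # 3x3 sub-block is the center-of-mass covariance
        B <- vcov_block(vc, -n, ki, kj)[1:3, 1:3]
        V <- (B + t(B)) / 2
        out[[length(out) + 1L]] <- data.frame(
          n1 = n[1], n2 = n[2], n3 = n[3], ki = ki, kj = kj,
          v11 = V[1, 1], v22 = V[2, 2], v33 = V[3, 3],
          v12 = V[1, 2], v13 = V[1, 3], v23 = V[2, 3])
      }
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("lv_jadp", "data.frame")
  out
}

# pack / unpack symmetric 3x3 matrices to the 6-vector convention used in
# joint-ADP tables (v11, v22, v33, v12, v13, v23)
sym_to_vec <- function(V) c(V[1, 1], V[2, 2], V[3, 3], V[1, 2], V[1, 3], V[2, 3])
vec_to_sym <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}
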