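# Staged refinement of spring constants against measured diffuse halos,
# with per-halo linear background terms profiled out exactly.

#' Select halos around the most intense Bragg peaks
#'
#' Picks the `n` most intense reflections inside a resolution window and
#' extracts, for each, the surrounding Brillouin-zone block of voxels from
#' the map (the central Bragg voxel itself is excluded, as are unmeasured
#' voxels).
#'
#' @param bragg data.frame with columns `h`, `k`, `l`, `I` (and optionally
#'   `sigma`).
#' @param map an `lv_map` with measured intensities and sigmas.
#' @param res_window resolution window in Angstroms, `c(dmin, dmax)`.
#' @param n number of halos requested.
#' @return list of halo observations: each has `h` (central Miller index),
#'   `hfrac` (voxel fractional indices), `dk` (fractional offsets from the
#'   center), `I`, `sigma`, `d` (resolution of the center).
#' @export
select_halos <- function(bragg, map, res_window = c(2.0, 2.5), n = 400) {
  d <- d_spacing(map$cell, as.matrix(bragg[, c("h", "k", "l")]))
  inwin <- d >= min(res_window) & d <= max(res_window)
  # the halo block must fit inside the map
  inmap <- abs(bragg$h) < map$hmax[1] & abs(bragg$k) < map$hmax[2] &
    abs(bragg$l) < map$hmax[3]
  cand <- bragg[inwin & inmap, , drop = FALSE]
  if (nrow(cand) == 0) stop("no Bragg peaks in the resolution window")
  cand <- cand[order(-cand$I), , drop = FALSE]
  if (nrow(cand) < n)
    warning(sprintf("only %d peaks available (%d requested)", nrow(cand), n))
  cand <- cand[seq_len(min(n, nrow(cand))), , drop = FALSE]
  ax <- map_axes(map)
  halos <- list()
  s <- map$subdiv
  for (r in seq_len(nrow(cand))) {
    g <- as.integer(cand[r, c("h", "k", "l")])
    ctr <- g * s + map$hmax * s + 1L # voxel index of the central RLP
    off <- as.matrix(expand.grid(a = -(s[1] %/% 2):(s[1] %/% 2),
                                 b = -(s[2] %/% 2):(s[2] %/% 2),
                                 cc = -(s[3] %/% 2):(s[3] %/% 2)))
    keep <- rowSums(off != 0) > 0
    off <- off[keep, , drop = FALSE]
    idx <- sweep(off, 2, ctr, "+")
    lin <- idx[, 1] + map$dims[1] * (idx[, 2] - 1) +
      map$dims[1] * map$dims[2] * (idx[, 3] - 1)
    meas <- map$measured[lin] & is.finite(map$I[lin])
    if (sum(meas) < 8) next
    dk <- sweep(off[meas, , drop = FALSE], 2, s, "/")
    halos[[length(halos) + 1L]] <- list(
      h = g, dk = dk, hfrac = sweep(dk, 2, g, "+"),
      I = map$I[lin][meas], sigma = pmax(map$sigma[lin][meas], 1e-12),
      d = d_spacing(map$cell, g))
  }
  if (!length(halos)) stop("no usable halos (all blocks unmeasured)")
  halos
}

# exact profiling of the per-halo linear background: weighted least squares
# of (I_obs - I_sim) on (1, dk1, dk2, dk3); returns coefficients and the
# profiled residual vector (inverse-sigma weighted)
profile_background <- function(halo, I_sim) {
  X <- cbind(1, halo$dk)
  w <- 1 / halo$sigma
  y <- (halo$I - I_sim)
  fit <- stats::lm.wfit(X * w, y * w, w = rep(1, length(y)))
  b <- fit$coefficients
  b[is.na(b)] <- 0
  list(coef = as.numeric(b), residual = as.numeric(y - X %*% b) / halo$sigma)
}

#' Weighted residuals of one halo given simulated intensities
#'
#' `(I_obs - I_sim - b0 - b . dk) / sigma`, with the four background
#' coefficients either supplied or profiled out exactly (the background
#' subproblem is linear).
#'
#' @param halo a halo observation from [select_halos()].
#' @param I_sim simulated one-phonon intensities at the halo voxels.
#' @param background optional length-4 coefficient vector; when `NULL` the
#'   optimal background is fit.
#' @return list with `residual` (inverse-sigma weighted) and `coef`.
#' @export
halo_residual <- function(halo, I_sim, background = NULL) {
  if (is.null(background)) return(profile_background(halo, I_sim))
  stopifnot(length(background) == 4)
  X <- cbind(1, halo$dk)
  r <- (halo$I - I_sim - as.numeric(X %*% background)) / halo$sigma
  list(residual = r, coef = background)
}

# simulate one-phonon intensities at all halo voxels, reusing one
# eigendecomposition per unique wavevector and precomputed structure factors
halo_predictor <- function(model, halos, supercell, kBT = 1) {
  hall <- do.call(rbind, lapply(halos, function(h) h$hfrac))
  nh <- vapply(halos, function(h) nrow(h$hfrac), integer(1))
  hd <- halo_decompose(hall, supercell)
  q <- q_cartesian(model$crystal$cell, hall)
  G <- one_phonon_sf_atoms(model$crystal, q, model$dof)
  kkey <- apply(round(sweep(hd$k, 2, supercell, "*")), 1, paste, collapse = ",")
  ukeys <- unique(kkey)
  krows <- lapply(ukeys, function(key) which(kkey == key))
  kvals <- hd$k[vapply(krows, `[`, integer(1), 1), , drop = FALSE]
  slices <- split(seq_len(nrow(hall)), rep(seq_along(halos), nh))
  function(m) {
    I <- numeric(nrow(hall))
    for (i in seq_along(ukeys)) {
      Ck <- covariance_kernel(m, kvals[i, ])
      Gr <- G[krows[[i]], , drop = FALSE]
      I[krows[[i]]] <- kBT * Re(rowSums((Gr %*% Ck) * Conj(Gr)))
    }
    lapply(slices, function(ix) I[ix])
  }
}

# chi-square over halos with backgrounds profiled out
halo_chi2 <- function(model, halos, predictor) {
  Isim <- predictor(model)
  total <- 0
  for (i in seq_along(halos)) {
    pr <- profile_background(halos[[i]], Isim[[i]])
    total <- total + sum(pr$residual^2)
  }
  total
}

#' Staged refinement of spring constants against halo observations
#'
#' Minimizes the inverse-sigma weighted least-squares error between
#' measured and simulated one-phonon halo intensities, with a 4-parameter
#' linear background profiled out exactly per halo. Four stages with
#' progressively fewer restraints:
#' 1. one global Gaussian constant;
#' 2. a Gaussian constant per interface class;
#' 3. a hybrid (Gaussian + parallel) constant per interface class;
#' 4. a hybrid constant per residue pair.
#' Stage results initialize the next stage (children inherit the parent
#' value; hybrid stages start with a tiny parallel component). Parameters
#' are log-transformed, enforcing positivity.
#'
#' @param crystal an `lv_crystal`.
#' @param contacts contact table from [find_contacts()].
#' @param halos halo observations from [select_halos()].
#' @param supercell supercell dimensions (must be compatible with the halo
#'   voxel offsets, i.e. the map subdivisions).
#' @param stages integer vector, subset of 1:4 (in order).
#' @param kBT temperature scale.
#' @param gamma_init initial global Gaussian constant.
#' @param dof 6 (rigid bodies) or 3 (translational bodies).
#' @param control list: `rel_tol` (default 1e-6), `max_iter` (default 200).
#' @return list with `model` (refined `lv_enm`), `stages` (per-stage level,
#'   form, parameter table, chi2, convergence), `backgrounds` (per-halo
#'   coefficients at the final parameters).
#' @export
refine_springs <- function(crystal, contacts, halos, supercell,
                           stages = 1:4, kBT = 1, gamma_init = 1,
                           dof = 6, control = list()) {
  rel_tol <- control$rel_tol %||% 1e-6
  max_iter <- control$max_iter %||% 200
  stage_def <- list(
    list(level = "global", form = "gaussian"),
    list(level = "interface", form = "gaussian"),
    list(level = "interface", form = "hybrid"),
    list(level = "residue_pair", form = "hybrid"))
  ids_of <- list(global = group_springs(contacts, crystal, "global"),
                 interface = group_springs(contacts, crystal, "interface"),
                 residue_pair = group_springs(contacts, crystal, "residue_pair"))
  # per-contact current values, carried between stages
  cg <- rep(gamma_init, nrow(contacts))
  cp <- rep(0, nrow(contacts))
  out_stages <- list()
  model <- NULL
  predictor <- NULL
  eps_p <- 1e-4
  for (st in stages) {
    def <- stage_def[[st]]
    ids <- ids_of[[def$level]]
    ng <- max(ids)
    g0 <- as.numeric(tapply(cg, ids, mean))
    p0 <- as.numeric(tapply(cp, ids, mean))
    hybrid <- def$form == "hybrid"
    if (hybrid) p0 <- pmax(p0, eps_p * g0)
    params <- spring_parameter_set(ids, g0, if (hybrid) p0 else 0,
                                   level = def$level)
    model <- build_enm(crystal, contacts, params, ids, dof = dof, kBT = kBT)
    if (is.null(predictor))
      predictor <- halo_predictor(model, halos, supercell, kBT)
    theta0 <- if (hybrid) log(c(g0, p0)) else log(g0)
    objective <- function(theta) {
      v <- exp(theta)
      m <- if (hybrid) set_params(model, v[seq_len(ng)], v[ng + seq_len(ng)])
      else set_params(model, v, rep(0, ng))
      tryCatch(halo_chi2(m, halos, predictor),
               error = function(e) 1e12) # unstable trial step
    }
    opt <- stats::nlminb(theta0, objective,
                         control = list(rel.tol = rel_tol,
                                        iter.max = max_iter))
    v <- exp(opt$par)
    gfit <- v[seq_len(ng)]
    pfit <- if (hybrid) v[ng + seq_len(ng)] else rep(0, ng)
    model <- set_params(model, gfit, pfit)
    cg <- gfit[ids]
    cp <- pfit[ids]
    out_stages[[length(out_stages) + 1L]] <- list(
      stage = st, level = def$level, form = def$form,
      params = data.frame(id = seq_len(ng), gamma_g = gfit, gamma_p = pfit),
      chi2 = opt$objective, convergence = opt$convergence,
      iterations = opt$iterations)
  }
  Isim <- predictor(model)
  backgrounds <- lapply(seq_along(halos), function(i)
    profile_background(halos[[i]], Isim[[i]])$coef)
  list(model = model, stages = out_stages, backgrounds = backgrounds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subtract the lattice contribution from a map and from ADPs
#'
#' Voxel-wise `I_internal = I_total - I_lattice` with sigma propagated
#' unchanged, and per-atom `U_internal = U_total - U_lattice` with a flag
#' where the residual is not positive semidefinite.
#'
#' @param map_total,map_lattice `lv_map`s on the same grid.
#' @param adps_total,adps_lattice optional ADP tables (columns
#'   `u11,u22,u33,u12,u13,u23`), matched by row.
#' @return list with `map` (residual `lv_map`) and, when ADPs are given,
#'   `adps` (residual table with logical `psd`).
#' @export
subtract_lattice <- function(map_total, map_lattice, adps_total = NULL,
                             adps_lattice = NULL) {
  stopifnot(all(dim(map_total$I) == dim(map_lattice$I)))
  out <- map_total
  out$I <- map_total$I - map_lattice$I
  res <- list(map = out)
  if (!is.null(adps_total)) {
    stopifnot(nrow(adps_total) == nrow(adps_lattice))
    cols <- c("u11", "u22", "u33", "u12", "u13", "u23")
    du <- adps_total[cols] - adps_lattice[cols]
    psd <- vapply(seq_len(nrow(du)), function(i) {
      U <- vec_to_sym(as.numeric(du[i, c("u11", "u22", "u33",
                                         "u12", "u13", "u23")]))
      min(eigen(U, symmetric = TRUE, only.values = TRUE)$values) >= -1e-10
    }, logical(1))
    adps <- cbind(du, b_iso = 8 * pi^2 * (du$u11 + du$u22 + du$u33) / 3,
                  psd = psd)
    res$adps <- adps
  }
  res
}
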