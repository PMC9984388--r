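# Rigid-group crystal construction: symmetry expansion of the asymmetric
# unit, inter-group contact search, spring grouping, and force-constant
# blocks for the elastic network.

.element_data <- data.frame(
  element = c("H", "C", "N", "O", "S", "P", "X"),
  mass = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 12.0),
  z = c(1, 6, 7, 8, 16, 15, 6),
  stringsAsFactors = FALSE
)

element_property <- function(element, what = c("mass", "z")) {
  what <- match.arg(what)
  i <- match(toupper(element), toupper(.element_data$element))
  if (anyNA(i)) stop("unknown element(s): ",
                     paste(unique(element[is.na(i)]), collapse = ", "))
  .element_data[[what]][i]
}

.solvent_resnames <- c("HOH", "WAT", "DOD", "CL", "NA", "SO4", "PO4", "GOL",
                       "EDO", "ACT", "NO3", "CA", "MG", "ZN", "K")

#' Construct a rigid group from an atom table
#'
#' The group origin is the (mass- and optionally occupancy-) weighted mean
#' position; the inertia tensor is taken about that origin.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` (Cartesian
#'   Angstroms) and optionally `occ`, `b`, `resid`, `chain`.
#' @param occ_weight logical; weight masses by occupancy when computing the
#'   origin, mass, and inertia (the convention for partial-occupancy atoms is
#'   not fixed by theory, so it is exposed as a flag).
#' @param op_index index of the generating symmetry operator (bookkeeping).
#' @return object of class `lv_group` with fields `atoms`, `origin`, `mass`,
#'   `inertia`, `op_index`.
#' @export
rigid_group <- function(atoms, occ_weight = FALSE, op_index = 1L) {
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$resid)) atoms$resid <- seq_len(nrow(atoms))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  m <- element_property(atoms$element, "mass")
  if (occ_weight) m <- m * atoms$occ
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  origin <- colSums(xyz * m) / sum(m)
  rel <- sweep(xyz, 2, origin)
  # inertia tensor sum m (|x|^2 I - x x^T)
  inert <- diag(3) * sum(m * rowSums(rel^2)) - t(rel * m) %*% rel
  structure(list(atoms = atoms, origin = as.numeric(origin), mass = sum(m),
                 masses = m, inertia = (inert + t(inert)) / 2,
                 op_index = as.integer(op_index)),
            class = "lv_group")
}

#' Expand an asymmetric unit to the full unit cell of rigid groups
#'
#' One rigid group is produced per chain per symmetry operator. Hydrogens and
#' solvent are excluded by default. Each symmetry mate is wrapped so that its
#' center of mass lies in the unit cell (atoms are never wrapped
#' individually, which would tear the body apart).
#'
#' @param asu data.frame of asymmetric-unit atoms (columns `element`, `x`,
#'   `y`, `z`, optional `chain`, `resid`, `occ`, `b`), Cartesian Angstroms.
#' @param cell an [unit_cell()].
#' @param exclude_hydrogen,exclude_solvent filters applied before expansion.
#' @param occ_weight see [rigid_group()].
#' @return object of class `lv_crystal` with fields `cell`, `groups` (list of
#'   `lv_group`), `K`, `asu_index` (map from unit-cell group to ASU chain).
#' @export
expand_to_unit_cell <- function(asu, cell, exclude_hydrogen = TRUE,
                                exclude_solvent = TRUE, occ_weight = FALSE) {
  stopifnot(inherits(cell, "lv_cell"))
  if (is.null(asu$chain)) asu$chain <- "A"
  keep <- rep(TRUE, nrow(asu))
  if (exclude_hydrogen) keep <- keep & toupper(asu$element) != "H"
  if (exclude_solvent && !is.null(asu$resname))
    keep <- keep & !(toupper(asu$resname) %in% .solvent_resnames)
  asu <- asu[keep, , drop = FALSE]
  if (nrow(asu) == 0) stop("empty asymmetric unit after filtering")
  chains <- unique(asu$chain)
  groups <- list()
  asu_index <- integer(0)
  for (iop in seq_along(cell$ops)) {
    op <- cell$ops[[iop]]
    for (ch in chains) {
      at <- asu[asu$chain == ch, , drop = FALSE]
      xf <- cell$frac %*% t(as.matrix(at[, c("x", "y", "z")]))
      xf2 <- apply_op(op, xf)
      # wrap by center of mass into [0, 1); the wrap shift is part of the
      # effective generating operator and is recorded for symmetry analysis
      com <- rowMeans(xf2)
      wrap <- -floor(com)
      xf2 <- xf2 + wrap
      xyz <- t(cell$ortho %*% xf2)
      at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
      g <- rigid_group(at, occ_weight = occ_weight, op_index = iop)
      g$wrap <- as.integer(wrap)
      groups[[length(groups) + 1L]] <- g
      asu_index <- c(asu_index, match(ch, chains))
    }
  }
  structure(list(cell = cell, groups = groups, K = length(groups),
                 asu_index = asu_index, chains = chains),
            class = "lv_crystal")
}

#' @export
print.lv_crystal <- function(x, ...) {
  cat(sprintf("<lv_crystal> %s, K=%d rigid groups, %d atoms/group (first)\n",
              x$cell$spacegroup, x$K, nrow(x$groups[[1]]$atoms)))
  invisible(x)
}

#' Find inter-group atomic contacts within a distance cutoff
#'
#' All atom pairs belonging to different rigid-group instances (same or
#' neighboring cells) with separation below the cutoff. Each unordered pair
#' of instances is stored once; the Hessian assembly adds both directions.
#' The contact vector points from the first atom to its partner.
#'
#' @param crystal an `lv_crystal`.
#' @param cutoff contact distance in Angstroms (default 4).
#' @return data.frame of class `lv_contacts`: columns `gi`, `ai`, `gj`, `aj`,
#'   `n1`, `n2`, `n3` (partner cell offset), `ux,uy,uz` (unit contact
#'   vector), `len`, `resid_i`, `resid_j`.
#' @export
find_contacts <- function(crystal, cutoff = 4) {
  stopifnot(inherits(crystal, "lv_crystal"), cutoff > 0)
  cell <- crystal$cell
  # perpendicular face spacings of the cell
  face <- cell$volume / c(
    sqrt(sum(cross3(cell$ortho[, 2], cell$ortho[, 3])^2)),
    sqrt(sum(cross3(cell$ortho[, 3], cell$ortho[, 1])^2)),
    sqrt(sum(cross3(cell$ortho[, 1], cell$ortho[, 2])^2)))
  if (cutoff > min(face) / 2)
    stop("cutoff exceeds half the smallest cell-face spacing; periodic images ambiguous")
  nrange <- pmax(1L, ceiling(cutoff / face))
  offs <- as.matrix(expand.grid(n1 = -nrange[1]:nrange[1],
                                n2 = -nrange[2]:nrange[2],
                                n3 = -nrange[3]:nrange[3]))
  K <- crystal$K
  res <- list()
  xyz <- lapply(crystal$groups, function(g)
    as.matrix(g$atoms[, c("x", "y", "z")]))
  for (gi in seq_len(K)) {
    for (gj in seq_len(K)) {
      for (r in seq_len(nrow(offs))) {
        n <- offs[r, ]
        # canonical orientation: gi < gj, or gi == gj with n lexicographically
        # positive (n != 0 required for same group)
        if (gi > gj) next
        if (gi == gj && !lex_positive(n)) next
        shift <- as.numeric(cell$ortho %*% n)
        xj <- sweep(xyz[[gj]], 2, -shift)
        # bounding-sphere pre-check
        ci <- crystal$groups[[gi]]$origin
        cj <- crystal$groups[[gj]]$origin + shift
        ri <- sqrt(max(rowSums(sweep(xyz[[gi]], 2, ci)^2)))
        rj <- sqrt(max(rowSums(sweep(xyz[[gj]], 2, crystal$groups[[gj]]$origin)^2)))
        if (sqrt(sum((ci - cj)^2)) > ri + rj + cutoff) next
        for (a in seq_len(nrow(xyz[[gi]]))) {
          d <- sweep(xj, 2, xyz[[gi]][a, ])
          dist <- sqrt(rowSums(d^2))
          hit <- which(dist <= cutoff & dist > 1e-6)
          for (b in hit) {
            res[[length(res) + 1L]] <- data.frame(
              gi = gi, ai = a, gj = gj, aj = b,
              n1 = n[1], n2 = n[2], n3 = n[3],
              ux = d[b, 1] / dist[b], uy = d[b, 2] / dist[b],
              uz = d[b, 3] / dist[b], len = dist[b],
              resid_i = crystal$groups[[gi]]$atoms$resid[a],
              resid_j = crystal$groups[[gj]]$atoms$resid[b])
          }
        }
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(gi = integer(0), ai = integer(0), gj = integer(0),
               aj = integer(0), n1 = integer(0), n2 = integer(0),
               n3 = integer(0), ux = numeric(0), uy = numeric(0),
               uz = numeric(0), len = numeric(0), resid_i = integer(0),
               resid_j = integer(0))
  class(out) <- c("lv_contacts", "data.frame")
  out
}

lex_positive <- function(n) {
  if (n[1] != 0) return(n[1] > 0)
  if (n[2] != 0) return(n[2] > 0)
  n[3] > 0
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Group springs by symmetry class
#'
#' Assigns every contact a parameter-group id. Two contacts related by a
#' space-group operator (which maps one pair of group instances onto the
#' other, transforming the cell offset accordingly) share an id. The
#' `interface` level partitions contacts into orbits of (group, group, cell
#' offset) triples under the space group; the `residue_pair` level refines
#' each interface class by the unordered pair of ASU residue identifiers; the
#' `global` level puts every contact in a single class.
#'
#' @param contacts output of [find_contacts()].
#' @param crystal the `lv_crystal` the contacts were computed from.
#' @param level one of `"global"`, `"interface"`, `"residue_pair"`.
#' @return integer vector of parameter-group ids (1-based, dense).
#' @export
group_springs <- function(contacts, crystal,
                          level = c("interface", "global", "residue_pair")) {
  level <- match.arg(level)
  if (nrow(contacts) == 0) stop("no contacts to group")
  if (level == "global") return(rep(1L, nrow(contacts)))
  iface <- interface_classes(contacts, crystal)
  if (level == "interface") return(iface)
  key <- paste(iface,
               pmin(contacts$resid_i, contacts$resid_j),
               pmax(contacts$resid_i, contacts$resid_j), sep = "|")
  as.integer(factor(key, levels = unique(key)))
}

# orbit of the (gi, gj, offset) triple under the space group, with the
# unordered-pair mirror (gj, gi, -offset) identified
interface_classes <- function(contacts, crystal) {
  ops <- crystal$cell$ops
  # effective generating operators include the center-of-mass wrap shift
  # applied when the unit cell was built
  eff <- lapply(crystal$groups, function(g) {
    op <- ops[[g$op_index]]
    w <- if (is.null(g$wrap)) c(0L, 0L, 0L) else g$wrap
    list(R = op$R, t = op$t + w)
  })
  nops <- length(ops)
  chain_of <- crystal$asu_index %||% rep(1L, length(eff))
  # action of op m on group index k: g.eff_k = eff_k2 + lattice shift,
  # restricted to groups generated from the same ASU chain
  act <- vector("list", nops)
  for (m in seq_len(nops)) {
    act[[m]] <- lapply(seq_along(eff), function(k) {
      composed <- compose_ops(ops[[m]], eff[[k]])
      cand <- which(chain_of == chain_of[k])
      mm <- match_op(eff[cand], composed)
      list(k2 = cand[mm$k2], shift = mm$shift)
    })
  }
  canon <- function(gi, gj, n) {
    m1 <- c(gi, gj, n)
    m2 <- c(gj, gi, -n)
    a <- paste(m1, collapse = ",")
    b <- paste(m2, collapse = ",")
    if (a <= b) a else b
  }
  orbit_key <- character(nrow(contacts))
  for (i in seq_len(nrow(contacts))) {
    gi <- contacts$gi[i]; gj <- contacts$gj[i]
    n <- c(contacts$n1[i], contacts$n2[i], contacts$n3[i])
    keys <- character(nops)
    for (m in seq_len(nops)) {
      ai <- act[[m]][[gi]]; aj <- act[[m]][[gj]]
      n2 <- ai_shifted_offset(ops[[m]], n, ai, aj)
      keys[m] <- canon(ai$k2, aj$k2, n2)
    }
    orbit_key[i] <- min(keys)
  }
  as.integer(factor(orbit_key, levels = unique(orbit_key)))
}

# image of the cell offset under op m: instance (k, c) -> (k2, shift + R c)
ai_shifted_offset <- function(op, n, ai, aj) {
  as.integer(round(aj$shift + op$R %*% n - ai$shift))
}

#' Hybrid spring force-constant block
#'
#' Returns the 3x3 symmetric force-constant matrix
#' `gamma_g * I + gamma_p * u %o% u` for a contact with unit vector `u`:
#' a Gaussian term restoring displacement in any direction plus a parallel
#' term restoring only the component along the inter-atomic vector.
#'
#' @param u unit contact vector (length 3).
#' @param gamma_g Gaussian stiffness (kBT/A^2), `>= 0`.
#' @param gamma_p parallel stiffness (kBT/A^2), `>= 0`.
#' @return 3x3 symmetric positive semidefinite matrix.
#' @export
force_constant_block <- function(u, gamma_g, gamma_p) {
  if (gamma_g < 0 || gamma_p < 0) stop("spring stiffness must be >= 0")
  u <- as.numeric(u)
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("zero-length contact vector")
  u <- u / nu
  gamma_g * diag(3) + gamma_p * (u %o% u)
}

#' Spring parameter set
#'
#' @param ids integer parameter-group id per contact (from
#'   [group_springs()]).
#' @param gamma_g,gamma_p per-group stiffnesses, recycled to the number of
#'   groups.
#' @param level grouping level label.
#' @return data.frame of class `lv_springs` with one row per parameter group.
#' @export
spring_parameter_set <- function(ids, gamma_g = 1, gamma_p = 0,
                                 level = "interface") {
  ng <- max(ids)
  out <- data.frame(id = seq_len(ng),
                    gamma_g = rep_len(gamma_g, ng),
                    gamma_p = rep_len(gamma_p, ng))
  if (any(out$gamma_g < 0) || any(out$gamma_p < 0))
    stop("spring stiffness must be >= 0")
  attr(out, "level") <- level
  class(out) <- c("lv_springs", "data.frame")
  out
}
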