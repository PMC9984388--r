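#' Unit cell geometry with space-group symmetry
#'
#' Builds a unit-cell description holding the cell parameters, the
#' orthogonalization/fractionalization transforms, the reciprocal basis, and
#' the space-group symmetry operators (fractional rotation + translation).
#'
#' The orthogonalization matrix follows the standard crystallographic (PDB)
#' convention: its columns are the cell basis vectors a, b, c in a Cartesian
#' frame with a along x and b in the xy plane. Reciprocal vectors include the
#' factor of 2*pi, so a fractional Miller index `h` maps to the Cartesian
#' scattering vector `q = recip %*% h` in inverse Angstroms (radians).
#'
#' @param a,b,c cell edge lengths in Angstroms.
#' @param alpha,beta,gamma cell angles in degrees.
#' @param spacegroup one of `"P1"`, `"P21"`, `"P212121"`, or `NULL` when a
#'   custom operator list is supplied via `ops`.
#' @param ops optional list of operators, each `list(R = <3x3 matrix>,
#'   t = <length-3 fractional translation>)`; overrides `spacegroup`.
#' @return an object of class `lv_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      spacegroup = "P1", ops = NULL) {
  stopifnot(a > 0, b > 0, c > 0)
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  v <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v <= 0) stop("degenerate unit cell (angles inconsistent)")
  ortho <- cbind(
    c(a, 0, 0),
    c(b * cg, b * sg, 0),
    c(c * cb, c * (ca - cb * cg) / sg, c * sqrt(v) / sg)
  )
  frac <- solve(ortho)
  recip <- 2 * pi * t(frac) # q_cart = recip %*% h_frac
  if (is.null(ops)) {
    if (is.null(spacegroup)) stop("either spacegroup or ops must be given")
    ops <- spacegroup_ops(spacegroup)
  } else {
    ops <- lapply(ops, function(o) list(R = matrix(as.numeric(o$R), 3, 3),
                                        t = as.numeric(o$t)))
    spacegroup <- if (is.null(spacegroup)) "custom" else spacegroup
  }
  check_ops_closed(ops)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, spacegroup = spacegroup, ops = ops,
                 ortho = ortho, frac = frac, recip = recip,
                 volume = a * b * c * sqrt(v)),
            class = "lv_cell")
}

#' @export
print.lv_cell <- function(x, ...) {
  cat(sprintf("<lv_cell> %s  a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  (%d ops)\n",
              x$spacegroup, x$a, x$b, x$c, x$alpha, x$beta, x$gamma, length(x$ops)))
  invisible(x)
}

#' Symmetry operators of the supported space groups
#'
#' Operators are returned in fractional coordinates as `list(R, t)`.
#' The screw settings follow the standard tables: P21 with the 2-fold screw
#' along b, P212121 with the three orthogonal 2-fold screws.
#'
#' @param name space group symbol.
#' @return list of operators.
#' @export
spacegroup_ops <- function(name) {
  id <- diag(3)
  op <- function(R, t) list(R = R, t = t)
  switch(name,
    "P1" = list(op(id, c(0, 0, 0))),
    "P21" = list(
      op(id, c(0, 0, 0)),
      op(diag(c(-1, 1, -1)), c(0, 0.5, 0))
    ),
    "P212121" = list(
      op(id, c(0, 0, 0)),
      op(diag(c(1, -1, -1)), c(0.5, 0.5, 0)),
      op(diag(c(-1, 1, -1)), c(0, 0.5, 0.5)),
      op(diag(c(-1, -1, 1)), c(0.5, 0, 0.5))
    ),
    stop("unknown space group symbol: ", name)
  )
}

# operators must form a group under composition modulo lattice translations
check_ops_closed <- function(ops, tol = 1e-10) {
  n <- length(ops)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      R <- ops[[i]]$R %*% ops[[j]]$R
      tt <- as.numeric(ops[[i]]$R %*% ops[[j]]$t + ops[[i]]$t)
      found <- FALSE
      for (k in seq_len(n)) {
        if (max(abs(R - ops[[k]]$R)) < tol) {
          dt <- tt - ops[[k]]$t
          if (max(abs(dt - round(dt))) < tol) { found <- TRUE; break }
        }
      }
      if (!found) stop("symmetry operators are not closed under composition")
    }
  }
  invisible(TRUE)
}

#' Apply a symmetry operator to fractional coordinates
#'
#' @param op operator `list(R, t)`.
#' @param xf 3-vector or 3-row matrix of fractional coordinates (columns are
#'   points).
#' @return transformed fractional coordinates, same shape.
#' @export
apply_op <- function(op, xf) {
  if (is.matrix(xf)) op$R %*% xf + op$t else as.numeric(op$R %*% xf + op$t)
}

# compose two fractional operators: (a o b)(x) = a(b(x))
compose_ops <- function(a, b) {
  list(R = a$R %*% b$R, t = as.numeric(a$R %*% b$t + a$t))
}

# identify g o op_k as op_k2 plus an integer lattice shift; returns
# list(k2, shift) or errors if not found (ops not a group)
match_op <- function(ops, composed, tol = 1e-8) {
  for (k in seq_along(ops)) {
    if (max(abs(composed$R - ops[[k]]$R)) < tol) {
      dt <- composed$t - ops[[k]]$t
      if (max(abs(dt - round(dt))) < tol) {
        return(list(k2 = k, shift = as.integer(round(dt))))
      }
    }
  }
  stop("operator composition not found in group")
}

#' Resolution (d-spacing) of Miller indices
#'
#' @param cell an `lv_cell`.
#' @param h matrix with 3 columns (or length-3 vector) of (fractional) Miller
#'   indices.
#' @return d-spacings in Angstroms (`Inf` at the origin).
#' @export
d_spacing <- function(cell, h) {
  h <- rbind_h(h)
  q <- cell$recip %*% t(h)
  qn <- sqrt(colSums(q^2))
  ifelse(qn > 0, 2 * pi / qn, Inf)
}

# coerce h input to an n x 3 matrix
rbind_h <- function(h) {
  if (is.null(dim(h))) matrix(h, ncol = 3) else as.matrix(h)
}

#' Cartesian scattering vectors for fractional Miller indices
#'
#' @inheritParams d_spacing
#' @return n x 3 matrix of q vectors (1/Angstrom, includes 2*pi).
#' @export
q_cartesian <- function(cell, h) {
  h <- rbind_h(h)
  t(cell$recip %*% t(h))
}
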