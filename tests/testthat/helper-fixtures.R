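# Shared fixtures, memoized so expensive toys are built once per test run.

.lv_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .lv_cache)) assign(key, force(expr), envir = .lv_cache)
  get(key, envir = .lv_cache)
}

toy_p1 <- function() memo("toy_p1", make_toy_crystal(toy_crystal_spec("P1")))

toy_p1_model <- function() memo("toy_p1_model", {
  toy <- toy_p1()
  build_enm(toy$crystal, toy$contacts, toy$params, toy$ids)
})

# translation-only hybrid-spring toy: anisotropic covariances with exactly
# the physics the delta-PDF deconvolution assumes (pure translations)
toy_surrogate <- function() memo("toy_surrogate", {
  toy <- make_toy_crystal(toy_crystal_spec(
    "P1", sigma_atom = 0.5, gamma_g = c(2, 2.8, 3.6), gamma_p = c(3, 5, 2)))
  model <- build_enm(toy$crystal, toy$contacts, toy$params, toy$ids, dof = 3)
  list(toy = toy, model = model)
})

toy_ortho <- function() memo("toy_ortho",
  make_toy_crystal(toy_crystal_spec("P212121", sigma_atom = 0.6)))

toy_ortho_model <- function() memo("toy_ortho_model", {
  toy <- toy_ortho()
  build_enm(toy$crystal, toy$contacts, toy$params, toy$ids)
})

# compact single body in a P1 cell (no contacts needed): used for the
# molecular-transform accuracy oracle
compact_body_crystal <- function(radius = 2.0, sigma = 0.5) {
  key <- paste0("compact_", radius, "_", sigma)
  memo(key, {
    uc <- unit_cell(13, 13.5, 14, 88, 92, 95, "P1")
    set.seed(42)
    xyz <- rbind(c(0, 0, 0), diag(3) * radius, -diag(3) * radius) +
      matrix(stats::rnorm(21, sd = 0.2), 7, 3)
    com <- as.numeric(uc$ortho %*% c(0.5, 0.5, 0.5))
    xyz <- sweep(xyz, 2, com - colMeans(xyz), "+")
    asu <- data.frame(element = "X", x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], occ = 1, b = 0, resid = 1:7,
                      chain = "A", sigma = sigma)
    expand_to_unit_cell(asu, uc)
  })
}

# brute-force all-pairs contact search over 3^3 neighbor cells (oracle)
brute_contacts <- function(crystal, cutoff) {
  cell <- crystal$cell
  hits <- 0L
  pairs <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (gi in seq_len(crystal$K)) for (gj in seq_len(crystal$K)) {
    xi <- as.matrix(crystal$groups[[gi]]$atoms[, c("x", "y", "z")])
    xj0 <- as.matrix(crystal$groups[[gj]]$atoms[, c("x", "y", "z")])
    for (r in seq_len(nrow(offs))) {
      n <- offs[r, ]
      if (gi == gj && all(n == 0)) next
      xj <- sweep(xj0, 2, -as.numeric(cell$ortho %*% n))
      for (a in seq_len(nrow(xi))) for (b in seq_len(nrow(xj))) {
        d <- sqrt(sum((xi[a, ] - xj[b, ])^2))
        if (d <= cutoff && d > 1e-6)
          pairs[[length(pairs) + 1L]] <- c(gi, a, gj, b, n)
      }
    }
  }
  pairs
}

# canonical string key of a contact table (unordered pairs, both directions)
contact_keys <- function(contacts) {
  fwd <- sprintf("%d.%d|%d.%d|%d,%d,%d", contacts$gi, contacts$ai,
                 contacts$gj, contacts$aj, contacts$n1, contacts$n2,
                 contacts$n3)
  rev <- sprintf("%d.%d|%d.%d|%d,%d,%d", contacts$gj, contacts$aj,
                 contacts$gi, contacts$ai, -contacts$n1, -contacts$n2,
                 -contacts$n3)
  sort(pmin(fwd, rev))
}

# local copy of the symmetric-matrix packing used in the package tables
vec_to_sym_test <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

# unwrap supercell offsets into the symmetric range for joint-ADP matching
unwrap_offsets <- function(df, supercell) {
  for (i in 1:3) {
    cn <- c("n1", "n2", "n3")[i]
    df[[cn]] <- ifelse(df[[cn]] > supercell[i] %/% 2,
                       df[[cn]] - supercell[i], df[[cn]])
  }
  df
}
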