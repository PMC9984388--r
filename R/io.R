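# File I/O: atomic models (PDB / mmCIF subset), diffuse maps and Bragg
# lists as documented tabular text, spring networks and joint-ADPs as JSON,
# TLS records in REFMAC-like convention.

#' Read atomic coordinates from a PDB file
#'
#' Parses ATOM/HETATM records (fixed columns): element, Cartesian
#' coordinates, occupancy, isotropic B, chain, residue number and name.
#'
#' @param path file path.
#' @return data.frame with columns `element`, `x`, `y`, `z`, `occ`, `b`,
#'   `chain`, `resid`, `resname`, `name`.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)
  el <- trimws(substr(lines, 77, 78))
  noel <- el == ""
  if (any(noel)) { # fall back to the atom-name column
    nm <- trimws(substr(lines[noel], 13, 16))
    el[noel] <- substr(nm, 1, 1)
  }
  data.frame(
    element = el,
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    occ = as.numeric(substr(lines, 55, 60)),
    b = as.numeric(substr(lines, 61, 66)),
    chain = trimws(substr(lines, 22, 22)),
    resid = as.integer(substr(lines, 23, 26)),
    resname = trimws(substr(lines, 18, 20)),
    name = trimws(substr(lines, 13, 16)),
    stringsAsFactors = FALSE)
}

#' Read the unit cell (and space group) from a PDB CRYST1 record
#'
#' @param path file path.
#' @return an [unit_cell()] (space-group symbol must be one of the
#'   supported settings).
#' @export
read_pdb_cell <- function(path) {
  lines <- readLines(path)
  cr <- lines[startsWith(lines, "CRYST1")]
  if (!length(cr)) stop("no CRYST1 record in ", path)
  cr <- cr[1]
  sg <- gsub(" ", "", substr(cr, 56, 66))
  unit_cell(as.numeric(substr(cr, 7, 15)), as.numeric(substr(cr, 16, 24)),
            as.numeric(substr(cr, 25, 33)), as.numeric(substr(cr, 34, 40)),
            as.numeric(substr(cr, 41, 47)), as.numeric(substr(cr, 48, 54)),
            spacegroup = sg)
}

#' Read atomic coordinates from an mmCIF file (atom_site subset)
#'
#' Minimal reader for the `_atom_site` loop: element, Cartesian
#' coordinates, occupancy, isotropic B, chain and residue identifiers.
#'
#' @param path file path.
#' @return data.frame as in [read_pdb()].
#' @export
read_mmcif <- function(path) {
  lines <- readLines(path)
  i <- which(trimws(lines) == "loop_")
  for (start in i) {
    j <- start + 1
    fields <- character(0)
    while (j <= length(lines) && startsWith(trimws(lines[j]), "_")) {
      fields <- c(fields, trimws(lines[j])); j <- j + 1
    }
    if (!any(startsWith(fields, "_atom_site."))) next
    rows <- list()
    while (j <= length(lines)) {
      ln <- trimws(lines[j])
      if (ln == "" || startsWith(ln, "_") || startsWith(ln, "loop_") ||
          startsWith(ln, "#")) break
      rows[[length(rows) + 1L]] <- scan(text = ln, what = "character",
                                        quiet = TRUE)
      j <- j + 1
    }
    tab <- do.call(rbind, rows)
    colnames(tab) <- sub("^_atom_site\\.", "", fields)
    pick <- function(nm, alt = NULL) {
      if (nm %in% colnames(tab)) tab[, nm]
      else if (!is.null(alt) && alt %in% colnames(tab)) tab[, alt]
      else NA
    }
    return(data.frame(
      element = pick("type_symbol"),
      x = as.numeric(pick("Cartn_x")),
      y = as.numeric(pick("Cartn_y")),
      z = as.numeric(pick("Cartn_z")),
      occ = as.numeric(pick("occupancy")),
      b = as.numeric(pick("B_iso_or_equiv")),
      chain = pick("auth_asym_id", "label_asym_id"),
      resid = suppressWarnings(as.integer(pick("auth_seq_id", "label_seq_id"))),
      resname = pick("auth_comp_id", "label_comp_id"),
      name = pick("auth_atom_id", "label_atom_id"),
      stringsAsFactors = FALSE))
  }
  stop("no _atom_site loop found in ", path)
}

#' Write / read a diffuse voxel map as tabular text
#'
#' The header line (prefixed `#`) carries the grid metadata as JSON (cell,
#' space group, subdivisions, hmax); the body is one voxel per line with
#' fractional Miller indices, intensity, sigma, and the measured flag. Only
#' measured voxels are written unless `all = TRUE`.
#'
#' @param map an `lv_map`.
#' @param path output path (`.tsv`).
#' @param all write unmeasured voxels too.
#' @export
write_map_tsv <- function(map, path, all = FALSE) {
  meta <- list(a = map$cell$a, b = map$cell$b, c = map$cell$c,
               alpha = map$cell$alpha, beta = map$cell$beta,
               gamma = map$cell$gamma, spacegroup = map$cell$spacegroup,
               subdiv = map$subdiv, hmax = map$hmax)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# lv_map ", jsonlite::toJSON(meta, auto_unbox = TRUE)),
             con)
  h <- map_hgrid(map)
  keep <- if (all) rep(TRUE, nrow(h)) else as.logical(map$measured)
  df <- data.frame(h = h[keep, 1], k = h[keep, 2], l = h[keep, 3],
                   I = as.numeric(map$I)[keep],
                   sigma = as.numeric(map$sigma)[keep],
                   measured = as.integer(map$measured)[keep])
  utils::write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_tsv
#' @param path input path.
#' @return an `lv_map`.
#' @export
read_map_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "# lv_map ")) stop("not an lv_map TSV file: ", path)
  meta <- jsonlite::fromJSON(sub("^# lv_map ", "", hdr))
  cell <- unit_cell(meta$a, meta$b, meta$c, meta$alpha, meta$beta,
                    meta$gamma, spacegroup = meta$spacegroup)
  map <- voxel_map(cell, meta$subdiv, meta$hmax)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  idx <- cbind(round((df$h + map$hmax[1]) * map$subdiv[1]) + 1,
               round((df$k + map$hmax[2]) * map$subdiv[2]) + 1,
               round((df$l + map$hmax[3]) * map$subdiv[3]) + 1)
  map$I[idx] <- df$I
  map$sigma[idx] <- df$sigma
  map$measured[idx] <- df$measured > 0
  map
}

#' Write / read a Bragg intensity list as TSV
#'
#' Columns `h k l I sigma` (sigma optional on input, written as 0 when
#' absent).
#'
#' @param bragg data.frame with columns `h`, `k`, `l`, `I` and optionally
#'   `sigma`.
#' @param path file path.
#' @export
write_bragg_tsv <- function(bragg, path) {
  if (is.null(bragg$sigma)) bragg$sigma <- 0
  utils::write.table(bragg[, c("h", "k", "l", "I", "sigma")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bragg_tsv
#' @export
read_bragg_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Export a spring network and its parameter grouping as JSON
#'
#' @param contacts contact table from [find_contacts()].
#' @param ids parameter-group id per contact.
#' @param params `lv_springs` table.
#' @param path output path.
#' @export
write_springs_json <- function(contacts, ids, params, path) {
  obj <- list(level = attr(params, "level"),
              parameters = params,
              contacts = cbind(contacts, param_id = ids))
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' Export joint-ADPs as JSON records
#'
#' One record per offset: `{offset: [n1,n2,n3], V: [6 floats], total,
#' aniso: [6 floats]}`.
#'
#' @param jadps data.frame with `n1,n2,n3` and `v11..v23`.
#' @param path output path.
#' @export
write_jadp_json <- function(jadps, path) {
  cols <- c("v11", "v22", "v33", "v12", "v13", "v23")
  recs <- lapply(seq_len(nrow(jadps)), function(i) {
    V <- vec_to_sym(as.numeric(jadps[i, cols]))
    sp <- split_adp(V)
    list(offset = as.integer(jadps[i, c("n1", "n2", "n3")]),
         V = as.numeric(jadps[i, cols]),
         total = sp$total,
         aniso = sym_to_vec(sp$aniso))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Format TLS matrices as REFMAC-like text records
#'
#' Libration is reported in squared degrees by default (`L` is computed in
#' rad^2; the unit flag is explicit).
#'
#' @param tls list with `T`, `L`, `S` from [tls_from_vcov()].
#' @param origin group origin (Angstroms).
#' @param l_unit `"deg2"` or `"rad2"`.
#' @return character vector of lines.
#' @export
format_tls <- function(tls, origin = c(0, 0, 0), l_unit = c("deg2", "rad2")) {
  l_unit <- match.arg(l_unit)
  fac <- if (l_unit == "deg2") (180 / pi)^2 else 1
  sfac <- if (l_unit == "deg2") (180 / pi) else 1
  Tm <- tls$T; Lm <- tls$L * fac; Sm <- tls$S * sfac
  c(sprintf("ORIGIN %10.4f %10.4f %10.4f", origin[1], origin[2], origin[3]),
    sprintf("T %9.5f %9.5f %9.5f %9.5f %9.5f %9.5f",
            Tm[1, 1], Tm[2, 2], Tm[3, 3], Tm[1, 2], Tm[1, 3], Tm[2, 3]),
    sprintf("L (%s) %9.5f %9.5f %9.5f %9.5f %9.5f %9.5f", l_unit,
            Lm[1, 1], Lm[2, 2], Lm[3, 3], Lm[1, 2], Lm[1, 3], Lm[2, 3]),
    sprintf("S %9.5f %9.5f %9.5f %9.5f %9.5f %9.5f %9.5f %9.5f %9.5f",
            Sm[1, 1], Sm[1, 2], Sm[1, 3], Sm[2, 1], Sm[2, 2], Sm[2, 3],
            Sm[3, 1], Sm[3, 2], Sm[3, 3]))
}
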