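#' @keywords internal
"_PACKAGE"

# Chemical alphabet used for the one-hot atom encoding.
CHEM_ALPHABET <- c("C", "H", "O", "N", "S", "SE")

# Van der Waals radii (Angstrom), Bondi-style values. Elements outside the
# table fall back to 1.7 (carbon-like), which only affects surface extent.
VDW_RADII <- c(
  C = 1.70, H = 1.20, O = 1.52, N = 1.55, S = 1.80, SE = 1.90,
  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)

# HETATM residue names never treated as ligands: water, common ions,
# buffers and cryoprotectants (standard pocket-benchmark exclusions).
LIGAND_EXCLUDE <- c(
  "HOH", "DOD", "WAT", "NA", "K", "CL", "BR", "I", "F", "ZN", "MG", "CA",
  "MN", "FE", "FE2", "CO", "NI", "CU", "CD", "HG", "SO4", "PO4", "GOL",
  "EDO", "PEG", "PG4", "MPD", "DMS", "ACT", "FMT", "NO3", "TRS", "BME",
  "IOD", "NH4", "CS", "LI", "RB", "SR", "BA", "AZI", "CO3", "CIT", "TAR",
  "MES", "EPE", "IMD", "PGE", "1PE", "BCT", "OH", "SCN", "CN", "BOG"
)

#' Map an element symbol to the chemical alphabet index
#'
#' The per-point chemical features one-hot encode atoms over the six-letter
#' alphabet C, H, O, N, S, Se (0-based indices 0..5). Any other element maps
#' to `"other"` and is excluded from the chemical featurization.
#'
#' @param symbol Character vector of element symbols (case-insensitive).
#' @return Integer vector with values in 0..5, `NA` for `"other"`.
#' @examples
#' element_to_chem_index(c("C", "se", "P"))
#' @export
element_to_chem_index <- function(symbol) {
  if (length(symbol) == 0L) return(integer(0))
  sym <- toupper(trimws(as.character(symbol)))
  if (any(is.na(sym) | sym == "")) {
    stop("element_to_chem_index: empty or missing element symbol", call. = FALSE)
  }
  match(sym, CHEM_ALPHABET) - 1L
}

vdw_radius <- function(symbol) {
  r <- VDW_RADII[toupper(trimws(symbol))]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Construct an atom set
#'
#' @param coords Numeric matrix, n x 3, Cartesian coordinates in Angstrom.
#' @param elements Character vector of element symbols, length n.
#' @param is_protein Logical vector, length n.
#' @param meta Optional data.frame of per-atom PDB metadata (resid, resno,
#'   chain, elety) retained for round-trip writing.
#' @return An object of class `atom_set`.
#' @export
atom_set <- function(coords, elements, is_protein = rep(TRUE, nrow(coords)),
                     meta = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(ncol(coords) == 3L, nrow(coords) == length(elements),
            nrow(coords) == length(is_protein))
  if (!all(is.finite(coords))) stop("atom_set: non-finite coordinates", call. = FALSE)
  chem <- element_to_chem_index(elements)
  if (!any(is_protein & !is.na(chem))) {
    stop("atom_set: no protein atom with an in-alphabet element", call. = FALSE)
  }
  structure(
    list(coords = coords, elements = toupper(trimws(elements)),
         chem_index = chem, is_protein = as.logical(is_protein), meta = meta),
    class = "atom_set"
  )
}

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("<atom_set> %d atoms (%d protein), %d in chemical alphabet\n",
              nrow(x$coords), sum(x$is_protein), sum(!is.na(x$chem_index))))
  invisible(x)
}

#' Construct a ligand site (ground-truth binding site)
#'
#' The site center is the unweighted arithmetic mean of the ligand's
#' heavy-atom coordinates; center-center distance (DCC) is measured to it.
#'
#' @param ligand_id Identifier, e.g. `"ATP_A_500"`.
#' @param atom_coords Numeric matrix, n x 3, heavy-atom coordinates.
#' @return An object of class `ligand_site` with fields `ligand_id`,
#'   `atom_coords` and `center`.
#' @export
ligand_site <- function(ligand_id, atom_coords) {
  atom_coords <- matrix(as.numeric(atom_coords), ncol = 3L)
  if (nrow(atom_coords) < 1L) stop("ligand_site: needs >= 1 heavy atom", call. = FALSE)
  if (!all(is.finite(atom_coords))) stop("ligand_site: non-finite coordinates", call. = FALSE)
  structure(
    list(ligand_id = as.character(ligand_id), atom_coords = atom_coords,
         center = colMeans(atom_coords)),
    class = "ligand_site"
  )
}

#' @export
print.ligand_site <- function(x, ...) {
  cat(sprintf("<ligand_site> %s: %d heavy atoms, center (%.2f, %.2f, %.2f)\n",
              x$ligand_id, nrow(x$atom_coords), x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Read a protein structure and its ligand sites from a PDB file
#'
#' ATOM records become the protein [atom_set()]; HETATM residues passing the
#' ligand filter become one [ligand_site()] each (per chain/residue-number
#' copy). Water, common ions and buffers are excluded; with
#' `ligand_selector = "auto"` any remaining HETATM residue with at least
#' `min_ligand_atoms` heavy atoms is a ligand. Only the highest-occupancy
#' alternate conformer of each atom is kept. All protein chains are merged;
#' hydrogens are used when present but never added.
#'
#' @param path Path to a PDB file.
#' @param ligand_selector Character vector of HETATM residue names to treat
#'   as ligands, or `"auto"` (default) for the size-based rule above.
#' @param min_ligand_atoms Minimum heavy-atom count for auto-detection.
#' @param exclude Residue names never treated as ligands.
#' @return A list with elements `atoms` ([atom_set()]) and `sites`
#'   (list of [ligand_site()]).
#' @export
read_structure <- function(path, ligand_selector = "auto",
                           min_ligand_atoms = 4L, exclude = LIGAND_EXCLUDE) {
  if (!file.exists(path)) stop("read_structure: file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("read_structure: cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  # keep highest-occupancy alternate conformer per atom identity
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$resid, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      keep[idx] <- FALSE
      keep[idx[which.max(occ[idx])]] <- TRUE
    }
    at <- at[keep, , drop = FALSE]
  }
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | trimws(at$elesy) == "",
                                substr(gsub("[^A-Za-z].*$", "", trimws(at$elety)), 1, 2),
                                at$elesy)))
  is_atom_rec <- at$type == "ATOM"
  if (!any(is_atom_rec)) stop("read_structure: no ATOM records (empty structure)", call. = FALSE)

  prot <- at[is_atom_rec, , drop = FALSE]
  atoms <- atom_set(
    coords = cbind(prot$x, prot$y, prot$z),
    elements = elem[is_atom_rec],
    is_protein = rep(TRUE, sum(is_atom_rec)),
    meta = data.frame(resid = prot$resid, resno = prot$resno,
                      chain = ifelse(is.na(prot$chain), "A", prot$chain),
                      elety = prot$elety, stringsAsFactors = FALSE)
  )

  het <- at[!is_atom_rec, , drop = FALSE]
  sites <- list()
  if (nrow(het) > 0L) {
    het_elem <- elem[!is_atom_rec]
    heavy <- het_elem != "H"
    grp <- paste(het$resid, ifelse(is.na(het$chain), "?", het$chain), het$resno, sep = "_")
    for (g in unique(grp)) {
      idx <- which(grp == g & heavy)
      if (length(idx) == 0L) next
      resname <- het$resid[idx[1]]
      if (toupper(resname) %in% toupper(exclude)) next
      selected <- if (identical(ligand_selector, "auto")) {
        length(idx) >= min_ligand_atoms
      } else {
        toupper(resname) %in% toupper(ligand_selector)
      }
      if (!selected) next
      sites[[length(sites) + 1L]] <-
        ligand_site(g, cbind(het$x[idx], het$y[idx], het$z[idx]))
    }
  }
  list(atoms = atoms, sites = sites)
}

#' Write an atom set (plus optional ligand sites) to a PDB file
#'
#' @param atoms An [atom_set()].
#' @param path Output file path.
#' @param sites Optional list of [ligand_site()] written as HETATM residues
#'   named `LIG`.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(atoms, path, sites = list()) {
  n <- nrow(atoms$coords)
  meta <- atoms$meta
  if (is.null(meta)) {
    meta <- data.frame(resid = rep("GLY", n), resno = seq_len(n),
                       chain = rep("A", n),
                       elety = atoms$elements, stringsAsFactors = FALSE)
  }
  xyz <- as.vector(t(atoms$coords))
  fmt <- "HETATM%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  serial <- n
  het_lines <- character(0)
  if (length(sites) > 0L) {
    for (s in seq_along(sites)) {
      ac <- sites[[s]]$atom_coords
      for (a in seq_len(nrow(ac))) {
        serial <- serial + 1L
        het_lines <- c(het_lines, sprintf(
          fmt, serial %% 100000L, " C", "", "LIG", "L", (1000L + s) %% 10000L, "",
          ac[a, 1], ac[a, 2], ac[a, 3], 1, 0, "C"))
      }
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", n),
                   resno = meta$resno, resid = meta$resid, chain = meta$chain,
                   elety = meta$elety, elesy = atoms$elements)
  if (length(het_lines) > 0L) {
    txt <- readLines(path)
    end <- grep("^END", txt)
    if (length(end) == 0L) end <- length(txt) + 1L
    txt <- append(txt, het_lines, after = end[1] - 1L)
    writeLines(txt, path)
  }
  invisible(path)
}

#' Tabular dump of an atom set
#'
#' @param atoms An [atom_set()].
#' @return A data.frame with columns x, y, z, element, chem_index, is_protein
#'   (chem_index is `"other"` for atoms outside the alphabet).
#' @export
atom_table <- function(atoms) {
  data.frame(
    x = atoms$coords[, 1], y = atoms$coords[, 2], z = atoms$coords[, 3],
    element = atoms$elements,
    chem_index = ifelse(is.na(atoms$chem_index), "other", atoms$chem_index),
    is_protein = atoms$is_protein, stringsAsFactors = FALSE
  )
}
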