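## Structure data model: atom-site tables, complex models with chain roles,
## membrane slabs, and PDB I/O (via bio3d).

CONFORMATION_LEVELS <- c("E1P", "E2P", "OBN")
ISOFORM_LEVELS <- c("Ab42", "isoD7", "pS8")

#' Construct an atom-site table
#'
#' The package represents structures as plain data frames of heavy-atom sites
#' with author residue numbering preserved exactly. Columns: `serial`, `name`
#' (atom name), `element`, `resname` (3-letter code), `resid` (author residue
#' number), `chain` (single character), `x`, `y`, `z` (angstrom), `het`
#' (logical, HETATM record).
#'
#' @param serial integer atom serial numbers.
#' @param name atom names.
#' @param element element symbols (non-empty).
#' @param resname residue 3-letter codes.
#' @param resid author residue numbers (integer).
#' @param chain single-character chain identifiers.
#' @param x,y,z coordinates in angstrom (finite).
#' @param het logical, `TRUE` for HETATM records.
#' @return A `data.frame` of atom sites.
#' @export
atom_sites <- function(serial, name, element, resname, resid, chain,
                       x, y, z, het = FALSE) {
  df <- data.frame(serial = as.integer(serial), name = as.character(name),
                   element = as.character(element),
                   resname = as.character(resname), resid = as.integer(resid),
                   chain = as.character(chain),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   het = as.logical(het))
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stopf("atom coordinates must be finite")
  if (any(!nzchar(df$element)))
    stopf("element symbols must be non-empty")
  df
}

#' Construct a receptor-ligand complex model
#'
#' A complex model bundles one structure (receptor chains with declared
#' subunit roles, one ligand, optional explicit membrane atoms) with its
#' receptor-conformation and ligand-isoform tags. The ligand is either a
#' peptide chain (by chain id) or a small-molecule HETATM group (by residue
#' name).
#'
#' @param atoms atom-site `data.frame` (see [atom_sites()]).
#' @param receptor_chains named character vector mapping chain id to role,
#'   roles in `c("alpha_subunit", "beta_subunit")`.
#' @param ligand_chain chain id of a peptide ligand, or `NULL`.
#' @param ligand_resname HETATM residue name of a compound ligand, or `NULL`.
#'   Exactly one of `ligand_chain` / `ligand_resname` must be given.
#' @param membrane_resname residue name selecting explicit membrane atoms
#'   (kept out of the receptor/ligand sets), or `NULL` for none.
#' @param conformation receptor conformation tag (default vocabulary
#'   `"E1P"`, `"E2P"`, `"OBN"`; extend via `conformation_levels`).
#' @param isoform ligand isoform tag (default vocabulary `"Ab42"`,
#'   `"isoD7"`, `"pS8"`; extend via `isoform_levels`).
#' @param model_id identifier string for the model.
#' @param conformation_levels,isoform_levels allowed tag vocabularies.
#' @return An object of class `complex_model`.
#' @export
complex_model <- function(atoms, receptor_chains, ligand_chain = NULL,
                          ligand_resname = NULL, membrane_resname = NULL,
                          conformation = NA_character_, isoform = NA_character_,
                          model_id = "model",
                          conformation_levels = CONFORMATION_LEVELS,
                          isoform_levels = ISOFORM_LEVELS) {
  if (is.null(names(receptor_chains)) || any(!nzchar(names(receptor_chains))))
    stopf("receptor_chains must be a named vector: chain id -> role")
  bad <- setdiff(receptor_chains, c("alpha_subunit", "beta_subunit"))
  if (length(bad)) stopf("unknown receptor role(s): %s", paste(bad, collapse = ", "))
  if (length(receptor_chains) < 1L) stopf("at least one receptor chain is required")
  if (is.null(ligand_chain) == is.null(ligand_resname))
    stopf("give exactly one of ligand_chain or ligand_resname")
  if (!is.null(ligand_chain) && ligand_chain %in% names(receptor_chains))
    stopf("ligand chain '%s' is also declared as a receptor chain", ligand_chain)
  if (!is.na(conformation) && !conformation %in% conformation_levels)
    stopf("conformation '%s' not in declared vocabulary (%s)",
          conformation, paste(conformation_levels, collapse = ", "))
  if (!is.na(isoform) && !isoform %in% isoform_levels)
    stopf("isoform '%s' not in declared vocabulary (%s)",
          isoform, paste(isoform_levels, collapse = ", "))
  for (ch in names(receptor_chains))
    if (!any(atoms$chain == ch & !atoms$het))
      stopf("declared receptor chain '%s' has no atoms", ch)
  m <- structure(list(model_id = model_id, atoms = atoms,
                      receptor_chains = receptor_chains,
                      ligand_chain = ligand_chain,
                      ligand_resname = ligand_resname,
                      membrane_resname = membrane_resname,
                      conformation = conformation, isoform = isoform),
                 class = "complex_model")
  if (nrow(ligand_atoms(m)) == 0L) stopf("ligand has zero atoms")
  m
}

#' @export
print.complex_model <- function(x, ...) {
  lig <- if (!is.null(x$ligand_chain))
    sprintf("peptide chain %s (%d residues)", x$ligand_chain,
            length(unique(ligand_atoms(x)$resid)))
  else
    sprintf("compound %s (%d heavy atoms)", x$ligand_resname,
            nrow(ligand_atoms(x)))
  cat(sprintf("complex_model '%s': %d atoms\n", x$model_id, nrow(x$atoms)))
  cat("  receptor:", paste(sprintf("%s=%s", names(x$receptor_chains),
                                   x$receptor_chains), collapse = ", "), "\n")
  cat("  ligand:  ", lig, "\n")
  if (nrow(membrane_atoms(x)) > 0L)
    cat(sprintf("  membrane: %d explicit atoms (%s)\n",
                nrow(membrane_atoms(x)), x$membrane_resname))
  cat(sprintf("  tags:     conformation=%s isoform=%s\n",
              x$conformation, x$isoform))
  invisible(x)
}

#' Atom subsets of a complex model
#'
#' `receptor_atoms()` returns the heavy atoms of the declared receptor chains,
#' `ligand_atoms()` the ligand atoms (peptide chain or HETATM group), and
#' `membrane_atoms()` the explicit membrane atoms (possibly zero rows).
#' `receptor_residues()` lists the receptor residue keys (chain, resid) in
#' chain/numbering order.
#'
#' @param model a `complex_model`.
#' @return A `data.frame` of atom sites (or of `chain`/`resid` pairs for
#'   `receptor_residues()`).
#' @export
receptor_atoms <- function(model) {
  model$atoms[model$atoms$chain %in% names(model$receptor_chains) &
                !model$atoms$het, , drop = FALSE]
}

#' @rdname receptor_atoms
#' @export
ligand_atoms <- function(model) {
  if (!is.null(model$ligand_chain))
    model$atoms[model$atoms$chain == model$ligand_chain & !model$atoms$het, ,
                drop = FALSE]
  else
    model$atoms[model$atoms$het & model$atoms$resname == model$ligand_resname, ,
                drop = FALSE]
}

#' @rdname receptor_atoms
#' @export
membrane_atoms <- function(model) {
  if (is.null(model$membrane_resname))
    model$atoms[0L, , drop = FALSE]
  else
    model$atoms[model$atoms$resname == model$membrane_resname, , drop = FALSE]
}

#' @rdname receptor_atoms
#' @export
receptor_residues <- function(model) {
  ra <- receptor_atoms(model)
  key <- !duplicated(paste(ra$chain, ra$resid))
  out <- ra[key, c("chain", "resid")]
  out <- out[order(out$chain, out$resid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define a membrane slab
#'
#' The membrane is abstracted as a slab normal to the z axis, bounded by
#' `z_min < z_max` (angstrom). Poses and compounds are tested against the slab
#' rather than against explicit lipids, so pre-refined structures with the
#' bilayer stripped can still be screened.
#'
#' @param z_min,z_max slab bounds in angstrom.
#' @return An object of class `membrane_slab`.
#' @export
membrane_slab <- function(z_min, z_max) {
  z_min <- as.numeric(z_min); z_max <- as.numeric(z_max)
  if (!is.finite(z_min) || !is.finite(z_max) || z_min >= z_max)
    stopf("membrane slab requires finite z_min < z_max (got %s, %s)",
          format(z_min), format(z_max))
  structure(list(z_min = z_min, z_max = z_max, normal = "z"),
            class = "membrane_slab")
}

#' @export
print.membrane_slab <- function(x, ...) {
  cat(sprintf("membrane_slab: z in [%.2f, %.2f] A (normal z)\n",
              x$z_min, x$z_max))
  invisible(x)
}

#' Infer the membrane slab from explicit membrane atoms
#'
#' When the structure carries explicit membrane pseudo-atoms, the slab bounds
#' are taken as the min/max z of the atoms whose name matches `selector`
#' (a regular expression, e.g. `"^P"` for phosphate-layer atoms).
#'
#' @param model a `complex_model` with membrane atoms.
#' @param selector regular expression matched against membrane atom names.
#' @return A [membrane_slab()].
#' @export
infer_membrane_slab <- function(model, selector = ".") {
  mem <- membrane_atoms(model)
  sel <- mem[grepl(selector, mem$name), , drop = FALSE]
  if (nrow(sel) == 0L)
    stopf("membrane selector '%s' matched no atoms", selector)
  membrane_slab(min(sel$z), max(sel$z))
}

## ---- PDB I/O ----------------------------------------------------------

## Element fallback when the PDB element column is blank: first letter of the
## atom name after stripping digits (adequate for C/N/O/S/P heavy atoms).
guess_element <- function(name) {
  e <- sub("^[0-9]*", "", name)
  substr(e, 1L, 1L)
}

#' Read a (multi-model) PDB file as complex model(s)
#'
#' Parses a PDB file (through bio3d) into one `complex_model` per MODEL
#' record. Hydrogens are dropped; alternate locations are resolved to the
#' highest-occupancy conformer (ties: first encountered); author residue
#' numbering is preserved exactly. Files with insertion codes are rejected.
#'
#' @param path PDB file path.
#' @param receptor_chains named character vector, chain id -> role.
#' @param ligand_chain,ligand_resname ligand declaration as in
#'   [complex_model()].
#' @param membrane_resname residue name of explicit membrane atoms, or `NULL`.
#' @param conformation,isoform tags as in [complex_model()].
#' @param model_id base identifier; multi-model files get `_m<k>` suffixes.
#' @param ... passed on to [complex_model()] (e.g. extended tag vocabularies).
#' @return A `complex_model`, or a list of them for multi-MODEL files.
#' @export
read_complex_pdb <- function(path, receptor_chains, ligand_chain = NULL,
                             ligand_resname = NULL, membrane_resname = NULL,
                             conformation = NA_character_,
                             isoform = NA_character_,
                             model_id = NULL, ...) {
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stopf("insertion codes are not supported (file %s)", basename(path))
  keep <- rep(TRUE, nrow(at))
  ## hydrogens out
  ele <- at$elesy
  ele[is.na(ele) | !nzchar(ele)] <- guess_element(at$elety[is.na(ele) | !nzchar(ele)])
  keep[toupper(ele) %in% c("H", "D")] <- FALSE
  ## altloc: highest occupancy per (chain, resid, resname, atom name); tie ->
  ## first encountered
  alt <- !is.na(at$alt) & nzchar(at$alt)
  if (any(alt)) {
    grp <- paste(at$chain, at$resno, at$resid, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    for (g in unique(grp[alt])) {
      idx <- which(grp == g & keep)
      if (length(idx) > 1L) {
        best <- idx[which.max(occ[idx])]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
  }
  at <- at[keep, , drop = FALSE]
  ele <- ele[keep]
  ## bio3d xyz columns come in x,y,z triples per original atom row
  cols <- as.vector(rbind(3L * which(keep) - 2L, 3L * which(keep) - 1L,
                          3L * which(keep)))
  xyz <- pdb$xyz[, cols, drop = FALSE]
  n_models <- nrow(xyz)
  if (is.null(model_id))
    model_id <- tools::file_path_sans_ext(basename(path))
  present <- unique(at$chain[at$type == "ATOM"])
  for (ch in names(receptor_chains))
    if (!ch %in% present)
      stopf("declared chain '%s' not found in %s", ch, basename(path))
  if (!is.null(ligand_chain) && !ligand_chain %in% present)
    stopf("declared chain '%s' not found in %s", ligand_chain, basename(path))
  build <- function(k) {
    v <- xyz[k, ]
    atoms <- atom_sites(serial = at$eleno, name = at$elety, element = ele,
                        resname = at$resid, resid = at$resno,
                        chain = at$chain,
                        x = v[c(TRUE, FALSE, FALSE)],
                        y = v[c(FALSE, TRUE, FALSE)],
                        z = v[c(FALSE, FALSE, TRUE)],
                        het = at$type == "HETATM")
    id <- if (n_models > 1L) sprintf("%s_m%d", model_id, k) else model_id
    complex_model(atoms, receptor_chains, ligand_chain = ligand_chain,
                  ligand_resname = ligand_resname,
                  membrane_resname = membrane_resname,
                  conformation = conformation, isoform = isoform,
                  model_id = id, ...)
  }
  if (n_models == 1L) build(1L) else lapply(seq_len(n_models), build)
}

#' Write complex model(s) to a PDB file
#'
#' One model writes plain ATOM/HETATM records; a list writes a multi-MODEL
#' file (MODEL/ENDMDL blocks). Coordinates are written at PDB precision
#' (3 decimals); author residue numbering is preserved.
#'
#' @param models a `complex_model` or a list of them (same atom layout).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(models, path) {
  if (inherits(models, "complex_model")) models <- list(models)
  multi <- length(models) > 1L
  con <- file(path, "w"); close(con)  # truncate
  for (k in seq_along(models)) {
    a <- models[[k]]$atoms
    if (multi) cat(sprintf("MODEL     %4d\n", k), file = path, append = TRUE)
    bio3d::write.pdb(file = path, append = TRUE, end = FALSE,
                     xyz = as.vector(t(atom_xyz(a))),
                     type = ifelse(a$het, "HETATM", "ATOM"),
                     eleno = a$serial, elety = a$name, resid = a$resname,
                     chain = a$chain, resno = a$resid,
                     o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                     elesy = a$element)
    if (multi) cat("ENDMDL\n", file = path, append = TRUE)
  }
  cat("END   \n", file = path, append = TRUE)
  invisible(path)
}
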