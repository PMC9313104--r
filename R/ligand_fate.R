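## Post-refinement classification of small-molecule poses (interface-bound /
## cavity-entered / membrane-embedded / displaced) and compound triage
## across receptor conformations.

FATE_LEVELS <- c("membrane_embedded", "cavity_entered", "interface_bound",
                 "displaced")

#' Classify the fate of a refined compound pose
#'
#' During refinement a compound can leave its docked site. The classifier
#' assigns exactly one label with precedence membrane > cavity > interface >
#' displaced:
#' \describe{
#'   \item{membrane_embedded}{at least `membrane_fraction` of the ligand's
#'     heavy atoms lie inside the membrane slab;}
#'   \item{cavity_entered}{the ligand centroid sits within the cavity radius
#'     of the vertical cavity axis and below (toward the membrane) the
#'     C-alpha centroid of the interface segments;}
#'   \item{interface_bound}{the ligand contacts at least
#'     `min_interface_contacts` distinct interface residues at the contact
#'     cutoff;}
#'   \item{displaced}{none of the above.}
#' }
#'
#' @param model a `complex_model` with a compound (HETATM) ligand.
#' @param segments interface residue definition: an `interface_segments`
#'   table.
#' @param slab a [membrane_slab()].
#' @param cavity a `cavity_definition`.
#' @param cutoff contact cutoff in angstrom (default 5).
#' @param membrane_fraction atom fraction defining membrane embedding
#'   (default 0.5).
#' @param min_interface_contacts distinct interface residues required for
#'   interface binding (default 3).
#' @return list(fate, metrics) where `metrics` holds the membrane fraction,
#'   axis distance, centroid z offset and interface-contact count behind the
#'   call.
#' @export
classify_fate <- function(model, segments, slab, cavity, cutoff = 5.0,
                          membrane_fraction = 0.5, min_interface_contacts = 3L) {
  if (!is.null(model$ligand_chain))
    stopf("ligand is a peptide; use filter_ensemble() for peptide poses")
  la <- ligand_atoms(model)
  memf <- membrane_overlap(model, slab)
  cen <- centroid(la)
  axis_dist <- sqrt(sum((cen[1:2] - cavity$center[1:2])^2))
  ra <- receptor_atoms(model)
  ca <- ra[ra$name == "CA", , drop = FALSE]
  ikeys <- segment_residue_keys(segments)
  ica <- ca[paste(ca$chain, ca$resid, sep = ":") %in% ikeys, , drop = FALSE]
  iface_z <- if (nrow(ica)) mean(ica$z) else NA_real_
  contacts <- compute_contacts(model, cutoff)
  ckeys <- paste(contacts$receptor_chain, contacts$receptor_residue, sep = ":")
  n_iface <- length(unique(ckeys[ckeys %in% ikeys]))
  fate <- if (memf >= membrane_fraction) "membrane_embedded"
    else if (axis_dist <= cavity$radius && !is.na(iface_z) && cen[3] < iface_z)
      "cavity_entered"
    else if (n_iface >= min_interface_contacts) "interface_bound"
    else "displaced"
  list(fate = fate,
       metrics = list(membrane_fraction = memf, axis_distance = axis_dist,
                      centroid_z = unname(cen[3]), interface_z = iface_z,
                      n_interface_contacts = n_iface))
}

#' Build a compound record table
#'
#' One row per compound x conformation with the docking metadata and the
#' post-refinement fate. This is the input schema of [triage_compounds()]
#' and of the `triage` command-line stage.
#'
#' @param compound_id compound accession strings.
#' @param conformation receptor conformation tags.
#' @param docking_rank integer docking rank within the conformation.
#' @param docking_affinity docking affinity in kcal/mol (more negative =
#'   stronger).
#' @param fate fate labels (see [classify_fate()]).
#' @return A `data.frame` of class `compound_records`.
#' @export
compound_records <- function(compound_id, conformation, docking_rank,
                             docking_affinity, fate) {
  if (!all(fate %in% FATE_LEVELS))
    stopf("unknown fate label(s): %s",
          paste(setdiff(fate, FATE_LEVELS), collapse = ", "))
  structure(data.frame(compound_id = as.character(compound_id),
                       conformation = as.character(conformation),
                       docking_rank = as.integer(docking_rank),
                       docking_affinity = as.numeric(docking_affinity),
                       fate = as.character(fate)),
            class = c("compound_records", "data.frame"))
}

#' Triage screened compounds by their fates across conformations
#'
#' Eliminates any compound with at least one membrane-embedded or
#' cavity-entered fate (reason precedence: membrane, then cavity) and any
#' remaining compound bound to the interface in fewer than
#' `min_interface_conformations` conformations (reason
#' `insufficient_interface`). Survivors are ranked by the number of
#' conformations in which they stay interface-bound (descending), ties
#' broken by mean docking affinity (ascending, i.e. strongest first).
#'
#' @param records a `compound_records` table covering the same conformation
#'   set for every compound.
#' @param min_interface_conformations survivor floor (default 2).
#' @return An object of class `triage_table`: `survivors` and `eliminated`
#'   data frames plus the wide fate matrix `fates`.
#' @export
triage_compounds <- function(records, min_interface_conformations = 2L) {
  confs <- sort(unique(records$conformation))
  by_cmp <- split(records, records$compound_id)
  for (r in by_cmp)
    if (!identical(sort(r$conformation), confs))
      stopf("compound %s does not cover the conformation set %s",
            r$compound_id[1L], paste(confs, collapse = ","))
  stats <- do.call(rbind, lapply(by_cmp, function(r) {
    data.frame(compound_id = r$compound_id[1L],
               n_interface_bound = sum(r$fate == "interface_bound"),
               n_membrane = sum(r$fate == "membrane_embedded"),
               n_cavity = sum(r$fate == "cavity_entered"),
               mean_affinity = mean(r$docking_affinity))
  }))
  rownames(stats) <- NULL
  reason <- ifelse(stats$n_membrane > 0L, "membrane",
            ifelse(stats$n_cavity > 0L, "cavity",
            ifelse(stats$n_interface_bound < min_interface_conformations,
                   "insufficient_interface", NA_character_)))
  surv <- stats[is.na(reason), , drop = FALSE]
  surv <- surv[order(-surv$n_interface_bound, surv$mean_affinity,
                     surv$compound_id), , drop = FALSE]
  if (nrow(surv)) surv$rank <- seq_len(nrow(surv))
  elim <- stats[!is.na(reason), , drop = FALSE]
  elim$reason <- reason[!is.na(reason)]
  rownames(surv) <- rownames(elim) <- NULL
  fates <- stats::reshape(
    as.data.frame(records)[, c("compound_id", "conformation", "fate")],
    idvar = "compound_id", timevar = "conformation", direction = "wide")
  names(fates) <- sub("^fate\\.", "", names(fates))
  rownames(fates) <- NULL
  structure(list(survivors = surv, eliminated = elim, fates = fates,
                 conformations = confs),
            class = "triage_table")
}

#' @export
print.triage_table <- function(x, ...) {
  cat(sprintf("triage_table over conformations %s\n",
              paste(x$conformations, collapse = ", ")))
  cat(sprintf("  survivors (%d):\n", nrow(x$survivors)))
  for (i in seq_len(nrow(x$survivors)))
    cat(sprintf("    %d. %s  interface-bound in %d, mean affinity %.2f kcal/mol\n",
                x$survivors$rank[i], x$survivors$compound_id[i],
                x$survivors$n_interface_bound[i], x$survivors$mean_affinity[i]))
  cat(sprintf("  eliminated (%d): %s\n", nrow(x$eliminated),
              paste(sprintf("%s (%s)", x$eliminated$compound_id,
                            x$eliminated$reason), collapse = ", ")))
  invisible(x)
}

#' Export a color-coded fate report
#'
#' TSV always; optionally an HTML table with the conventional coloring:
#' green for interface-bound, yellow for cavity-entered, red for
#' membrane-embedded, grey for displaced.
#'
#' @param table a `triage_table`.
#' @param tsv_path output TSV path.
#' @param html_path optional output HTML path.
#' @return `tsv_path`, invisibly.
#' @export
fate_report <- function(table, tsv_path, html_path = NULL) {
  utils::write.table(table$fates, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(html_path)) {
    cols <- c(interface_bound = "#a6d96a", cavity_entered = "#ffffbf",
              membrane_embedded = "#d7191c", displaced = "#cccccc")
    f <- table$fates
    rows <- vapply(seq_len(nrow(f)), function(i) {
      cells <- vapply(names(f)[-1L], function(cn) {
        sprintf('<td style="background:%s">%s</td>', cols[[f[i, cn]]], f[i, cn])
      }, "")
      sprintf("<tr><td>%s</td>%s</tr>", f$compound_id[i],
              paste(cells, collapse = ""))
    }, "")
    html <- c("<table border='1'>",
              sprintf("<tr><th>compound</th>%s</tr>",
                      paste(sprintf("<th>%s</th>", names(f)[-1L]),
                            collapse = "")),
              rows, "</table>")
    writeLines(html, html_path)
  }
  invisible(tsv_path)
}

#' Worked triage example: ten screened compounds, three conformations
#'
#' A typed-in example reproducing a published virtual-screening triage of
#' ten NCI compounds docked against the E1P, E2P and ouabain-bound (OBN)
#' conformations of Na,K-ATPase, with the post-refinement fate of each of
#' the 30 complexes. Six complexes end in the membrane (one compound in all
#' three conformations, one in two, one in one), two compounds slide into
#' the pump cavity, one compound stays interface-bound in all three
#' conformations and two in two conformations.
#'
#' @return A `compound_records` table (30 rows).
#' @export
screening_triage_example <- function() {
  compounds <- c("NCI39918", "NCI610512", "NCI686480", "NCI39921", "NCI617551",
                 "NCI84171", "NCI298806", "NCI23128", "NCI688806", "NCI58783")
  rank <- list(E1P = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
               E2P = c(4, 7, 3, 1, 2, 5, 10, 8, 6, 9),
               OBN = c(3, 5, 4, 2, 7, 1, 9, 6, 8, 10))
  aff <- list(E1P = c(-9.4, -9.3, -9.1, -8.9, -8.9, -8.7, -8.7, -8.7, -8.7, -8.6),
              E2P = c(-8.0, -7.4, -8.2, -8.7, -8.3, -7.9, -5.6, -7.3, -7.6, -6.5),
              OBN = c(-8.6, -7.6, -8.1, -8.7, -7.4, -8.9, -6.7, -7.6, -7.4, -6.4))
  fate <- list(
    E1P = c("interface_bound", "membrane_embedded", "membrane_embedded",
            "interface_bound", "interface_bound", "interface_bound",
            "displaced", "interface_bound", "membrane_embedded",
            "interface_bound"),
    E2P = c("displaced", "displaced", "membrane_embedded", "interface_bound",
            "interface_bound", "interface_bound", "displaced", "displaced",
            "membrane_embedded", "interface_bound"),
    OBN = c("displaced", "cavity_entered", "membrane_embedded", "displaced",
            "interface_bound", "cavity_entered", "cavity_entered",
            "displaced", "displaced", "displaced"))
  do.call(rbind, lapply(names(rank), function(cf) {
    compound_records(compounds, cf, rank[[cf]], aff[[cf]], fate[[cf]])
  }))
}
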