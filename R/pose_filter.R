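## Accept/reject docked peptide poses against the membrane-embedded
## receptor: cavity localization, membrane avoidance, multipoint contact.

#' Define the inter-subunit cavity from target interface segments
#'
#' The binding cavity sits in the gap between the receptor subunits; its
#' reference point is the unweighted centroid of the C-alpha atoms of the
#' declared target segments, with a vertical (z) axis through it.
#'
#' @param model a `complex_model`.
#' @param target_segments an `interface_segments` table of the targeted
#'   interface ranges.
#' @param radius cavity radius in angstrom used by downstream cavity tests
#'   (default 12).
#' @return An object of class `cavity_definition`: `center` (3-vector),
#'   `radius`, `n_calpha`.
#' @export
cavity_center <- function(model, target_segments, radius = 12) {
  if (radius <= 0) stopf("cavity radius must be > 0")
  ra <- receptor_atoms(model)
  ca <- ra[ra$name == "CA", , drop = FALSE]
  picked <- lapply(seq_len(nrow(target_segments)), function(i) {
    sel <- ca$chain == target_segments$chain[i] &
      ca$resid >= target_segments$start[i] &
      ca$resid <= target_segments$end[i]
    if (!any(sel))
      stopf("target segment %s:%d-%d resolves to no C-alpha atoms",
            target_segments$chain[i], target_segments$start[i],
            target_segments$end[i])
    ca[sel, , drop = FALSE]
  })
  pts <- do.call(rbind, picked)
  if (nrow(pts) < 3L)
    stopf("target segments resolve to %d C-alpha atoms (need >= 3)", nrow(pts))
  structure(list(center = centroid(pts), radius = radius,
                 n_calpha = nrow(pts)),
            class = "cavity_definition")
}

#' @export
print.cavity_definition <- function(x, ...) {
  cat(sprintf("cavity_definition: center (%.2f, %.2f, %.2f) A, radius %.1f A (%d CA)\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$n_calpha))
  invisible(x)
}

#' Fraction of ligand heavy atoms inside the membrane slab
#'
#' @param model a `complex_model`.
#' @param slab a [membrane_slab()].
#' @return Fraction in \[0, 1\]. The membrane-avoidance criterion passes only
#'   when the fraction is exactly zero (any membrane-touching pose is
#'   discarded).
#' @export
membrane_overlap <- function(model, slab) {
  la <- ligand_atoms(model)
  mean(la$z >= slab$z_min & la$z <= slab$z_max)
}

#' Cavity-proximity test for a ligand pose
#'
#' A pose counts as cavity-localized when at least `min_fraction` of its
#' ligand residue centroids lie within `max_dist` of the cavity center
#' ("mainly positioned in or near the cavity"). The boundary is inclusive:
#' a fraction exactly at `min_fraction` passes.
#'
#' @param model a `complex_model`.
#' @param cavity a `cavity_definition`.
#' @param max_dist distance threshold in angstrom (default 15).
#' @param min_fraction required fraction of ligand residues (default 0.3).
#' @return list(pass, fraction).
#' @export
cavity_proximity <- function(model, cavity, max_dist = 15, min_fraction = 0.3) {
  if (max_dist <= 0) stopf("max_dist must be > 0")
  la <- ligand_atoms(model)
  units <- if (is.null(model$ligand_chain)) rep(1L, nrow(la)) else la$resid
  cen <- do.call(rbind, lapply(split(seq_len(nrow(la)), units),
                               function(i) centroid(la[i, , drop = FALSE])))
  d <- sqrt(rowSums(sweep(cen, 2L, cavity$center)^2))
  frac <- mean(d <= max_dist)
  list(pass = frac >= min_fraction, fraction = frac)
}

#' Multipoint-contact test
#'
#' Groups contacted receptor residues into sequence clusters: residues on the
#' same chain join one cluster when separated by fewer than `min_separation`
#' positions; clusters on different chains are always distinct. The test
#' passes when at least `min_sites` clusters exist, i.e. the ligand grips the
#' receptor at several well-separated points of its structure rather than at
#' a single patch.
#'
#' @param contacts a `contact_pairs` table.
#' @param min_sites minimum number of clusters (default 3).
#' @param min_separation minimum sequence separation between clusters in
#'   residues (default 20).
#' @return list(pass, n_clusters, clusters) where `clusters` is a data frame
#'   (chain, start, end).
#' @export
multipoint_contacts <- function(contacts, min_sites = 3L, min_separation = 20L) {
  if (min_sites < 2L) stopf("min_sites must be >= 2")
  if (min_separation < 1L) stopf("min_separation must be >= 1")
  res <- unique(data.frame(chain = contacts$receptor_chain,
                           resid = contacts$receptor_residue))
  if (nrow(res) == 0L)
    return(list(pass = FALSE, n_clusters = 0L,
                clusters = data.frame(chain = character(0),
                                      start = integer(0), end = integer(0))))
  cl <- do.call(rbind, lapply(split(res, res$chain), function(s) {
    runs <- merge_runs(s$resid, gap_tolerance = min_separation - 2L)
    runs$chain <- s$chain[1L]
    runs[, c("chain", "start", "end")]
  }))
  rownames(cl) <- NULL
  list(pass = nrow(cl) >= min_sites, n_clusters = nrow(cl), clusters = cl)
}

#' Filter an ensemble of docked poses
#'
#' Applies the three pose-acceptance criteria to every model: (1) cavity
#' localization, (2) no membrane overlap, (3) multipoint contact. Each
#' criterion can be toggled off for ablation; a pose passes when all enabled
#' criteria pass. Input order is preserved and a verdict is emitted for every
#' model.
#'
#' @param models list of `complex_model`s.
#' @param slab a [membrane_slab()].
#' @param cavity a `cavity_definition`.
#' @param cutoff contact cutoff for criterion 3 (default 5).
#' @param max_dist,min_fraction cavity-proximity parameters.
#' @param min_sites,min_separation multipoint parameters.
#' @param criteria character subset of
#'   `c("cavity_localized", "no_membrane_overlap", "multipoint")` to enforce.
#' @return list(verdicts = data.frame of class `filter_verdicts`,
#'   survivors = list of passing models).
#' @export
filter_ensemble <- function(models, slab, cavity, cutoff = 5.0,
                            max_dist = 15, min_fraction = 0.3,
                            min_sites = 3L, min_separation = 20L,
                            criteria = c("cavity_localized",
                                         "no_membrane_overlap", "multipoint")) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  rows <- lapply(models, function(m) {
    prox <- cavity_proximity(m, cavity, max_dist, min_fraction)
    memf <- membrane_overlap(m, slab)
    mp <- multipoint_contacts(compute_contacts(m, cutoff),
                              min_sites, min_separation)
    data.frame(model_id = m$model_id,
               cavity_localized = prox$pass,
               no_membrane_overlap = memf == 0,
               multipoint = mp$pass,
               cavity_fraction = prox$fraction,
               membrane_fraction = memf,
               n_contact_clusters = mp$n_clusters)
  })
  v <- if (length(rows)) do.call(rbind, rows)
       else data.frame(model_id = character(0), cavity_localized = logical(0),
                       no_membrane_overlap = logical(0), multipoint = logical(0),
                       cavity_fraction = numeric(0),
                       membrane_fraction = numeric(0),
                       n_contact_clusters = integer(0))
  enabled <- as.matrix(v[, criteria, drop = FALSE])
  v$passed <- if (nrow(v)) apply(enabled, 1L, all) else logical(0)
  class(v) <- c("filter_verdicts", "data.frame")
  list(verdicts = v, survivors = models[v$passed])
}

#' @export
print.filter_verdicts <- function(x, ...) {
  cat(sprintf("filter_verdicts: %d poses, %d passed\n", nrow(x), sum(x$passed)))
  cat(sprintf("  failed cavity localization: %d\n", sum(!x$cavity_localized)))
  cat(sprintf("  failed membrane avoidance:  %d\n", sum(!x$no_membrane_overlap)))
  cat(sprintf("  failed multipoint contact:  %d\n", sum(!x$multipoint)))
  invisible(x)
}

#' Export filter verdicts
#'
#' @param verdicts a `filter_verdicts` data frame.
#' @param path output path (`.tsv` or `.json` chosen by extension).
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(verdicts, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(as.data.frame(verdicts), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  else
    utils::write.table(as.data.frame(verdicts), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
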