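## Intermolecular contact detection, per-residue profiles, ensemble
## aggregation, complex scoring and interface-segment calling.

#' Detect receptor-ligand contacts in a complex
#'
#' A receptor residue and a ligand unit are in contact when their minimum
#' heavy-atom distance is at or below `cutoff`. For a peptide ligand the
#' units are its residues; for a small-molecule ligand the whole compound is
#' one unit by default (`by = "residue"`), or each ligand atom separately
#' (`by = "atom"`). Residue-residue counting is the default because docking
#' and refinement outputs differ in how reliably they place individual
#' side-chain atoms.
#'
#' @param model a `complex_model`.
#' @param cutoff contact distance cutoff in angstrom (default 5.0, a standard
#'   heavy-atom interface definition).
#' @param by `"residue"` (ligand residues / whole compound) or `"atom"`
#'   (individual ligand atoms as units).
#' @return A `data.frame` of class `contact_pairs` with columns
#'   `receptor_chain`, `receptor_residue`, `ligand_unit`, `min_distance`.
#' @export
compute_contacts <- function(model, cutoff = 5.0, by = c("residue", "atom")) {
  by <- match.arg(by)
  if (!is.numeric(cutoff) || cutoff <= 0) stopf("cutoff must be > 0")
  ra <- receptor_atoms(model)
  la <- ligand_atoms(model)
  empty <- data.frame(receptor_chain = character(0),
                      receptor_residue = integer(0),
                      ligand_unit = integer(0),
                      min_distance = numeric(0))
  out <- empty
  if (nrow(ra) > 0L && nrow(la) > 0L) {
    d <- cross_dist(atom_xyz(ra), atom_xyz(la))
    rgrp <- paste(ra$chain, ra$resid)
    lgrp <- if (by == "atom") la$serial
            else if (is.null(model$ligand_chain)) rep(1L, nrow(la))
            else la$resid
    ## min distance per (receptor residue, ligand unit) cell
    rf <- factor(rgrp, levels = unique(rgrp))
    lf <- factor(lgrp, levels = unique(lgrp))
    mins <- tapply(as.vector(d),
                   list(rf[row(d)[seq_along(d)]], lf[col(d)[seq_along(d)]]),
                   min)
    hit <- which(mins <= cutoff, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      rkeys <- rownames(mins)[hit[, 1L]]
      parts <- strsplit(rkeys, " ", fixed = TRUE)
      out <- data.frame(
        receptor_chain = vapply(parts, `[[`, "", 1L),
        receptor_residue = as.integer(vapply(parts, `[[`, "", 2L)),
        ligand_unit = as.integer(colnames(mins)[hit[, 2L]]),
        min_distance = mins[hit])
      out <- out[order(out$receptor_chain, out$receptor_residue,
                       out$ligand_unit), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  structure(out, class = c("contact_pairs", "data.frame"),
            cutoff = cutoff, by = by, model_id = model$model_id)
}

#' Per-residue contact profile of one or more contact lists
#'
#' Counts, for every receptor residue, either the number of distinct ligand
#' units it contacts (`mode = "pair_count"`) or whether it is contacted at
#' all (`mode = "binary"`). Supplying `model` fixes the residue universe so
#' uncontacted residues appear with count zero.
#'
#' @param contacts a `contact_pairs` table from [compute_contacts()].
#' @param model optional `complex_model` supplying the receptor residue
#'   universe; if `NULL`, only contacted residues appear.
#' @param mode `"pair_count"` or `"binary"`.
#' @return A `data.frame` of class `contact_profile` with columns `chain`,
#'   `resid`, `count`; attributes `n_models` (= 1) and `mode`.
#' @export
residue_profile <- function(contacts, model = NULL,
                            mode = c("pair_count", "binary")) {
  mode <- match.arg(mode)
  universe <- if (!is.null(model)) receptor_residues(model)
              else unique(data.frame(chain = contacts$receptor_chain,
                                     resid = contacts$receptor_residue))
  universe <- universe[order(universe$chain, universe$resid), , drop = FALSE]
  key <- paste(universe$chain, universe$resid)
  cnt <- integer(length(key))
  if (nrow(contacts) > 0L) {
    ckey <- paste(contacts$receptor_chain, contacts$receptor_residue)
    tab <- table(ckey)
    idx <- match(names(tab), key)
    if (anyNA(idx))
      stopf("contacts reference receptor residues absent from the model")
    cnt[idx] <- as.integer(tab)
    if (mode == "binary") cnt <- pmin(cnt, 1L)
  }
  structure(data.frame(chain = universe$chain, resid = universe$resid,
                       count = cnt, row.names = NULL),
            class = c("contact_profile", "data.frame"),
            n_models = 1L, mode = mode)
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf("contact_profile: %d residues over %d model(s), mode=%s; ",
              nrow(x), attr(x, "n_models"), attr(x, "mode")))
  cat(sprintf("max count %d at %s:%d\n", max(x$count),
              x$chain[which.max(x$count)], x$resid[which.max(x$count)]))
  invisible(x)
}

#' Aggregate contact profiles across an ensemble
#'
#' Element-wise sum of per-model profiles over the same receptor; the
#' ensemble size `n_models` accumulates. This is how per-conformation (or
#' cross-isoform) contact maps are built from individual complexes.
#'
#' @param profiles list of `contact_profile`s over identical residue sets.
#' @return A `contact_profile` with summed counts.
#' @export
aggregate_profiles <- function(profiles) {
  if (length(profiles) == 0L) stopf("no profiles to aggregate")
  ref <- profiles[[1L]]
  key0 <- paste(ref$chain, ref$resid)
  cnt <- ref$count
  modes <- attr(ref, "mode")
  n <- attr(ref, "n_models") %||% 1L
  for (p in profiles[-1L]) {
    if (!identical(paste(p$chain, p$resid), key0))
      stopf("profiles cover different receptor residue sets")
    cnt <- cnt + p$count
    n <- n + (attr(p, "n_models") %||% 1L)
    modes <- c(modes, attr(p, "mode"))
  }
  structure(data.frame(chain = ref$chain, resid = ref$resid, count = cnt,
                       row.names = NULL),
            class = c("contact_profile", "data.frame"),
            n_models = n, mode = unique(modes)[1L])
}

#' Call interface segments from an aggregated contact profile
#'
#' Residues whose count reaches `max(2, threshold_fraction * max(count))`
#' seed segments; seeds on the same chain separated by at most
#' `gap_tolerance` non-seed residues are merged into one inclusive range;
#' ranges shorter than `min_length` residues are dropped. The relative
#' threshold with an absolute floor copes with ensembles whose peak heights
#' differ between receptor conformations.
#'
#' @param profile a `contact_profile` (typically aggregated).
#' @param threshold_fraction seed threshold as a fraction of the profile
#'   maximum, in (0, 1] (default 0.25).
#' @param gap_tolerance maximum run of non-seed residues bridged when merging
#'   (default 2).
#' @param min_length minimum segment length in residues (default 3).
#' @return A `data.frame` of class `interface_segments` with columns `chain`,
#'   `start`, `end`, `peak_count`, sorted by chain then start.
#' @export
detect_segments <- function(profile, threshold_fraction = 0.25,
                            gap_tolerance = 2L, min_length = 3L) {
  if (!(threshold_fraction > 0 && threshold_fraction <= 1))
    stopf("threshold_fraction must be in (0, 1]")
  if (gap_tolerance < 0L) stopf("gap_tolerance must be >= 0")
  if (min_length < 1L) stopf("min_length must be >= 1")
  empty <- structure(data.frame(chain = character(0), start = integer(0),
                                end = integer(0), peak_count = integer(0)),
                     class = c("interface_segments", "data.frame"))
  if (nrow(profile) == 0L || max(profile$count) == 0L) return(empty)
  thr <- max(2, threshold_fraction * max(profile$count))
  seeds <- profile[profile$count >= thr, , drop = FALSE]
  if (nrow(seeds) == 0L) return(empty)
  out <- do.call(rbind, lapply(split(seeds, seeds$chain), function(s) {
    runs <- merge_runs(s$resid, gap_tolerance)
    if (nrow(runs) == 0L) return(NULL)
    runs$chain <- s$chain[1L]
    runs$peak_count <- vapply(seq_len(nrow(runs)), function(i) {
      sel <- profile$chain == s$chain[1L] & profile$resid >= runs$start[i] &
        profile$resid <= runs$end[i]
      as.integer(max(profile$count[sel]))
    }, 0L)
    runs
  }))
  out <- out[out$end - out$start + 1L >= min_length,
             c("chain", "start", "end", "peak_count"), drop = FALSE]
  out <- out[order(out$chain, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("interface_segments", "data.frame"),
            threshold = thr)
}

#' Construct an interface segment table directly
#'
#' Convenience constructor for segment tables typed in from published range
#' lists or external tools, in author numbering with inclusive bounds.
#'
#' @param chain chain ids.
#' @param start,end inclusive residue bounds (`start <= end`).
#' @param peak_count optional peak contact count per segment.
#' @return An `interface_segments` data frame.
#' @export
interface_segments <- function(chain, start, end, peak_count = NA_integer_) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stopf("segment start must be <= end")
  df <- data.frame(chain = as.character(chain), start = start, end = end,
                   peak_count = rep_len(as.integer(peak_count), length(start)))
  df <- df[order(df$chain, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("interface_segments", "data.frame"))
}

#' Score a complex by its contact footprint
#'
#' A transparent surrogate scoring function used to rate complexes from the
#' contact analysis: the number of distinct receptor residues contacted plus
#' 0.1 times the total number of contact pairs. Larger interfaces with more
#' redundant contacts score higher; the score is deterministic given the
#' model and the contact cutoff.
#'
#' @param model a `complex_model`.
#' @param contacts its `contact_pairs` table (computed if omitted).
#' @param cutoff contact cutoff used when `contacts` is omitted.
#' @return A one-row `data.frame` of class `complex_score`: `model_id`,
#'   `total_contacts`, `n_interface_residues`, `score`.
#' @export
score_complex <- function(model, contacts = NULL, cutoff = 5.0) {
  if (is.null(contacts)) contacts <- compute_contacts(model, cutoff)
  n_res <- nrow(unique(data.frame(contacts$receptor_chain,
                                  contacts$receptor_residue)))
  structure(data.frame(model_id = model$model_id,
                       total_contacts = nrow(contacts),
                       n_interface_residues = n_res,
                       score = n_res + 0.1 * nrow(contacts)),
            class = c("complex_score", "data.frame"))
}

#' Rank scored complexes and keep the top k
#'
#' Descending by score; ties broken by model id (lexicographic) so the
#' ranking is stable and reproducible.
#'
#' @param scores a `data.frame` of [score_complex()] rows (rbind-ed).
#' @param k how many to keep (default 5; truncated to the table size).
#' @return The top-`k` rows, re-ranked, with a `rank` column.
#' @export
rank_complexes <- function(scores, k = 5L) {
  if (k < 1L) stopf("k must be >= 1")
  ord <- order(-scores$score, scores$model_id)
  out <- scores[ord[seq_len(min(k, nrow(scores)))], , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Export profiles and segments as TSV
#'
#' Plot-ready long tables: profiles as (chain, resid, count), segments as
#' (chain, start, end, peak_count).
#'
#' @param x a `contact_profile` or `interface_segments`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
write_segments_tsv <- write_profile_tsv
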