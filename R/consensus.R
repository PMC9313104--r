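## Cross-conformation interface comparison: consensus segments, Jaccard
## similarity, docking-vs-refined narrowing, peptide orientation statistics
## and annotation of excluded regions.

#' Bundle one conformation's interface call
#'
#' @param conformation conformation tag (e.g. `"E1P"`).
#' @param stage `"docking"` or `"refined"` (post-MD).
#' @param segments an `interface_segments` table; segments must not overlap
#'   within a chain.
#' @param profile optional source `contact_profile`.
#' @return An object of class `conformation_interface`.
#' @export
conformation_interface <- function(conformation, stage = c("docking", "refined"),
                                   segments, profile = NULL) {
  stage <- match.arg(stage)
  for (s in split(segments, segments$chain)) {
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)]))
      stopf("overlapping segments on chain %s", s$chain[1L])
  }
  structure(list(conformation = conformation, stage = stage,
                 segments = segments, profile = profile),
            class = "conformation_interface")
}

jaccard_keys <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Consensus of interfaces across receptor conformations
#'
#' Intersects the residue sets of two or more conformation interfaces,
#' re-segments the intersection with the same merge rule used for segment
#' calling, and reports pairwise Jaccard similarity of the residue sets.
#' The union is reported as well: a universal interface blocker must cover
#' every conformation's sites, so both the strict core and the full extent
#' are of interest.
#'
#' @param interfaces list of `conformation_interface`s (>= 2, same receptor
#'   numbering and stage).
#' @param gap_tolerance,min_length segment re-merge parameters (defaults as
#'   in [detect_segments()]).
#' @return An object of class `consensus_report`: `per_conformation` (named
#'   residue-key sets), `intersection_segments`, `union_segments`,
#'   `intersection_keys`, `jaccard` (data frame of pairs),
#'   `excluded_regions` (empty; see [annotate_excluded()]).
#' @export
interface_consensus <- function(interfaces, gap_tolerance = 2L, min_length = 3L) {
  if (length(interfaces) < 2L) stopf("need >= 2 conformation interfaces")
  tags <- vapply(interfaces, function(x) x$conformation, "")
  if (anyDuplicated(tags)) stopf("duplicate conformation tags")
  keys <- lapply(interfaces, function(x) segment_residue_keys(x$segments))
  names(keys) <- tags
  inter <- Reduce(intersect, keys)
  uni <- Reduce(union, keys)
  pairs <- utils::combn(seq_along(tags), 2L)
  jac <- data.frame(a = tags[pairs[1L, ]], b = tags[pairs[2L, ]],
                    jaccard = apply(pairs, 2L, function(p)
                      jaccard_keys(keys[[p[1L]]], keys[[p[2L]]])))
  structure(list(per_conformation = keys,
                 intersection_keys = sort(inter),
                 intersection_segments =
                   keys_to_segments(inter, gap_tolerance, min_length),
                 union_segments = keys_to_segments(uni, gap_tolerance = 0L,
                                                   min_length = 1L),
                 jaccard = jac,
                 excluded_regions = NULL),
            class = "consensus_report")
}

## residue keys -> merged segment table
keys_to_segments <- function(keys, gap_tolerance = 2L, min_length = 3L) {
  df <- split_residue_keys(keys)
  if (nrow(df) == 0L)
    return(interface_segments(character(0), integer(0), integer(0)))
  out <- do.call(rbind, lapply(split(df, df$chain), function(s) {
    runs <- merge_runs(s$resid, gap_tolerance)
    runs$chain <- s$chain[1L]
    runs
  }))
  out <- out[out$end - out$start + 1L >= min_length, , drop = FALSE]
  interface_segments(out$chain, out$start, out$end)
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("consensus_report over %d conformations (%s)\n",
              length(x$per_conformation),
              paste(names(x$per_conformation), collapse = ", ")))
  cat(sprintf("  intersection: %d residues in %d segment(s)\n",
              length(x$intersection_keys), nrow(x$intersection_segments)))
  cat(sprintf("  pairwise Jaccard: %s\n",
              paste(sprintf("%s-%s %.2f", x$jaccard$a, x$jaccard$b,
                            x$jaccard$jaccard), collapse = ", ")))
  if (!is.null(x$excluded_regions) && nrow(x$excluded_regions) > 0L)
    cat(sprintf("  excluded regions: %d\n", nrow(x$excluded_regions)))
  invisible(x)
}

#' Interface narrowing from docking to refinement
#'
#' Refinement typically sharpens docking interfaces: contact peaks narrow.
#' Matches refined segments to docking segments by maximal residue overlap
#' and reports per-segment widths plus the total-width ratio
#' (refined / docking).
#'
#' @param docking,refined `conformation_interface`s of the two stages.
#' @return list(segment_changes data frame, total_ratio).
#' @export
narrowing_metric <- function(docking, refined) {
  dk <- segment_residue_keys(docking$segments)
  rk <- segment_residue_keys(refined$segments)
  ds <- docking$segments
  changes <- do.call(rbind, lapply(seq_len(nrow(ds)), function(i) {
    seg_keys <- paste(ds$chain[i], seq(ds$start[i], ds$end[i]), sep = ":")
    ov <- vapply(seq_len(nrow(refined$segments)), function(j) {
      rs <- refined$segments[j, ]
      if (rs$chain != ds$chain[i]) return(0L)
      length(intersect(seg_keys,
                       paste(rs$chain, seq(rs$start, rs$end), sep = ":")))
    }, 0L)
    j <- if (length(ov) && max(ov) > 0L) which.max(ov) else NA_integer_
    data.frame(chain = ds$chain[i], docking_start = ds$start[i],
               docking_end = ds$end[i],
               docking_width = ds$end[i] - ds$start[i] + 1L,
               refined_start = if (is.na(j)) NA_integer_ else refined$segments$start[j],
               refined_end = if (is.na(j)) NA_integer_ else refined$segments$end[j],
               refined_width = if (is.na(j)) 0L
                               else refined$segments$end[j] - refined$segments$start[j] + 1L)
  }))
  list(segment_changes = changes,
       total_ratio = length(rk) / length(dk))
}

#' Classify the orientation of a docked peptide in the cavity
#'
#' Compares the distance of the N-terminal-window centroid and the
#' C-terminal-window centroid (heavy atoms of the first/last `window`
#' residues) to the cavity center. The terminus whose window sits closer is
#' called "inside"; differences under `ambiguity` angstrom are ambiguous.
#'
#' @param model a `complex_model` with a peptide ligand.
#' @param cavity a `cavity_definition`.
#' @param window terminal window size in residues (default 5).
#' @param ambiguity tie band in angstrom (default 2).
#' @return `"C_in"`, `"N_in"` or `"ambiguous"`.
#' @export
peptide_orientation <- function(model, cavity, window = 5L, ambiguity = 2) {
  if (is.null(model$ligand_chain))
    stopf("ligand is not a peptide; orientation is undefined for compounds")
  la <- ligand_atoms(model)
  resids <- sort(unique(la$resid))
  if (length(resids) < 2L * window)
    stopf("peptide has %d residues; need >= %d for window %d",
          length(resids), 2L * window, window)
  n_set <- resids[seq_len(window)]
  c_set <- resids[seq(length(resids) - window + 1L, length(resids))]
  dN <- sqrt(sum((centroid(la[la$resid %in% n_set, ]) - cavity$center)^2))
  dC <- sqrt(sum((centroid(la[la$resid %in% c_set, ]) - cavity$center)^2))
  if (abs(dN - dC) < ambiguity) "ambiguous" else if (dC < dN) "C_in" else "N_in"
}

#' Orientation statistics over an ensemble
#'
#' @param models list of peptide `complex_model`s.
#' @param cavity a `cavity_definition`.
#' @param ... passed to [peptide_orientation()].
#' @return An object of class `orientation_stats`: counts `n_C_in`,
#'   `n_N_in`, `n_ambiguous` (summing to the ensemble size).
#' @export
orientation_stats <- function(models, cavity, ...) {
  calls <- vapply(models, peptide_orientation, "", cavity = cavity, ...)
  structure(list(n_C_in = sum(calls == "C_in"),
                 n_N_in = sum(calls == "N_in"),
                 n_ambiguous = sum(calls == "ambiguous"),
                 calls = calls),
            class = "orientation_stats")
}

#' @export
print.orientation_stats <- function(x, ...) {
  cat(sprintf("orientation_stats: %d C-terminus-in, %d N-terminus-in, %d ambiguous (n = %d)\n",
              x$n_C_in, x$n_N_in, x$n_ambiguous, length(x$calls)))
  invisible(x)
}

#' Remove excluded regions from an interface, keeping them annotated
#'
#' Regions far from the targeted cavity (e.g. a large peripheral interaction
#' area on the beta-subunit) are excluded from downstream target-site
#' definitions but retained in the report with a reason.
#'
#' @param segments an `interface_segments` table.
#' @param exclusions an `interface_segments` table of regions to remove.
#' @param reason reason text recorded for the excluded regions.
#' @return list(kept = `interface_segments` after set difference,
#'   excluded = data frame of exclusion ranges with `reason`).
#' @export
annotate_excluded <- function(segments, exclusions,
                              reason = "far from targeted cavity") {
  keys <- segment_residue_keys(segments)
  exk <- segment_residue_keys(exclusions)
  kept <- keys_to_segments(setdiff(keys, exk), gap_tolerance = 0L,
                           min_length = 1L)
  excluded <- as.data.frame(exclusions)[, c("chain", "start", "end")]
  if (nrow(excluded)) excluded$reason <- reason
  list(kept = kept, excluded = excluded)
}

#' Export a consensus report
#'
#' JSON report of per-conformation residue sets, intersection/union segments
#' and pairwise Jaccard indices; optionally a BED-like TSV of the
#' intersection segments (chain, start-1, end; 0-based half-open in that
#' export only).
#'
#' @param report a `consensus_report`.
#' @param path output JSON path.
#' @param bed_path optional BED-like TSV path.
#' @return `path`, invisibly.
#' @export
write_consensus_report <- function(report, path, bed_path = NULL) {
  jsonlite::write_json(
    list(conformations = names(report$per_conformation),
         per_conformation = report$per_conformation,
         intersection_residues = report$intersection_keys,
         intersection_segments = as.data.frame(report$intersection_segments),
         union_segments = as.data.frame(report$union_segments),
         jaccard = report$jaccard,
         excluded_regions = report$excluded_regions),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bed_path)) {
    seg <- as.data.frame(report$intersection_segments)
    utils::write.table(data.frame(chain = seg$chain, start = seg$start - 1L,
                                  end = seg$end),
                       bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
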