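## Internal helpers shared across modules.

## Squared-distance-free cross distance matrix between two coordinate
## matrices (rows = points, cols = x,y,z). Clamps tiny negatives from
## floating cancellation before sqrt.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

## Coordinate matrix from an atom-site data frame.
atom_xyz <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

centroid <- function(atoms) {
  if (is.matrix(atoms)) colMeans(atoms) else colMeans(atom_xyz(atoms))
}

## Expand an interface segment table (chain, start, end) to a per-residue
## key vector "chain:resid", used for set arithmetic across conformations.
segment_residue_keys <- function(segments) {
  if (nrow(segments) == 0L) return(character(0))
  unlist(lapply(seq_len(nrow(segments)), function(i) {
    paste(segments$chain[i], seq(segments$start[i], segments$end[i]), sep = ":")
  }), use.names = FALSE)
}

split_residue_keys <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(chain = character(0), resid = integer(0)))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(chain = vapply(parts, `[[`, "", 1L),
             resid = as.integer(vapply(parts, `[[`, "", 2L)))
}

## Merge a sorted integer residue vector (one chain) into inclusive runs,
## bridging gaps of at most `gap_tolerance` missing residues.
merge_runs <- function(resids, gap_tolerance = 0L) {
  if (length(resids) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  resids <- sort(unique(as.integer(resids)))
  brk <- which(diff(resids) > gap_tolerance + 1L)
  starts <- resids[c(1L, brk + 1L)]
  ends <- resids[c(brk, length(resids))]
  data.frame(start = starts, end = ends)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
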