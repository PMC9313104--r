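## Deterministic synthetic-structure generator. Builds toy two-subunit
## receptors with a cavity between the chains above a membrane slab, plants
## peptide poses of prescribed acceptance classes and compound poses of
## prescribed fates, and writes full fixture ensembles (multi-model PDBs,
## metadata TSV, ground-truth JSON). Everything is reproducible from a seed;
## the receptor geometry itself uses no randomness at all.
##
## Residues are a C-alpha plus one side-chain pseudo-atom: enough for
## distance-based contact analysis without rotamer modeling. The generator
## emulates the docking/MD outputs of a membrane pump-peptide system; it
## makes no claim of physical realism (no torsions, no energies).

#' Build a synthetic two-subunit receptor skeleton
#'
#' Two pseudo-helical chains (A = alpha-subunit, B = beta-subunit) flank a
#' cavity on the extracellular (+z) side of a membrane slab. The declared
#' interface segments are "planted": their residues are rearranged into an
#' arc facing the cavity so that correctly placed ligands contact them. The
#' returned skeleton records the ground truth (planted segments, slab,
#' cavity center, anchor coordinates) used by the pose planters and by
#' tests.
#'
#' @param n_alpha,n_beta residues per chain (>= 30 each).
#' @param planted `interface_segments` table of planted interface ranges
#'   (default: three alpha-subunit segments 20-25, 45-49, 70-80 and one
#'   beta-subunit segment 15-19, mimicking a multi-site interface whose
#'   sites are >= 20 residues apart in sequence).
#' @param slab numeric `c(z_min, z_max)` membrane bounds (default
#'   `c(-30, -2)`).
#' @param with_membrane add explicit membrane pseudo-atoms (resname `MEM`,
#'   atom name `P`) at the two slab faces.
#' @return An object of class `receptor_skeleton`.
#' @export
make_receptor <- function(n_alpha = 90L, n_beta = 50L,
                          planted = interface_segments(
                            chain = c("A", "A", "A", "B"),
                            start = c(20L, 45L, 70L, 15L),
                            end = c(25L, 49L, 80L, 19L)),
                          slab = c(-30, -2), with_membrane = TRUE) {
  if (n_alpha < 30L || n_beta < 30L) stopf("chains need >= 30 residues")
  center0 <- c(0, 0, 10)
  band_radius <- 9
  build_chain <- function(chain, n, x0) {
    i <- seq_len(n)
    data.frame(chain = chain, resid = i,
               x = x0 + 2 * cos(0.6 * i) * sign(x0),
               y = 2 * sin(0.6 * i),
               z = -28 + 0.8 * (i - 1))
  }
  ca <- rbind(build_chain("A", n_alpha, -26), build_chain("B", n_beta, 26))
  ## rearrange planted residues onto cavity-facing bands: each segment sits
  ## on its own horizontal circle (radius `band_radius` around the cavity
  ## axis, one z level per segment) with uniform ~2.2 A spacing, so contact
  ## counts are near-uniform along a segment and distinct segments are
  ## spatially well separated
  pk <- split_residue_keys(segment_residue_keys(planted))
  step_deg <- 2 * asin(1.1 / band_radius) * 180 / pi   # 2.2 A chord
  for (ch in unique(pk$chain)) {
    segs <- planted[planted$chain == ch, , drop = FALSE]
    z_levels <- if (nrow(segs) == 1L) 10
                else seq(2, 18, length.out = nrow(segs))
    for (si in seq_len(nrow(segs))) {
      res <- seq(segs$start[si], segs$end[si])
      span <- step_deg * (length(res) - 1L)
      a0 <- if (ch == "A") 100 else -span / 2           # A on -x, B on +x side
      ang <- a0 + step_deg * (seq_along(res) - 1L)
      idx <- match(paste(ch, res), paste(ca$chain, ca$resid))
      ca$x[idx] <- center0[1] + band_radius * cos(ang * pi / 180)
      ca$y[idx] <- center0[2] + band_radius * sin(ang * pi / 180)
      ca$z[idx] <- z_levels[si]
    }
  }
  ## side-chain pseudo-atom: radially outward (away from the cavity axis for
  ## planted residues, away from the chain axis otherwise)
  planted_key <- paste(pk$chain, pk$resid)
  is_planted <- paste(ca$chain, ca$resid) %in% planted_key
  ux <- ifelse(is_planted, ca$x - center0[1], ifelse(ca$chain == "A", -1, 1))
  uy <- ifelse(is_planted, ca$y - center0[2], 0)
  nrm <- sqrt(ux^2 + uy^2); nrm[nrm == 0] <- 1
  cb <- ca
  cb$x <- ca$x + 1.5 * ux / nrm
  cb$y <- ca$y + 1.5 * uy / nrm
  atoms <- rbind(
    data.frame(ca, name = "CA", stringsAsFactors = FALSE),
    data.frame(cb, name = "CB", stringsAsFactors = FALSE))
  atoms <- atoms[order(atoms$chain, atoms$resid, atoms$name), , drop = FALSE]
  df <- atom_sites(serial = seq_len(nrow(atoms)), name = atoms$name,
                   element = "C", resname = "ALA", resid = atoms$resid,
                   chain = atoms$chain, x = atoms$x, y = atoms$y,
                   z = atoms$z, het = FALSE)
  if (with_membrane) {
    g <- expand.grid(x = seq(-20, 20, by = 10), y = seq(-20, 20, by = 10),
                     z = slab)
    mem <- atom_sites(serial = nrow(df) + seq_len(nrow(g)), name = "P",
                      element = "P", resname = "MEM",
                      resid = seq_len(nrow(g)), chain = "M",
                      x = g$x, y = g$y, z = g$z, het = TRUE)
    df <- rbind(df, mem)
  }
  ca_df <- df[df$name == "CA", , drop = FALSE]
  anchors <- ca_df[match(planted_key, paste(ca_df$chain, ca_df$resid)), ,
                   drop = FALSE]
  structure(list(atoms = df,
                 receptor_chains = c(A = "alpha_subunit", B = "beta_subunit"),
                 membrane_resname = if (with_membrane) "MEM" else NULL,
                 planted = planted,
                 slab = membrane_slab(slab[1], slab[2]),
                 cavity_center = centroid(anchors),
                 axis = center0,
                 anchors = anchors),
            class = "receptor_skeleton")
}

#' @export
print.receptor_skeleton <- function(x, ...) {
  cat(sprintf("receptor_skeleton: %d atoms, %d planted interface residues\n",
              nrow(x$atoms), nrow(x$anchors)))
  cat(sprintf("  cavity center (%.2f, %.2f, %.2f); slab [%.1f, %.1f]\n",
              x$cavity_center[1], x$cavity_center[2], x$cavity_center[3],
              x$slab$z_min, x$slab$z_max))
  invisible(x)
}

## shared: peptide/compound atoms appended to a receptor skeleton
assemble_model <- function(receptor, extra_atoms, model_id, conformation,
                           isoform, ligand_chain = NULL, ligand_resname = NULL) {
  atoms <- rbind(receptor$atoms, extra_atoms)
  atoms$serial <- seq_len(nrow(atoms))
  complex_model(atoms, receptor$receptor_chains,
                ligand_chain = ligand_chain, ligand_resname = ligand_resname,
                membrane_resname = receptor$membrane_resname,
                conformation = conformation, isoform = isoform,
                model_id = model_id)
}

#' Plant a docked peptide pose of a prescribed acceptance class
#'
#' Pose classes map onto the three pose-acceptance criteria:
#' \describe{
#'   \item{good}{wraps the cavity, contacting every planted segment; passes
#'     all criteria. `orientation` controls which terminus sits inside the
#'     cavity.}
#'   \item{membrane_violator}{a good pose whose middle residues dip into the
#'     membrane slab; fails only the membrane-avoidance criterion.}
#'   \item{single_point}{clings to the first planted segment only; fails
#'     only the multipoint criterion.}
#'   \item{far}{translated far from the receptor; no contacts at all (fails
#'     cavity localization and multipoint).}
#' }
#'
#' @param receptor a `receptor_skeleton`.
#' @param pose_class one of `"good"`, `"membrane_violator"`,
#'   `"single_point"`, `"far"`.
#' @param orientation `"C_in"` or `"N_in"`: which terminal window is pulled
#'   into the cavity (good-derived classes).
#' @param noise_sd coordinate noise, angstrom (default 0.3).
#' @param seed RNG seed for the noise.
#' @param n_res peptide length (default 42).
#' @param conformation,isoform,model_id model tags.
#' @return A `complex_model` with peptide chain `P`.
#' @export
plant_peptide_pose <- function(receptor, pose_class = c("good",
                                 "membrane_violator", "single_point", "far"),
                               orientation = c("C_in", "N_in"),
                               noise_sd = 0.3, seed = 1L, n_res = 42L,
                               conformation = "E1P", isoform = "Ab42",
                               model_id = "pose") {
  pose_class <- match.arg(pose_class)
  orientation <- match.arg(orientation)
  set.seed(seed)
  anchors <- receptor$anchors
  if (pose_class == "single_point") {
    s1 <- receptor$planted[1L, ]
    anchors <- anchors[anchors$chain == s1$chain & anchors$resid >= s1$start &
                         anchors$resid <= s1$end, , drop = FALSE]
  }
  cen <- receptor$cavity_center
  axis <- receptor$axis
  k <- seq_len(n_res)
  ## terminal window pulled into the cavity (good-derived classes); the
  ## remaining residues are spread evenly over the planted anchors so every
  ## planted residue is contacted with near-uniform multiplicity
  term <- if (pose_class %in% c("good", "membrane_violator")) {
    if (orientation == "C_in") seq(n_res - 4L, n_res) else 1:5
  } else integer(0)
  body_res <- setdiff(k, term)
  anchor_of <- integer(n_res)
  n_anchor <- nrow(anchors)
  n_body <- length(body_res)
  if (n_body >= n_anchor) {
    ## every anchor at least once; leftover residues reinforce the segment
    ## ends, where one-sided neighbourhoods would otherwise thin the counts
    seg_tab <- if (pose_class == "single_point")
      receptor$planted[1L, , drop = FALSE] else receptor$planted
    sizes <- seg_tab$end - seg_tab$start + 1L
    ends_idx <- cumsum(sizes)
    end_pool <- as.vector(rbind(ends_idx - sizes + 1L, ends_idx))
    rem <- n_body %% n_anchor
    anchor_of[body_res] <- sort(c(rep(seq_len(n_anchor), n_body %/% n_anchor),
                                  rep_len(end_pool, max(rem, 1L))[seq_len(rem)]))
  } else {
    anchor_of[body_res] <- floor((seq_len(n_body) - 1L) * n_anchor / n_body) + 1L
  }
  pos <- matrix(NA_real_, n_res, 3L)
  a <- atom_xyz(anchors)[anchor_of[body_res], , drop = FALSE]
  ## offset radially (in xy) toward the cavity axis, keeping the anchor's z:
  ## contacts stay local to the anchored segment band
  u <- cbind(axis[1] - a[, 1], axis[2] - a[, 2], 0)
  u <- sweep(u, 1L, sqrt(rowSums(u^2)), "/")
  pos[body_res, ] <- a + 4.4 * u +
    matrix(stats::rnorm(3L * length(body_res), 0, noise_sd), ncol = 3L)
  if (length(term)) {
    ang <- 2 * pi * seq_along(term) / length(term)
    pos[term, ] <- cbind(axis[1] + 1.5 * cos(ang), axis[2] + 1.5 * sin(ang),
                         cen[3] + c(-0.5, 0, 0.5, 0, -0.5)) +
      matrix(stats::rnorm(3L * length(term), 0, 0.05), ncol = 3L)
  }
  if (pose_class == "membrane_violator") {
    ## mid-residues dip into the slab near the cavity axis, away from the
    ## transmembrane columns, so only the membrane criterion is violated
    mid <- 15:24
    pos[mid, 1L] <- axis[1] + seq(-2, 2, length.out = length(mid))
    pos[mid, 2L] <- axis[2] + stats::rnorm(length(mid), 0, 0.3)
    pos[mid, 3L] <- (receptor$slab$z_min + receptor$slab$z_max) / 2 +
      stats::rnorm(length(mid), 0, 0.3)
  }
  if (pose_class == "far") pos <- sweep(pos, 2L, c(120, 0, 40), "+")
  pep <- rbind(
    data.frame(resid = k, name = "CA", x = pos[, 1], y = pos[, 2],
               z = pos[, 3]),
    data.frame(resid = k, name = "CB", x = pos[, 1], y = pos[, 2],
               z = pos[, 3] + 1.2))
  pep <- pep[order(pep$resid, pep$name), , drop = FALSE]
  extra <- atom_sites(serial = seq_len(nrow(pep)), name = pep$name,
                      element = "C", resname = "ALA", resid = pep$resid,
                      chain = "P", x = pep$x, y = pep$y, z = pep$z,
                      het = FALSE)
  assemble_model(receptor, extra, model_id, conformation, isoform,
                 ligand_chain = "P")
}

#' Plant a refined compound pose of a prescribed fate
#'
#' Places a 12-heavy-atom compound (HETATM group `LIG`) so that the fate
#' classifier recovers the planted class at default thresholds:
#' interface-bound poses touch planted interface residues from the
#' extracellular side, cavity-entered poses sit on the cavity axis below
#' the interface, membrane-embedded poses sit inside the slab, displaced
#' poses sit far from everything.
#'
#' @param receptor a `receptor_skeleton`.
#' @param fate_class one of `"interface_bound"`, `"cavity_entered"`,
#'   `"membrane_embedded"`, `"displaced"`.
#' @param seed RNG seed for the placement noise.
#' @param n_atoms ligand heavy-atom count (default 12).
#' @param conformation,model_id model tags.
#' @return A `complex_model` with a HETATM ligand `LIG`.
#' @export
plant_compound_pose <- function(receptor, fate_class = c("interface_bound",
                                  "cavity_entered", "membrane_embedded",
                                  "displaced"),
                                seed = 1L, n_atoms = 12L,
                                conformation = "E1P", model_id = "compound") {
  fate_class <- match.arg(fate_class)
  set.seed(seed)
  cen <- receptor$cavity_center
  iface_z <- mean(receptor$anchors$z)
  cluster_at <- function(p) {
    ang <- 2 * pi * seq_len(n_atoms) * 0.381966  # golden-angle spread
    zz <- 1.5 * cos(pi * seq_len(n_atoms) / n_atoms)
    rr <- sqrt(pmax(1.5^2 - zz^2, 0))
    sweep(cbind(rr * cos(ang), rr * sin(ang), zz), 2L, p, "+") +
      matrix(stats::rnorm(3L * n_atoms, 0, 0.1), ncol = 3L)
  }
  pos <- switch(fate_class,
    membrane_embedded = cluster_at(c(0, 0,
      (receptor$slab$z_min + receptor$slab$z_max) / 2)),
    displaced = cluster_at(c(45, 45, 35)),
    cavity_entered = cluster_at(c(cen[1], cen[2], iface_z - 8)),
    interface_bound = {
      n_anchor <- nrow(receptor$anchors)
      take <- seq(n_anchor - n_atoms + 1L, n_anchor)
      a <- atom_xyz(receptor$anchors)[take, , drop = FALSE]
      u <- cbind(receptor$axis[1] - a[, 1], receptor$axis[2] - a[, 2], 0)
      u <- sweep(u, 1L, sqrt(rowSums(u^2)), "/")
      a + 3.8 * u + matrix(stats::rnorm(3L * n_atoms, 0, 0.1), ncol = 3L)
    })
  extra <- atom_sites(serial = seq_len(n_atoms),
                      name = sprintf("C%d", seq_len(n_atoms)),
                      element = "C", resname = "LIG", resid = 1L,
                      chain = "X", x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      het = TRUE)
  assemble_model(receptor, extra, model_id, conformation, NA_character_,
                 ligand_resname = "LIG")
}

## derived per-model seed, kept well below 2^31
model_seed <- function(seed, conf_index, i) {
  (abs(seed) %% 2^20) * 1024L + conf_index * 64L + i
}

#' Generate a full synthetic docking-ensemble fixture
#'
#' Writes, per receptor conformation, one multi-model PDB of docked peptide
#' poses (receptor + membrane + peptide chain `P` per MODEL), plus a
#' metadata TSV and a ground-truth JSON describing exactly what was
#' planted. A fraction of the poses are decoys cycling through the violator
#' classes; good poses cycle through the ligand isoform tags and follow the
#' orientation plan.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; equal seeds give byte-identical fixtures.
#' @param n_models poses per conformation (default 15: five complexes for
#'   each of three ligand isoforms).
#' @param conformations receptor conformation tags (default E1P, E2P, OBN).
#' @param decoy_fraction fraction of poses that are decoys (default 0.2).
#' @param orientation_plan optional character vector (`"C_in"`/`"N_in"`)
#'   assigned to the good poses in order; default alternates.
#' @param receptor a `receptor_skeleton` (default [make_receptor()]).
#' @return Invisibly, list(files, ground_truth, models).
#' @export
make_ensemble <- function(dir, seed = 1L, n_models = 15L,
                          conformations = c("E1P", "E2P", "OBN"),
                          decoy_fraction = 0.2, orientation_plan = NULL,
                          receptor = make_receptor()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_decoy <- round(n_models * decoy_fraction)
  n_good <- n_models - n_decoy
  decoy_classes <- rep_len(c("far", "membrane_violator", "single_point"),
                           max(n_decoy, 1L))[seq_len(n_decoy)]
  isoforms <- rep_len(ISOFORM_LEVELS, n_good)
  orientations <- if (is.null(orientation_plan))
    rep_len(c("C_in", "N_in"), n_good)
  else rep_len(orientation_plan, n_good)
  meta <- NULL
  files <- character(0)
  all_models <- list()
  for (ci in seq_along(conformations)) {
    conf <- conformations[ci]
    plan <- data.frame(
      i = seq_len(n_models),
      pose_class = c(rep("good", n_good), decoy_classes),
      orientation = c(orientations, rep("C_in", n_decoy)),
      isoform = c(isoforms, rep("Ab42", n_decoy)))
    models <- lapply(seq_len(n_models), function(i) {
      plant_peptide_pose(receptor, plan$pose_class[i],
                         orientation = plan$orientation[i],
                         seed = model_seed(seed, ci, i),
                         conformation = conf, isoform = plan$isoform[i],
                         model_id = sprintf("%s_m%d", conf, i))
    })
    f <- file.path(dir, sprintf("poses_%s.pdb", conf))
    write_complex_pdb(models, f)
    files <- c(files, f)
    plan$conformation <- conf
    plan$model_id <- vapply(models, function(m) m$model_id, "")
    meta <- rbind(meta, plan[, c("model_id", "conformation", "isoform",
                                 "pose_class", "orientation")])
    all_models[[conf]] <- models
  }
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gt <- list(seed = seed, n_models = n_models,
             conformations = conformations,
             decoy_fraction = decoy_fraction,
             planted_segments = as.data.frame(receptor$planted),
             slab = c(receptor$slab$z_min, receptor$slab$z_max),
             cavity_center = unname(receptor$cavity_center),
             models = meta)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(files = files, ground_truth = gt, models = all_models))
}

#' Generate a synthetic compound-screening fixture set
#'
#' One single-model PDB per compound x conformation following a fate plan
#' (default: the worked ten-compound example of
#' [screening_triage_example()]), plus the compound metadata TSV consumed
#' by the triage stage and a ground-truth JSON.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param plan a `compound_records` table giving the fates to plant.
#' @param receptor a `receptor_skeleton`.
#' @return Invisibly, list(files, plan, models).
#' @export
make_compound_set <- function(dir, seed = 1L,
                              plan = screening_triage_example(),
                              receptor = make_receptor()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  confs <- sort(unique(plan$conformation))
  files <- character(nrow(plan))
  models <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    ci <- match(plan$conformation[i], confs)
    m <- plant_compound_pose(receptor, plan$fate[i],
                             seed = model_seed(seed, ci, i),
                             conformation = plan$conformation[i],
                             model_id = sprintf("%s_%s", plan$compound_id[i],
                                                plan$conformation[i]))
    f <- file.path(dir, sprintf("%s_%s.pdb", plan$compound_id[i],
                                plan$conformation[i]))
    write_complex_pdb(m, f)
    files[i] <- f
    models[[i]] <- m
  }
  utils::write.table(
    as.data.frame(plan)[, c("compound_id", "conformation", "docking_rank",
                            "docking_affinity")],
    file.path(dir, "compounds.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(list(seed = seed, plan = as.data.frame(plan)),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(files = files, plan = plan, models = models))
}
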