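# Independent brute-force contact oracle and small hand-built models used
# across the test files. The oracle deliberately shares no code with the
# package: plain nested loops over atom pairs.

oracle_contacts <- function(model, cutoff = 5.0) {
  ra <- receptor_atoms(model)
  la <- ligand_atoms(model)
  lunit <- if (is.null(model$ligand_chain)) rep(1L, nrow(la)) else la$resid
  out <- list()
  for (rk in unique(paste(ra$chain, ra$resid))) {
    ri <- which(paste(ra$chain, ra$resid) == rk)
    for (lu in unique(lunit)) {
      li <- which(lunit == lu)
      dmin <- Inf
      for (i in ri) for (j in li) {
        d <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                    (ra$z[i] - la$z[j])^2)
        if (d < dmin) dmin <- d
      }
      if (dmin <= cutoff) {
        p <- strsplit(rk, " ")[[1]]
        out[[length(out) + 1L]] <- data.frame(
          receptor_chain = p[1], receptor_residue = as.integer(p[2]),
          ligand_unit = as.integer(lu), min_distance = dmin)
      }
    }
  }
  if (!length(out))
    return(data.frame(receptor_chain = character(0),
                      receptor_residue = integer(0),
                      ligand_unit = integer(0), min_distance = numeric(0)))
  out <- do.call(rbind, out)
  out[order(out$receptor_chain, out$receptor_residue, out$ligand_unit), ]
}

# tiny two-chain receptor + peptide model built directly from coordinates
toy_model <- function(receptor_xyz, ligand_xyz, ligand_het = FALSE,
                      receptor_resid = seq_len(nrow(receptor_xyz)),
                      receptor_chain = rep("A", nrow(receptor_xyz)),
                      ligand_resid = seq_len(nrow(ligand_xyz)),
                      model_id = "toy") {
  n_r <- nrow(receptor_xyz); n_l <- nrow(ligand_xyz)
  atoms <- atom_sites(
    serial = seq_len(n_r + n_l),
    name = rep("CA", n_r + n_l),
    element = "C",
    resname = c(rep("ALA", n_r), rep(if (ligand_het) "LIG" else "ALA", n_l)),
    resid = c(receptor_resid, ligand_resid),
    chain = c(receptor_chain, rep(if (ligand_het) "X" else "P", n_l)),
    x = c(receptor_xyz[, 1], ligand_xyz[, 1]),
    y = c(receptor_xyz[, 2], ligand_xyz[, 2]),
    z = c(receptor_xyz[, 3], ligand_xyz[, 3]),
    het = c(rep(FALSE, n_r), rep(ligand_het, n_l)))
  rc <- stats::setNames(rep("alpha_subunit", length(unique(receptor_chain))),
                        unique(receptor_chain))
  rc[names(rc) == "B"] <- "beta_subunit"
  complex_model(atoms, rc,
                ligand_chain = if (ligand_het) NULL else "P",
                ligand_resname = if (ligand_het) "LIG" else NULL,
                model_id = model_id)
}

# random receptor/ligand pair for oracle cross-checks
random_toy <- function(seed, het = FALSE) {
  set.seed(seed)
  n_r <- sample(6:12, 1)
  n_l <- sample(3:6, 1)
  toy_model(matrix(stats::runif(3 * n_r, 0, 15), ncol = 3),
            matrix(stats::runif(3 * n_l, 0, 15), ncol = 3),
            ligand_het = het,
            receptor_chain = sample(c("A", "B"), n_r, replace = TRUE),
            model_id = sprintf("rnd%d", seed))
}

expect_same_contacts <- function(got, want) {
  got <- as.data.frame(got); rownames(got) <- NULL
  want <- as.data.frame(want); rownames(want) <- NULL
  expect_equal(got[, c("receptor_chain", "receptor_residue", "ligand_unit")],
               want[, c("receptor_chain", "receptor_residue", "ligand_unit")])
  expect_equal(got$min_distance, want$min_distance, tolerance = 1e-10)
}

table1_refined <- function() {
  list(
    E1P = interface_segments(
      chain = c("A", "A", "A", "A", "B", "B", "B", "B", "B", "B"),
      start = c(117, 311, 794, 884, 82, 91, 196, 217, 266, 287),
      end   = c(126, 318, 794, 894, 87, 111, 196, 217, 273, 298)),
    E2P = interface_segments(
      chain = c("A", "A", "A", "A", "A", "A", "B", "B", "B", "B", "B"),
      start = c(117, 310, 879, 883, 886, 970, 83, 91, 217, 268, 287),
      end   = c(124, 316, 879, 883, 893, 979, 85, 107, 218, 273, 290)),
    OBN = interface_segments(
      chain = c("A", "A", "A", "A", "A", "A", "A",
                "B", "B", "B", "B", "B", "B", "B", "B"),
      start = c(115, 306, 792, 879, 883, 886, 974, 2, 91, 100, 103, 216, 273,
                287, 294),
      end   = c(125, 317, 795, 879, 883, 893, 974, 87, 91, 100, 107, 218, 273,
                290, 294)))
}
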