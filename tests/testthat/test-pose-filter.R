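# Pose acceptance: cavity definition, membrane overlap, cavity proximity,
# multipoint contact, and ensemble filtering.

test_that("cavity center is the unweighted C-alpha centroid of the targets", {
  atoms <- atom_sites(serial = 1:3, name = c("CA", "CA", "CA"), element = "C",
                      resname = "ALA", resid = c(1, 2, 5), chain = "A",
                      x = c(0, 2, 50), y = 0, z = 0, het = FALSE)
  lig <- atom_sites(serial = 4, name = "CA", element = "C", resname = "ALA",
                    resid = 1, chain = "P", x = 1, y = 1, z = 1, het = FALSE)
  m <- complex_model(rbind(atoms, lig), c(A = "alpha_subunit"),
                     ligand_chain = "P")
  cav <- cavity_center(m, interface_segments("A", 1, 5))
  expect_equal(unname(cav$center), c(52 / 3, 0, 0))
  ## two segments with CA at (0,0,0) and (2,0,0) -> (1,0,0), but <3 CA errors
  expect_error(cavity_center(m, interface_segments("A", 1, 2)), ">= 3")
  expect_error(cavity_center(m, interface_segments("A", 90, 95)),
               "90-95")
})

test_that("fixture cavity center is recovered and lies in the chain gap", {
  rec <- make_receptor()
  m <- plant_peptide_pose(rec, "good", seed = 2)
  cav <- cavity_center(m, rec$planted)
  expect_lt(sqrt(sum((cav$center - rec$cavity_center)^2)), 0.5)
  ## between the subunit columns, above the slab
  expect_lt(abs(cav$center[1]), 26)
  expect_gt(cav$center[3], rec$slab$z_max)
})

test_that("membrane overlap is the exact inside-slab atom fraction", {
  slab <- membrane_slab(-10, 0)
  mk <- function(z) toy_model(matrix(c(0, 0, 20), ncol = 3),
                              cbind(0, 0, z))
  expect_equal(membrane_overlap(mk(c(5, 6, 7, 8)), slab), 0)
  expect_equal(membrane_overlap(mk(c(-5, -6, 7, 8)), slab), 0.5)
  expect_equal(membrane_overlap(mk(-5), slab), 1)
})

test_that("cavity proximity uses an inclusive fraction threshold", {
  cav <- structure(list(center = c(0, 0, 0), radius = 12),
                   class = "cavity_definition")
  ## 10 ligand residues, exactly 3 within 15 A -> fraction 0.3 passes
  lig <- rbind(cbind(c(5, 8, 10), 0, 0), cbind(seq(30, 70, length.out = 7), 0, 0))
  m <- toy_model(matrix(c(0, 0, -40), ncol = 3), lig)
  pr <- cavity_proximity(m, cav)
  expect_equal(pr$fraction, 0.3)
  expect_true(pr$pass)
  ## 50 A away fails with fraction 0
  m_far <- toy_model(matrix(c(0, 0, -40), ncol = 3),
                     cbind(seq(50, 60, length.out = 10), 0, 0))
  pr_far <- cavity_proximity(m_far, cav)
  expect_false(pr_far$pass)
  expect_equal(pr_far$fraction, 0)
})

test_that("multipoint clustering respects sequence separation and chains", {
  mk_contacts <- function(chain, resid) {
    structure(data.frame(receptor_chain = chain, receptor_residue = resid,
                         ligand_unit = rep_len(1L, length(resid)),
                         min_distance = rep_len(4, length(resid))),
              class = c("contact_pairs", "data.frame"))
  }
  ## three sites ~200 residues apart -> 3 clusters, pass
  r3 <- multipoint_contacts(mk_contacts("A", c(120, 313, 890)))
  expect_true(r3$pass)
  expect_equal(r3$n_clusters, 3)
  ## one contiguous patch -> 1 cluster, fail
  r1 <- multipoint_contacts(mk_contacts("A", 120:124))
  expect_false(r1$pass)
  expect_equal(r1$n_clusters, 1)
  ## cross-chain sites always count separately
  r2 <- multipoint_contacts(mk_contacts(c("A", "B"), c(120, 85)),
                            min_sites = 2)
  expect_true(r2$pass)
  ## boundary: separation exactly min_separation splits
  expect_equal(multipoint_contacts(mk_contacts("A", c(100, 120)))$n_clusters, 2)
  expect_equal(multipoint_contacts(mk_contacts("A", c(100, 119)))$n_clusters, 1)
  ## empty contacts -> fail with zero clusters
  expect_false(multipoint_contacts(mk_contacts(character(0), integer(0)))$pass)
})

test_that("planted violators fail exactly their targeted criterion", {
  rec <- make_receptor()
  cav <- cavity_center(plant_peptide_pose(rec, "good", seed = 1), rec$planted)
  mv <- filter_ensemble(list(plant_peptide_pose(rec, "membrane_violator",
                                                seed = 5, model_id = "mv")),
                        rec$slab, cav)$verdicts
  expect_false(mv$no_membrane_overlap)
  expect_true(mv$cavity_localized && mv$multipoint)
  sp <- filter_ensemble(list(plant_peptide_pose(rec, "single_point",
                                                seed = 6, model_id = "sp")),
                        rec$slab, cav)$verdicts
  expect_false(sp$multipoint)
  expect_true(sp$cavity_localized && sp$no_membrane_overlap)
  expect_equal(sp$n_contact_clusters, 1)
  far <- filter_ensemble(list(plant_peptide_pose(rec, "far",
                                                 seed = 7, model_id = "far")),
                         rec$slab, cav)$verdicts
  expect_false(far$cavity_localized)
  expect_false(far$multipoint)
  expect_true(far$no_membrane_overlap)
})

test_that("ensemble filtering keeps planted-good poses and drops violators", {
  rec <- make_receptor()
  classes <- c(rep("good", 6), "membrane_violator", "far", "single_point",
               "membrane_violator")
  models <- lapply(seq_along(classes), function(i)
    plant_peptide_pose(rec, classes[i], seed = 100 + i,
                       model_id = sprintf("m%02d", i)))
  cav <- cavity_center(models[[1]], rec$planted)
  res <- filter_ensemble(models, rec$slab, cav)
  expect_equal(nrow(res$verdicts), 10)
  expect_equal(sum(res$verdicts$passed), 6)
  expect_equal(res$verdicts$passed, classes == "good")
  ## verdict rows keep input order
  expect_equal(res$verdicts$model_id, sprintf("m%02d", 1:10))
  ## idempotence: refiltering the survivors changes nothing
  res2 <- filter_ensemble(res$survivors, rec$slab, cav)
  expect_true(all(res2$verdicts$passed))
  expect_equal(vapply(res2$survivors, function(m) m$model_id, ""),
               vapply(res$survivors, function(m) m$model_id, ""))
  ## order invariance of verdicts
  perm <- c(4, 1, 9, 2, 10, 3, 7, 5, 8, 6)
  res3 <- filter_ensemble(models[perm], rec$slab, cav)
  expect_equal(res3$verdicts$passed, res$verdicts$passed[perm])
  ## empty input -> empty output
  res0 <- filter_ensemble(list(), rec$slab, cav)
  expect_equal(nrow(res0$verdicts), 0)
  expect_length(res0$survivors, 0)
  ## criterion toggling: with membrane check disabled, violators pass
  resm <- filter_ensemble(models, rec$slab, cav,
                          criteria = c("cavity_localized", "multipoint"))
  expect_equal(sum(resm$verdicts$passed), 8)
})
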