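# Contact detection, profiles, aggregation, segment calling and scoring.

test_that("contact detection matches the brute-force all-pairs oracle", {
  for (seed in 1:30) {
    m <- random_toy(seed, het = seed %% 2 == 0)
    for (cutoff in c(3, 5, 8)) {
      got <- compute_contacts(m, cutoff)
      expect_same_contacts(got, oracle_contacts(m, cutoff))
    }
  }
})

test_that("separated and near-zero-cutoff cases give empty contact lists", {
  base <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), ncol = 3, byrow = TRUE)
  far <- toy_model(base, base + 100)           # ligand displaced 100 A
  expect_equal(nrow(compute_contacts(far)), 0)
  near <- toy_model(base, sweep(base, 2, c(0.5, 0, 0), "+"))  # 0.5 A apart
  expect_equal(nrow(compute_contacts(near, cutoff = 0.1)), 0)
})

test_that("a peptide 3.5 A from receptor residues 10-14 hits exactly those", {
  rec_xyz <- cbind(seq(0, 80, by = 4), 0, 0)   # residues 1..21 along x
  lig_xyz <- cbind(seq(36, 52, by = 4), 3.5, 0) # faces residues 10..14
  m <- toy_model(rec_xyz, lig_xyz, receptor_resid = 1:21)
  got <- compute_contacts(m, cutoff = 5)
  expect_setequal(unique(got$receptor_residue), 10:14)
})

test_that("contacts grow monotonically with the cutoff", {
  m <- random_toy(7)
  key <- function(ct) paste(ct$receptor_chain, ct$receptor_residue,
                            ct$ligand_unit)
  prev <- character(0)
  for (cutoff in c(2, 4, 6, 10)) {
    cur <- key(compute_contacts(m, cutoff))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("contact detection is invariant to atom order", {
  m <- random_toy(11)
  m2 <- m
  set.seed(1)
  m2$atoms <- m$atoms[sample(nrow(m$atoms)), ]
  expect_same_contacts(compute_contacts(m2), compute_contacts(m))
})

test_that("residue profiles count distinct ligand units (and binarize)", {
  # receptor residue 10 contacted by ligand residues 1,2,3; residue 12 by one
  rec_xyz <- rbind(c(0, 0, 0), c(50, 0, 0))
  lig_xyz <- rbind(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3), c(52, 0, 0))
  m <- toy_model(rec_xyz, lig_xyz, receptor_resid = c(10, 12))
  ct <- compute_contacts(m)
  p <- residue_profile(ct, model = m)
  expect_equal(p$count[p$resid == 10], 3)
  expect_equal(p$count[p$resid == 12], 1)
  b <- residue_profile(ct, model = m, mode = "binary")
  expect_equal(b$count, c(1, 1))
  z <- residue_profile(compute_contacts(m, cutoff = 0.5), model = m)
  expect_equal(z$count, c(0, 0))
  # oracle recount from the pair list itself
  recount <- table(paste(ct$receptor_chain, ct$receptor_residue))
  expect_equal(unname(recount[paste("A", 10)]), 3)
})

test_that("aggregation sums element-wise, accumulates n_models, checks keys", {
  rec_xyz <- cbind(seq(0, 8, by = 2), 0, 0)
  one_hot <- function(at) {
    m <- toy_model(rec_xyz, matrix(rec_xyz[at, ] + c(0, 3, 0), ncol = 3),
                   receptor_resid = 1:5)
    residue_profile(compute_contacts(m), model = m)
  }
  profs <- replicate(15, one_hot(3), simplify = FALSE)
  agg <- aggregate_profiles(profs)
  expect_equal(agg$count[agg$resid == 3], 15)
  expect_equal(attr(agg, "n_models"), 15)
  ## order invariance
  profs2 <- c(profs[8:15], profs[1:7])
  expect_equal(as.data.frame(aggregate_profiles(profs2)),
               as.data.frame(aggregate_profiles(profs)))
  ## mismatched residue sets
  other <- toy_model(cbind(0:3 * 2, 0, 0), matrix(c(0, 3, 0), ncol = 3),
                     receptor_resid = 1:4)
  expect_error(
    aggregate_profiles(list(profs[[1]],
                            residue_profile(compute_contacts(other),
                                            model = other))),
    "different receptor")
})

test_that("segment calling follows the seed/merge/min-length rule", {
  mk_profile <- function(counts, resid = seq_along(counts)) {
    structure(data.frame(chain = "A", resid = resid, count = counts),
              class = c("contact_profile", "data.frame"),
              n_models = 1L, mode = "pair_count")
  }
  ## hand enumeration: threshold max(2, 0.25*7)=2; seeds 3,4,5; run length 3
  s1 <- detect_segments(mk_profile(c(0, 0, 5, 6, 7, 0, 0, 1, 0)))
  expect_equal(as.data.frame(s1),
               data.frame(chain = "A", start = 3L, end = 5L, peak_count = 7L),
               ignore_attr = TRUE)
  ## two seed runs split by 3 non-seeds > gap_tolerance 2
  s2 <- detect_segments(mk_profile(c(5, 5, 5, 0, 0, 0, 5, 5, 5)))
  expect_equal(nrow(s2), 2)
  expect_equal(s2$start, c(1L, 7L))
  ## same runs split by 2 non-seeds merge into one segment
  s3 <- detect_segments(mk_profile(c(5, 5, 5, 0, 0, 5, 5, 5)))
  expect_equal(nrow(s3), 1)
  expect_equal(c(s3$start, s3$end), c(1L, 8L))
  ## all-zero profile -> no segments
  expect_equal(nrow(detect_segments(mk_profile(rep(0, 9)))), 0)
  ## min_length drops short segments
  s4 <- detect_segments(mk_profile(c(9, 9, 0, 0, 0, 0, 9, 0, 0)))
  expect_equal(nrow(s4), 0)
})

test_that("complex scoring and ranking follow the surrogate formula", {
  ## 10 interface residues, 14 pairs -> 10 + 0.1*14 = 11.4
  rec_xyz <- cbind(seq(0, 45, by = 5), 0, 0)           # residues 1..10
  lig_xyz <- rbind(cbind(seq(0, 45, by = 5), 3, 0),    # each residue once
                   cbind(seq(0, 15, by = 5), 0, 3))    # residues 1..4 again
  m <- toy_model(rec_xyz, lig_xyz, receptor_resid = 1:10,
                 ligand_resid = 1:14)
  sc <- score_complex(m)
  expect_equal(sc$n_interface_residues, 10)
  expect_equal(sc$total_contacts, 14)
  expect_equal(sc$score, 11.4)
  ## ranking: descending, stable lexicographic tie-break, k clamps
  scores <- data.frame(model_id = c("b", "a", "c"),
                       total_contacts = c(5, 5, 2),
                       n_interface_residues = c(3, 3, 1),
                       score = c(3.5, 3.5, 1.2))
  top <- rank_complexes(scores, k = 10)
  expect_equal(top$model_id, c("a", "b", "c"))
  expect_equal(top$rank, 1:3)
  expect_equal(nrow(rank_complexes(scores, k = 2)), 2)
})

test_that("profiles and segments are invariant to model order in ensembles", {
  d <- tempfile()
  make_ensemble(d, seed = 21, n_models = 6, conformations = "E1P",
                decoy_fraction = 0)
  ms <- read_complex_pdb(file.path(d, "poses_E1P.pdb"),
                         c(A = "alpha_subunit", B = "beta_subunit"),
                         ligand_chain = "P", membrane_resname = "MEM")
  profs <- lapply(ms, function(m)
    residue_profile(compute_contacts(m), model = m))
  a <- aggregate_profiles(profs)
  b <- aggregate_profiles(rev(profs))
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_equal(as.data.frame(detect_segments(a)),
               as.data.frame(detect_segments(b)))
  unlink(d, recursive = TRUE)
})
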