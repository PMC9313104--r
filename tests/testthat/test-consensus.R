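# Cross-conformation interface consensus, narrowing, orientation and
# exclusion annotation.

test_that("identical and disjoint interfaces give Jaccard 1 and 0", {
  seg <- interface_segments("A", c(10, 40), c(15, 45))
  ia <- conformation_interface("E1P", "refined", seg)
  ib <- conformation_interface("E2P", "refined", seg)
  rep1 <- interface_consensus(list(ia, ib))
  expect_equal(rep1$jaccard$jaccard, 1)
  expect_equal(as.data.frame(rep1$intersection_segments)[, 1:3],
               as.data.frame(seg)[, 1:3])
  ic <- conformation_interface("OBN", "refined",
                               interface_segments("A", 100, 110))
  rep0 <- interface_consensus(list(ia, ic))
  expect_equal(rep0$jaccard$jaccard, 0)
  expect_equal(nrow(rep0$intersection_segments), 0)
  expect_length(rep0$intersection_keys, 0)
})

test_that("consensus is symmetric and invariant to conformation order", {
  t1 <- table1_refined()
  ifaces <- lapply(names(t1), function(cf)
    conformation_interface(cf, "refined", t1[[cf]]))
  a <- interface_consensus(ifaces)
  b <- interface_consensus(rev(ifaces))
  expect_setequal(a$intersection_keys, b$intersection_keys)
  key <- function(j) paste(pmin(j$a, j$b), pmax(j$a, j$b))
  expect_equal(a$jaccard$jaccard[order(key(a$jaccard))],
               b$jaccard$jaccard[order(key(b$jaccard))])
})

test_that("published-style per-conformation ranges intersect as computed", {
  ## set arithmetic over the three typed-in refined interface range lists
  t1 <- table1_refined()
  rep <- interface_consensus(lapply(names(t1), function(cf)
    conformation_interface(cf, "refined", t1[[cf]])))
  got <- as.data.frame(rep$intersection_segments)[, c("chain", "start", "end")]
  want <- data.frame(chain = c("A", "A", "A", "B", "B", "B"),
                     start = c(117L, 311L, 886L, 83L, 100L, 287L),
                     end = c(124L, 316L, 893L, 85L, 107L, 290L))
  expect_equal(got, want)
  ## the consensus core covers the canonical target-site ranges
  covers <- function(chain, lo, hi)
    all(paste(chain, lo:hi, sep = ":") %in% rep$intersection_keys)
  expect_true(covers("A", 119, 124))
  expect_true(covers("A", 311, 316))
  expect_true(covers("A", 887, 893))
  expect_true(covers("B", 84, 85))
  expect_true(covers("B", 287, 290))
  ## intersection is a subset of every conformation's residue set
  for (k in rep$per_conformation)
    expect_true(all(rep$intersection_keys %in% k))
})

test_that("narrowing metric pairs segments by overlap and ratios widths", {
  docking <- conformation_interface("E2P", "docking",
    interface_segments("A", c(113, 309, 883, 970), c(128, 316, 900, 979)))
  refined <- conformation_interface("E2P", "refined",
    interface_segments("A", c(117, 310, 886, 970), c(124, 316, 893, 979)))
  nm <- narrowing_metric(docking, refined)
  seg1 <- nm$segment_changes[nm$segment_changes$docking_start == 113, ]
  expect_equal(seg1$docking_width, 16)
  expect_equal(seg1$refined_width, 8)
  expect_lt(nm$total_ratio, 1)
  ## identity comparison is exactly 1
  expect_equal(narrowing_metric(docking, docking)$total_ratio, 1)
})

test_that("peptide orientation separates C-in, N-in and ambiguous poses", {
  cav <- structure(list(center = c(0, 0, 0), radius = 12),
                   class = "cavity_definition")
  mk_pep <- function(zs) toy_model(matrix(c(50, 50, 50), ncol = 3),
                                   cbind(0, 0, zs))
  ## C-terminal window at the center, N-terminal window 30 A out
  expect_equal(peptide_orientation(mk_pep(seq(30, 0, length.out = 12)), cav),
               "C_in")
  expect_equal(peptide_orientation(mk_pep(seq(0, 30, length.out = 12)), cav),
               "N_in")
  ## symmetric placement -> ambiguous
  expect_equal(peptide_orientation(mk_pep(c(5:0, 0:5)), cav), "ambiguous")
  ## compounds have no orientation
  het <- toy_model(matrix(c(50, 50, 50), ncol = 3),
                   cbind(0, 0, 1:12), ligand_het = TRUE)
  expect_error(peptide_orientation(het, cav), "not a peptide")
  ## too-short peptide
  expect_error(peptide_orientation(mk_pep(1:6), cav), ">=")
})

test_that("a planted 17/13 orientation plan is recovered exactly", {
  d <- tempfile()
  res <- make_ensemble(d, seed = 31, n_models = 30, conformations = "E1P",
                       decoy_fraction = 0,
                       orientation_plan = rep(c("C_in", "N_in"), c(17, 13)))
  models <- res$models$E1P
  rec <- make_receptor()
  cav <- cavity_center(models[[1]], rec$planted)
  st <- orientation_stats(models, cav)
  expect_equal(st$n_C_in, 17)
  expect_equal(st$n_N_in, 13)
  expect_equal(st$n_ambiguous, 0)
  expect_equal(st$n_C_in + st$n_N_in + st$n_ambiguous, length(models))
  unlink(d, recursive = TRUE)
})

test_that("exclusion annotation removes regions but keeps them reported", {
  e1p_beta <- interface_segments("B", c(82, 91, 196, 217, 266, 287),
                                 c(87, 111, 196, 217, 273, 298))
  excl <- interface_segments("B", c(216, 267, 285), c(226, 273, 290))
  ann <- annotate_excluded(e1p_beta, excl, reason = "far from cavity")
  got <- as.data.frame(ann$kept)[, c("chain", "start", "end")]
  want <- data.frame(chain = "B", start = c(82L, 91L, 196L, 266L, 291L),
                     end = c(87L, 111L, 196L, 266L, 298L))
  expect_equal(got, want)
  expect_equal(ann$excluded$reason, rep("far from cavity", 3))
  ## empty exclusion is the identity
  none <- annotate_excluded(e1p_beta, interface_segments(character(0),
                                                         integer(0),
                                                         integer(0)))
  expect_setequal(paste(none$kept$chain, none$kept$start, none$kept$end),
                  paste(e1p_beta$chain, e1p_beta$start, e1p_beta$end))
})
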