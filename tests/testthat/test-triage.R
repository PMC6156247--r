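test_that("best_pose picks the maximal binding score with stated tie-breaks", {
  poses <- data.frame(compound_id = "C01", target_id = "STAT1",
                      pose_rank = 1:3, bs = c(7.1, 8.09, 6.0),
                      crash = c(-1, -1.66, -1), polar_score = 5)
  expect_equal(best_pose(poses)$bs, 8.09)

  one <- poses[1, ]
  expect_equal(best_pose(one), one)

  tie <- data.frame(compound_id = "X", target_id = "T", pose_rank = 1:2,
                    bs = 5.0, crash = c(-2.0, -1.0), polar_score = 5)
  expect_equal(best_pose(tie)$crash, -1.0)

  tie$crash <- -1  # full tie: lower rank wins
  expect_equal(best_pose(tie)$pose_rank, 1)

  expect_error(best_pose(poses[0, ]), "at least one")
  two <- poses; two$compound_id[2] <- "other"
  expect_error(best_pose(two), "single compound")
})

test_that("rank_top_k orders the primary-screen scores as published", {
  summ <- data.frame(compound_id = primary_screen_scores$compound_id,
                     STAT1 = primary_screen_scores$bs,
                     stringsAsFactors = FALSE)
  expect_equal(rank_top_k(summ, "STAT1", 1)$compound_id, "J01")
  expect_equal(rank_top_k(summ, "STAT1", 3)$compound_id,
               c("J01", "E01", "C01"))
  expect_message(all12 <- rank_top_k(summ, "STAT1", 99), "returning all")
  expect_equal(nrow(all12), 12)
  expect_error(rank_top_k(summ, "STAT9", 1), "STAT9")
})

test_that("summarize_best_scores collapses poses to best BS per target", {
  poses <- as_pose_table(rbind(
    make_pose_set("A", "STAT1", n_both = 3, bs_top = 8.2),
    make_pose_set("A", "STAT2", n_both = 3, bs_top = 5.0),
    make_pose_set("B", "STAT1", n_both = 3, bs_top = 7.1),
    make_pose_set("B", "STAT2", n_both = 3, bs_top = 7.5)))
  s <- summarize_best_scores(poses)
  expect_equal(s$compound_id, c("A", "B"))
  expect_equal(s$STAT1, c(8.2, 7.1))
  expect_equal(s$STAT2, c(5.0, 7.5))
})

test_that("similarity filter honors inclusive thresholds and the MW rule", {
  comp <- as_compound_table(data.frame(
    compound_id = c("a", "b", "c", "d"), name = c("a", "b", "c", "d"),
    mw = c(340, 320, 299, 310), source_library = "CDL",
    sim_C01 = c(0.767, 0.49, 0.6, NA), sim_E01 = c(NA, NA, NA, NA),
    stringsAsFactors = FALSE))
  expect_warning(
    kept <- similarity_filter(comp, c("C01", "E01"), min_sim = 0.5,
                              min_mw = 300),
    "without any similarity")
  expect_equal(kept$compound_id, "a")

  # boundary: sim exactly at the threshold is kept
  comp$sim_C01[2] <- 0.5
  expect_warning(kept2 <- similarity_filter(comp, "C01", 0.5, 300))
  expect_equal(kept2$compound_id, c("a", "b"))

  # idempotence
  expect_warning(once <- similarity_filter(comp, "C01", 0.5, 300))
  expect_equal(similarity_filter(once, "C01", 0.5, 300), once)
})

test_that("cbav is the reference-minus-other score difference", {
  expect_equal(cbav(8.23, 8.23), 0)
  expect_equal(cbav(8.23, 4.87), 3.36)
  expect_equal(cbav(4.0, 5.5), -1.5)
  expect_error(cbav(Inf, 1), "finite")
})

test_that("cbav is antisymmetric over random score pairs", {
  set.seed(42)
  a <- runif(200, 2, 10); b <- runif(200, 2, 10)
  expect_equal(cbav(a, b) + cbav(b, a), rep(0, 200))
})

test_that("cbav_filter reproduces the published keep/drop decisions", {
  # rebuild best-score maps from the published BS and CBAV columns
  summ <- data.frame(compound_id = rescreen_cbav$compound_id,
                     STAT1 = rescreen_cbav$bs_stat1,
                     STAT2 = rescreen_cbav$bs_stat1 -
                       rescreen_cbav$cbav_stat2,
                     STAT3 = rescreen_cbav$bs_stat1 -
                       rescreen_cbav$cbav_stat3,
                     stringsAsFactors = FALSE)
  kept <- cbav_filter(summ, "STAT1", 0)
  # every compound with both CBAVs >= 0 survives; E01, F01 do not
  expect_setequal(kept$compound_id,
                  c("C01", paste0("C01L_", LETTERS[1:6], "03")))
  expect_equal(kept$cbav_STAT2[kept$compound_id == "C01L_F03"], 3.36)
  expect_equal(kept$cbav_STAT3[kept$compound_id == "C01L_F03"], 0.22)

  # inclusive boundary: cbav exactly 0 is kept
  zero <- data.frame(compound_id = "z", STAT1 = 5, STAT2 = 5, STAT3 = 4)
  expect_equal(cbav_filter(zero, "STAT1", 0)$compound_id, "z")

  # idempotence (appended cbav_ columns must not become targets)
  expect_equal(cbav_filter(kept, "STAT1", 0), kept)
})

test_that("pocket occupancy classification covers flags and coordinates", {
  expect_equal(classify_pocket_occupancy(
    data.frame(occupies_py0 = 1, occupies_pyx = 1)), "BOTH")
  expect_equal(classify_pocket_occupancy(
    data.frame(occupies_py0 = 0, occupies_pyx = 0)), "NEITHER")

  pockets <- list(pocket_definition("pY0", c(0, 0, 0), 5),
                  pocket_definition("pYX", c(20, 0, 0), 5))
  at_centroid <- data.frame(atom_x = 0, atom_y = 0, atom_z = 0)
  expect_equal(classify_pocket_occupancy(at_centroid, pockets), "PY0_ONLY")

  # just outside both radii: distance = radius + epsilon
  outside <- data.frame(atom_x = c(5.001, 20), atom_y = c(0, 5.001),
                        atom_z = 0)
  d2 <- c(5.001^2, 5.001^2)  # brute-force distances to both centroids
  expect_true(all(d2 > 25))
  expect_equal(classify_pocket_occupancy(outside, pockets), "NEITHER")

  expect_error(classify_pocket_occupancy(at_centroid, NULL), "pocket")
})

test_that("lbpv matches published worked fractions and a brute-force count", {
  expect_equal(lbpv(make_pose_set(n_both = 19, n_py0 = 1), "BOTH"), 0.95)
  expect_equal(lbpv(make_pose_set(n_both = 5, n_neither = 15), "BOTH"),
               0.25)
  expect_equal(lbpv(make_pose_set(n_py0 = 20), "BOTH"), 0)

  set.seed(7)
  for (i in 1:20) {
    cls <- sample(c("PY0_ONLY", "PYX_ONLY", "BOTH", "NEITHER"), 20,
                  replace = TRUE)
    for (q in c("BOTH", "NEITHER", "PY0_ONLY", "PYX_ONLY"))
      expect_equal(lbpv(cls, q), sum(cls == q) / 20)
    expect_equal(lbpv(cls, "PY0"),
                 sum(cls %in% c("PY0_ONLY", "BOTH")) / 20)
  }

  expect_error(lbpv(character(0), "BOTH"), "at least one")
  expect_warning(lbpv(make_pose_set(n_both = 10), "BOTH"), "fewer")
})

test_that("lbpv obeys the inclusion-exclusion identity", {
  set.seed(11)
  for (i in 1:50) {
    cls <- sample(c("PY0_ONLY", "PYX_ONLY", "BOTH", "NEITHER"),
                  sample(20, 1), replace = TRUE)
    suppressWarnings(
      expect_equal(lbpv(cls, "PY0") + lbpv(cls, "PYX") -
                     lbpv(cls, "BOTH") + lbpv(cls, "NEITHER"),
                   1, tolerance = 1e-12))
  }
})

test_that("ddg0_impairment applies the sign rule", {
  wt <- list(target_id = "STAT1", ligand_id = "L", variant = "wt",
             dg0_kcal_mol = -8.0)
  mut <- list(target_id = "STAT1", ligand_id = "L", variant = "R602A",
              dg0_kcal_mol = -5.0)
  r <- ddg0_impairment(wt, mut)
  expect_equal(r$ddg0, 3.0); expect_true(r$impaired)

  mut$dg0_kcal_mol <- -8.0
  expect_false(ddg0_impairment(wt, mut)$impaired)
  mut$dg0_kcal_mol <- -11.0
  r <- ddg0_impairment(wt, mut)
  expect_equal(r$ddg0, -3.0); expect_false(r$impaired)

  mut$ligand_id <- "other"
  expect_error(ddg0_impairment(wt, mut), "share")
  expect_error(ddg0_impairment(mut, mut), "wild-type")
})

test_that("run_triage passes a clean compound and empties on bad CBAV", {
  poses <- as_pose_table(rbind(
    make_pose_set("ONLY", "STAT1", n_both = 20, bs_top = 9),
    make_pose_set("ONLY", "STAT2", n_both = 20, bs_top = 6),
    make_pose_set("ONLY", "STAT3", n_both = 20, bs_top = 6)))
  comp <- as_compound_table(data.frame(
    compound_id = "ONLY", name = "only", mw = 350, source_library = "CDL",
    sim_C01 = 0.8, stringsAsFactors = FALSE))
  cfg <- list(reference_target = "STAT1", top_k = 5,
              similarity_refs = "C01")
  rep <- run_triage(poses, comp, cfg)
  expect_equal(rep$final, "ONLY")
  expect_true(all(vapply(rep$stages, `[[`, numeric(1), "n_out") == 1))

  # reference scored worse than another target: CBAV stage empties
  flipped <- poses
  flipped$bs[flipped$target_id == "STAT2"] <-
    flipped$bs[flipped$target_id == "STAT2"] + 5
  expect_message(rep2 <- run_triage(flipped, comp, cfg), "emptied")
  expect_equal(rep2$final, character(0))
  expect_equal(rep2$stages[[4]]$n_out, 0)
  expect_equal(rep2$stages[[5]]$n_out, 0)
})
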