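# Penalty functions, ligand RMSD and the similarity score.

test_that("the per-residue distance penalty is free below 1 A then decays", {
  expect_equal(residue_distance_penalty(0), 1)
  expect_equal(residue_distance_penalty(1), 1)
  expect_equal(residue_distance_penalty(2), exp(-1), tolerance = 1e-12)
  # beyond 2.5 A a pair contributes almost nothing
  expect_lt(residue_distance_penalty(2.5), 0.11)
  expect_error(residue_distance_penalty(-0.1), "non-negative")
  # the alternative double-exponential reading
  expect_equal(residue_distance_penalty(2, form = "double_exp"), exp(-2))
})

test_that("the SASA penalty anchors at 0, 60 and 90 points difference", {
  expect_equal(sasa_penalty(0), 1)
  expect_equal(sasa_penalty(60), log10(40) - 1, tolerance = 1e-12)
  expect_equal(sasa_penalty(90), 0)
  expect_equal(sasa_penalty(100), 0)
  expect_error(sasa_penalty(101), "\\[0, 100\\]")
  expect_error(sasa_penalty(-1), "\\[0, 100\\]")
})

test_that("the ligand factor is free below 0.5 A and zero beyond 4.5 A", {
  expect_equal(ligand_alignment_factor(0), 1)
  expect_equal(ligand_alignment_factor(0.5), 1)
  expect_equal(ligand_alignment_factor(2.5), log(3, 5), tolerance = 1e-12)
  expect_equal(ligand_alignment_factor(4.5), 0)
  expect_equal(ligand_alignment_factor(6), 0)
  expect_error(ligand_alignment_factor(-1), "non-negative")
})

test_that("all penalty factors stay inside [0, 1]", {
  r <- seq(0, 12, by = 0.05)
  expect_true(all(residue_distance_penalty(r) > 0 &
                  residue_distance_penalty(r) <= 1))
  expect_true(all(ligand_alignment_factor(r) >= 0 &
                  ligand_alignment_factor(r) <= 1))
  s <- seq(0, 100, by = 0.5)
  expect_true(all(sasa_penalty(s) >= 0 & sasa_penalty(s) <= 1))
})

test_that("per-pair RMSD uses CA plus CB except for glycine", {
  a <- toy_site("LEU", ca = c(0, 0, 0), cb = c(1.5, 0, 0),
                rel_sasa = 50, d_i = 3)
  b <- toy_site("LEU", ca = c(0, 0, 0), cb = c(1.5, 2, 0),
                rel_sasa = 50, d_i = 3)
  id <- cpassr:::.identity_transform()
  expect_equal(pair_rmsd(a$residues[1, ], b$residues[1, ], id,
                         use_cbeta = TRUE), sqrt(2), tolerance = 1e-12)
  expect_equal(pair_rmsd(a$residues[1, ], b$residues[1, ], id,
                         use_cbeta = FALSE), 0)
  g <- toy_site("GLY", ca = c(0, 0, 0), rel_sasa = 50, d_i = 3)
  expect_equal(pair_rmsd(g$residues[1, ], b$residues[1, ], id,
                         use_cbeta = TRUE), 0)
})

test_that("ligand RMSD maps the smaller ligand onto the larger", {
  la <- toy_ligand(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)))
  id <- cpassr:::.identity_transform()
  expect_equal(ligand_rmsd(la, la, id), 0)
  lb <- toy_ligand(rbind(c(1, 0, 0), c(11, 0, 0), c(21, 0, 0)))
  expect_equal(ligand_rmsd(la, lb, id), 1, tolerance = 1e-12)

  set.seed(8)
  small <- toy_ligand(matrix(rnorm(9, sd = 2), 3))
  big <- toy_ligand(matrix(rnorm(15, sd = 2), 5))
  got <- ligand_rmsd(small, big, id)
  # brute force over every atom pair
  d <- cpassr:::.cross_dist(cpassr:::.ligand_heavy_xyz(small),
                            cpassr:::.ligand_heavy_xyz(big))
  expect_equal(got, sqrt(mean(apply(d, 1, min)^2)), tolerance = 1e-12)
  # symmetric choice of the smaller side
  expect_equal(ligand_rmsd(big, small, id), got, tolerance = 1e-12)
})

test_that("percent similarity is the ratio to the reference score", {
  expect_equal(percent_similarity(41.3, 82.6), 50)
  expect_equal(percent_similarity(0, 5), 0)
  expect_equal(percent_similarity(3, 3), 100)
  expect_error(percent_similarity(1, 0), "positive")
})

two_residue_pair <- function() {
  la <- toy_ligand(rbind(c(0, 2, 0), c(1, 2, 0), c(2, 2, 0)))
  lb <- toy_ligand(rbind(c(0, 3.5, 0), c(1, 3.5, 0)))
  a <- toy_site(c("ALA", "LEU"),
                ca = rbind(c(0, 0, 0), c(5, 0, 0)),
                cb = rbind(c(1.53, 0, 0), c(5, 1.53, 0)),
                rel_sasa = c(40, 80), d_i = c(2, 4), ligand = la)
  b <- toy_site(c("SER", "LEU"),
                ca = rbind(c(2, 0, 0), c(5, 0.8, 0)),
                cb = rbind(c(1.53, 1, 0), c(5, 2.33, 0)),
                rel_sasa = c(55, 80), d_i = c(2, 4), ligand = lb)
  list(a = a, b = b)
}

test_that("a worked two-residue example reproduces the full formula", {
  p <- two_residue_pair()
  sim <- score_alignment(p$a, p$b, identity_alignment(2))
  # every term written out by hand:
  #   ligand: 2-atom ligand maps onto the 3-atom one, nearest distances all
  #   1.5 -> RMSD 1.5, corrected 1.0 -> factor log5(4)
  #   pair 1 (ALA-SER): weight 2/2, dSASA 15, RMSD sqrt((2^2+1^2)/2)
  #   pair 2 (LEU-LEU): weight 2/4, dSASA 0, RMSD 0.8 (free region)
  expected <- log(5 - 1.0, 5) *
    (1.0 * (log10(100 - 15) - 1) * exp(-(sqrt(2.5) - 1)^2) * 0.0063 +
     0.5 * 1 * 1 * 0.0371)
  expect_equal(sim$s_ab, expected, tolerance = 1e-9)
  expect_equal(sim$ligand_rmsd_raw, 1.5, tolerance = 1e-12)
  # breakdown self-consistency
  expect_equal(sim$s_ab,
               sim$ligand_factor * sum(sim$pair_breakdown$contribution),
               tolerance = 1e-9)
  # self-score: weights 1 and 0.5 against ALA and LEU self-probabilities
  expect_equal(sim$s_aa, 1 * 0.0215 + 0.5 * 0.0371, tolerance = 1e-12)
  expect_equal(sim$percent, 100 * sim$s_ab / sim$s_aa, tolerance = 1e-9)
})

test_that("self-alignment scores 100 percent with unit penalties", {
  site <- fixture_site(make_site_structure(fixture_spec(seed = 31)))
  sim <- score_alignment(site, site, identity_alignment(site_size(site)))
  expect_equal(sim$percent, 100, tolerance = 1e-9)
  expect_true(all(sim$pair_breakdown$dist_penalty == 1))
  expect_true(all(sim$pair_breakdown$sasa_penalty == 1))
  expect_equal(sim$ligand_factor, 1)
  w <- sort(sim$pair_breakdown$dist_weight, decreasing = TRUE)
  expect_equal(w[1], 1)                  # closest residue weighs 1
  expect_true(all(w <= 1))
})

test_that("disabling a penalty never decreases the score", {
  p <- two_residue_pair()
  al <- identity_alignment(2)
  full <- score_alignment(p$a, p$b, al, options = score_options())$s_ab
  no_sasa <- score_alignment(p$a, p$b, al,
    options = score_options(use_sasa = FALSE))$s_ab
  no_lig <- score_alignment(p$a, p$b, al,
    options = score_options(use_ligand_rmsd = FALSE))$s_ab
  v1 <- score_alignment(p$a, p$b, al,
    options = score_options(version = "v1"))$s_ab
  expect_gte(no_sasa, full)
  expect_gte(no_lig, full)
  expect_gte(v1, full)
})

test_that("v1 and v2 agree when every added term sits at no-penalty", {
  la <- toy_ligand(rbind(c(0, 2, 0), c(1, 2, 0)))
  a <- toy_site(c("HIS", "TRP", "GLU"),
                ca = rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)),
                cb = rbind(c(1, 1, 0), c(4, 1, 0), c(1, 4, 0)),
                rel_sasa = c(30, 60, 90), d_i = c(2, 3, 4), ligand = la)
  al <- identity_alignment(3)
  v1 <- score_alignment(a, a, al, options = score_options(version = "v1"))
  v2 <- score_alignment(a, a, al, options = score_options(version = "v2"))
  expect_equal(v1$s_ab, v2$s_ab, tolerance = 1e-12)
})

test_that("manual sites always disable the ligand factor", {
  p <- two_residue_pair()
  m <- toy_site(c("ALA", "LEU"),
                ca = rbind(c(0, 0, 0), c(5, 0, 0)),
                cb = rbind(c(1.53, 0, 0), c(5, 1.53, 0)),
                rel_sasa = c(40, 80), d_i = c(2, 4))   # no ligand: manual
  sim <- score_alignment(m, p$b, identity_alignment(2))
  expect_equal(sim$ligand_factor, 1)
  expect_true(is.na(sim$ligand_rmsd_raw))
})
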