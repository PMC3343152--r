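canon <- function(phi, psi) {
  ens <- conformation_ensemble(
    phi = matrix(c(NA, phi, 0), 1), psi = matrix(c(0, psi, NA), 1),
    omega = matrix(c(180, 180, NA), 1), residue_names = rep("GLN", 3))
  assign_regions_hard(ens)$labels[1, 2]
}

test_that("canonical (phi, psi) points classify into their regions", {
  expect_equal(canon(-57, -47), "alphaR")
  expect_equal(canon(60, 45), "alphaL")
  expect_equal(canon(-75, 150), "PPII")
  expect_equal(canon(-140, 150), "beta")
  expect_equal(canon(-75, -170), "PPII")   # wrapped psi branch
  expect_equal(canon(-140, -170), "beta")
})

test_that("hard assignment is a full partition of the torus", {
  set.seed(31)
  n <- 500
  phi <- matrix(wrap_angle(runif(n * 6, -180, 180)), n, 6)
  psi <- matrix(wrap_angle(runif(n * 6, -180, 180)), n, 6)
  omg <- matrix(180, n, 6)
  phi[, 1] <- NA; psi[, 6] <- NA; omg[, 6] <- NA
  ens <- conformation_ensemble(phi, psi, omg, rep("GLN", 6))
  lab <- assign_regions_hard(ens)
  defined <- !is.na(ens$phi) & !is.na(ens$psi)
  expect_true(all(!is.na(lab$labels[defined])))
  expect_true(all(is.na(lab$labels[!defined])))
  pops <- mean_region_populations(lab)
  expect_equal(sum(pops[1:4]), 100, tolerance = 0.1)
})

test_that("clustered assignment agrees with hard assignment on separated blobs", {
  spec <- synthetic_spec(300, 40, within_sd = 20, seed = 32)
  ens <- generate_ensemble(spec)$ensemble
  hard <- assign_regions_hard(ens)
  cl <- assign_regions_cluster(ens)
  ok <- !is.na(hard$labels)
  expect_gte(mean(hard$labels[ok] == cl$labels[ok]), 0.95)
})

test_that("clustering recovers displaced blobs that hard boundaries split", {
  set.seed(33)
  n_half <- 2000
  # blob A inside alphaR but drifted toward the PPII border; blob B inside
  # PPII; both spill across psi = 50 where the hard boundary sits. Smaller
  # blobs at the alphaL and beta centers keep those clusters anchored.
  psiA <- wrap_angle(rnorm(n_half, 35, 20))
  psiB <- wrap_angle(rnorm(n_half, 95, 20))
  phiAB <- wrap_angle(rnorm(2 * n_half, -70, 10))
  phiL <- wrap_angle(rnorm(n_half / 2, 57, 10))
  psiL <- wrap_angle(rnorm(n_half / 2, 47, 10))
  phiB2 <- wrap_angle(rnorm(n_half / 2, -140, 10))
  psiB2 <- wrap_angle(rnorm(n_half / 2, 150, 10))
  n_tot <- 3 * n_half
  phi <- cbind(NA_real_, c(phiAB, phiL, phiB2), 0)
  psi <- cbind(0, c(psiA, psiB, psiL, psiB2), NA_real_)
  omg <- cbind(180, 180, NA_real_)[rep(1, n_tot), ]
  ens <- conformation_ensemble(phi, psi, omg, rep("GLN", 3))
  isAB <- seq_len(2 * n_half)
  truth <- rep(c("alphaR", "PPII"), each = n_half)
  hard <- assign_regions_hard(ens)$labels[isAB, 2]
  cl <- assign_regions_cluster(ens)$labels[isAB, 2]
  acc_hard <- mean(hard == truth)
  acc_cl <- mean(cl == truth)
  expect_gt(acc_cl, acc_hard)
  expect_gte(acc_cl, 0.90)
})

test_that("degenerate inputs fall back gracefully", {
  # all points at one center: no crash, single label
  lab <- matrix("alphaR", 200, 4)
  ens <- ens_from_labels(lab)
  cl <- assign_regions_cluster(ens)
  got <- cl$labels[!is.na(cl$labels)]
  expect_true(all(got == "alphaR"))
  # fewer than 100 defined pairs: falls back to hard with a warning
  small <- generate_ensemble(synthetic_spec(5, 5, seed = 3))$ensemble
  expect_warning(cl2 <- assign_regions_cluster(small), "hard")
  expect_identical(cl2$labels, assign_regions_hard(small)$labels)
})

test_that("grid width must divide 360", {
  ens <- generate_ensemble(synthetic_spec(50, 10, seed = 4))$ensemble
  expect_error(assign_regions_cluster(ens, grid_deg = 7), "divide 360")
})

test_that("population profiles report per-residue percentages", {
  lab <- labels_object(rbind(c("alphaR", "alphaR", "PPII"),
                             c("alphaR", "alphaL", "beta"),
                             c("alphaR", "PPII", "alphaL"),
                             c("alphaR", "beta", "alphaR")))
  prof <- region_population_profile(lab)
  expect_equal(prof$alphaR[1], 100)
  expect_equal(unlist(prof[2, c("alphaR", "alphaL", "PPII", "beta")],
                      use.names = FALSE), c(25, 25, 25, 25))
  expect_error(region_population_profile(lab, residue_filter = "TRP"),
               "no residues")
})

test_that("generator marginals are recovered within binomial error", {
  spec <- q40_like(n_conformations = 10000, seed = 35)
  g <- generate_ensemble(spec)
  lab <- assign_regions_hard(g$ensemble)
  prof <- region_population_profile(lab)
  prof <- prof[prof$n_defined > 0, ]  # terminal residues have no defined label
  # 95% binomial CI at p = 0.80, n = 10000 is about +/- 0.8 percentage points;
  # allow 3 sigma plus the label-recovery error of the 15-degree scatter
  expect_true(all(abs(prof$alphaR - 80) < 3.5))
  expect_true(all(abs(prof$beta - 8) < 2.5))
})

test_that("alpha-tilde mask implements the alternation definition", {
  lab <- labels_object(matrix(c("alphaR", "alphaL", "alphaR", "beta"), 1))
  expect_equal(alpha_tilde_mask(lab)[1, ], c(1L, 1L, 1L, 0L))
  lab2 <- labels_object(matrix(c("alphaL", "alphaR"), 1))
  expect_equal(alpha_tilde_mask(lab2)[1, ], c(1L, 1L))
  lab3 <- labels_object(matrix("alphaR", 3, 5))
  expect_true(all(alpha_tilde_mask(lab3) == 0L))
})

test_that("alpha-tilde mask of the reversed sequence is the reversed mask", {
  spec <- synthetic_spec(200, 12,
                         region_marginals = c(alphaR = 0.5, alphaL = 0.3,
                                              PPII = 0.1, beta = 0.1),
                         seed = 36)
  lab <- sample_regions(spec)
  fwd <- alpha_tilde_mask(lab)
  rev_lab <- labels_object(lab$labels[, ncol(lab$labels):1])
  expect_identical(alpha_tilde_mask(rev_lab), fwd[, ncol(fwd):1])
})

test_that("mean populations and alpha-tilde content match enumeration", {
  lab <- labels_object(matrix("alphaR", 5, 6))
  pops <- mean_region_populations(lab)
  expect_equal(unname(pops), c(100, 0, 0, 0, 0))
  # strict alternation in every conformation -> 100% alpha-tilde
  alt <- labels_object(matrix(rep(c("alphaR", "alphaL"), 3), 10, 6,
                              byrow = TRUE))
  expect_equal(unname(mean_region_populations(alt)["alpha_tilde"]), 100)
  # i.i.d. labels: empirical alpha-tilde percentage matches the brute-force
  # enumeration of label neighbourhoods
  p <- c(alphaR = 0.8, alphaL = 0.05, PPII = 0.07, beta = 0.08)
  spec <- synthetic_spec(20000, 10, region_marginals = p, seed = 37)
  lab2 <- sample_regions(spec)
  expected <- 100 * oracle_alpha_tilde_prob(p, 10)
  got <- mean_region_populations(lab2)["alpha_tilde"]
  expect_lt(abs(got - expected), 1.0)
})

test_that("region percentages are invariant under conformation permutation", {
  spec <- synthetic_spec(500, 8, seed = 38)
  lab <- sample_regions(spec)
  perm <- labels_object(lab$labels[sample(nrow(lab$labels)), ])
  expect_equal(mean_region_populations(lab), mean_region_populations(perm))
})
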