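test_that("amide hydrogens follow the DSSP placement convention", {
  h <- ideal_helix(6)
  conf <- h$coords[[1]]
  H <- place_backbone_hydrogen(conf, h$residue_names)
  expect_true(all(is.na(H[1, ])))
  d <- sqrt(rowSums((H[-1, ] - conf[-1, "N", ])^2))
  expect_equal(d, rep(1, 5), tolerance = 1e-12)
  # prolines get no hydrogen
  H2 <- place_backbone_hydrogen(conf, c("GLN", "PRO", rep("GLN", 4)))
  expect_true(all(is.na(H2[2, ])))
})

test_that("Kabsch-Sander energy matches direct formula evaluation", {
  # symmetric degenerate arrangement: all four distances equal -> E = 0
  e0 <- kabsch_sander_energy(N = c(0, 0, 0), H = c(1, 0, 0),
                             C = c(0.5, 1, 0), O = c(0.5, -1, 0))
  expect_equal(as.numeric(e0), 0, tolerance = 1e-12)
  # canonical linear H-bond: N-H...O=C collinear, r_ON = 2.9 A
  N <- c(0, 0, 0); H <- c(1, 0, 0); O <- c(2.9, 0, 0); C <- c(4.131, 0, 0)
  e <- kabsch_sander_energy(N, H, C, O)
  ref <- 0.084 * 332 * (1 / 2.9 + 1 / 3.131 - 1 / 1.9 - 1 / 4.131)
  expect_equal(as.numeric(e), ref, tolerance = 1e-12)
  expect_lt(as.numeric(e), -0.5)
  # distant pair: negligible energy
  far <- kabsch_sander_energy(N, H, C + c(15, 0, 0), O + c(15, 0, 0))
  expect_lt(abs(as.numeric(far)), 0.05)
})

test_that("ideal helix fixture is assigned helical codes and i -> i-4 bonds", {
  h <- ideal_helix(12)
  ssr <- assign_ss(h)
  expect_true(all(ssr$ss[1, 2:11] == "H"))
  hb <- ssr$hbonds[[1]]
  expect_true(all(hb$donor - hb$acceptor == 4))
  expect_true(all(hb$energy < -0.5))
  # amide H points back toward the acceptor O: N-H...O angle > 140 degrees
  conf <- h$coords[[1]]
  H <- place_backbone_hydrogen(conf, h$residue_names)
  ang <- sapply(seq_len(nrow(hb)), function(j) {
    hn <- H[hb$donor[j], ] - conf[hb$donor[j], "N", ]
    ho <- conf[hb$acceptor[j], "O", ] - H[hb$donor[j], ]
    acos(sum(hn * ho) / sqrt(sum(hn^2) * sum(ho^2))) * 180 / pi
  })
  expect_true(all(180 - ang > 140))
  stats <- helix_segment_stats(ssr$ss, h$residue_names)
  expect_equal(unname(stats$segment_count_distribution["1"]), 100)
})

test_that("extended and PPII chains have no hydrogen bonds", {
  for (ens in list(extended_beta(12), ppii_helix(12))) {
    ssr <- assign_ss(ens)
    expect_equal(nrow(ssr$hbonds[[1]]), 0)
    expect_true(all(ssr$ss[1, ] %in% c("C", "S")))
  }
})

test_that("antiparallel hairpin fixture gets ladder codes and one hairpin", {
  hp <- beta_hairpin("turn2")
  ssr <- assign_ss(hp)
  lab <- assign_regions_hard(hp)
  ss <- ssr$ss[1, ]
  expect_true(any(ss[2:5] == "E") && any(ss[8:11] == "E"))
  expect_true(all(ss[6:7] %in% c("T", "S")))
  found <- detect_hairpins(lab, ssr, "beta")
  expect_equal(nrow(found), 1)
  expect_equal(found$type, "beta_hairpin")
})

test_that("bend-loop hairpin fixture yields exactly one hairpin", {
  hp <- beta_hairpin()
  ssr <- assign_ss(hp)
  lab <- assign_regions_hard(hp)
  found <- detect_hairpins(lab, ssr, "beta")
  expect_equal(nrow(found), 1)
  strands <- detect_strands(lab, ssr$hbonds, "beta")
  expect_equal(nrow(strands), 2)
  expect_equal(strands$length, c(4, 4))
  # removing all H-bonds kills the hairpin and isolates the strands
  no_hb <- ssr
  no_hb$hbonds <- lapply(no_hb$hbonds, function(h) h[0, ])
  expect_equal(nrow(detect_hairpins(lab, no_hb, "beta")), 0)
  iso <- detect_strands(lab, no_hb$hbonds, "beta")
  expect_true(all(iso$isolated))
  # a connector with no bend/turn-coded residue fails the geometry clause
  flat <- ssr
  flat$ss[1, ] <- "C"
  expect_equal(nrow(detect_hairpins(lab, flat, "beta")), 0)
})

test_that("strand detection honours pattern, length and isolation", {
  lab <- labels_object(matrix(c("beta", "beta", "beta", "alphaR", "PPII"), 1))
  no_bonds <- list(data.frame(donor = integer(), acceptor = integer(),
                              energy = numeric()))
  s3 <- detect_strands(lab, no_bonds, "beta", min_len = 3)
  expect_equal(nrow(s3), 1)
  expect_true(s3$isolated)
  expect_equal(nrow(detect_strands(lab, no_bonds, "beta", min_len = 4)), 0)
  # alternation: both phases accepted, broken alternation rejected
  lab2 <- labels_object(matrix(c("alphaR", "alphaL", "alphaR", "alphaL",
                                 "alphaR"), 1))
  a <- detect_strands(lab2, NULL, "alpha_tilde")
  expect_equal(a$length, 5)
  expect_true(is.na(a$isolated))
  lab3 <- labels_object(matrix(c("alphaR", "alphaR", "alphaL"), 1))
  expect_equal(nrow(detect_strands(lab3, NULL, "alpha_tilde")), 0)
  expect_error(detect_strands(lab3, NULL, "gamma"), "arg")
})

test_that("every alpha-tilde strand residue carries the alpha-tilde mask", {
  spec <- synthetic_spec(300, 15,
                         region_marginals = c(alphaR = 0.45, alphaL = 0.45,
                                              PPII = 0.05, beta = 0.05),
                         seed = 41)
  lab <- sample_regions(spec)
  mask <- alpha_tilde_mask(lab)
  strands <- detect_strands(lab, NULL, "alpha_tilde", min_len = 3)
  for (j in seq_len(nrow(strands)))
    expect_true(all(mask[strands$conformation[j],
                         strands$start[j]:strands$end[j]] == 1L))
  # min_len = 4 instances are a subset of min_len = 3 instances
  s4 <- detect_strands(lab, NULL, "alpha_tilde", min_len = 4)
  key <- function(d) paste(d$conformation, d$start, d$end)
  expect_true(all(key(s4) %in% key(strands)))
})

test_that("helix content and segment counts match a run-length oracle", {
  set.seed(42)
  codes <- c("H", "G", "I", "T", "S", "C", "E", "B")
  ss <- matrix(sample(codes, 50 * 20, replace = TRUE,
                      prob = c(.3, .1, .02, .15, .1, .3, .02, .01)), 50, 20)
  stats <- helix_segment_stats(ss, rep("GLN", 20))
  expect_equal(stats$alpha_content, 100 * mean(ss == "H"))
  oracle_counts <- apply(ss, 1, function(s) length(oracle_segments(s)))
  got <- as.numeric(stats$segment_count_distribution)
  ora <- 100 * tabulate(oracle_counts + 1L,
                        nbins = length(got)) / nrow(ss)
  expect_equal(got, ora)
  # arithmetic case: one 10-residue H run per conformation in a 40-mer
  ss2 <- matrix("C", 30, 40)
  ss2[, 11:20] <- "H"
  st2 <- helix_segment_stats(ss2, rep("GLN", 40))
  expect_equal(st2$alpha_content, 25)
  expect_equal(unname(st2$segment_count_distribution["1"]), 100)
})

test_that("turn typing distinguishes type I-beta, other beta and gamma", {
  phi <- c(-140, -60, -90, -140, -140)
  psi <- c(150, -30, 0, 150, 150)
  ens <- build_backbone(
    conformation_ensemble(matrix(c(NA, phi[-1]), 1), matrix(c(psi[-5], NA), 1),
                          matrix(c(rep(180, 4), NA), 1), rep("GLN", 5)))
  ssr <- assign_ss(ens)
  lab <- assign_regions_hard(ens)
  expect_true(any(ssr$hbonds[[1]]$donor - ssr$hbonds[[1]]$acceptor == 3))
  ct <- classify_turns(ssr, lab)
  expect_equal(nrow(ct$turns), 1)
  expect_equal(ct$turns$turn_type, "beta_I")
  # fabricate: same geometry, but middle labels not alphaR -> other beta
  lab2 <- lab
  lab2$labels[1, 2] <- "PPII"
  expect_equal(classify_turns(ssr, lab2)$turns$turn_type, "beta_other")
  # fabricated i -> i+2 bond only -> gamma turn
  ssr2 <- ssr
  ssr2$hbonds[[1]] <- data.frame(donor = 4L, acceptor = 2L, energy = -1)
  ct2 <- classify_turns(ssr2, lab)
  expect_equal(ct2$turns$turn_type, "gamma")
  expect_equal(unname(ct2$summary["beta_count"]), 0)
})

test_that("motif prevalence equals a brute-force any() scan", {
  set.seed(43)
  inst <- data.frame(conformation = sample(1:200, 37, replace = TRUE),
                     type = "beta_strand", start = 3L, end = 5L,
                     length = 3L, isolated = FALSE, min_len = 3L)
  ens <- generate_ensemble(synthetic_spec(200, 10, seed = 5))$ensemble
  prev <- motif_prevalence(inst, ens)
  expect_equal(prev$prevalence_pct, oracle_prevalence(inst, 200))
  # 3 of 200 conformations -> 1.5%
  inst2 <- inst[match(unique(inst$conformation)[1:3], inst$conformation), ]
  expect_equal(motif_prevalence(inst2, ens)$prevalence_pct, 1.5)
  # spans touching prolines are excluded
  ens_p <- generate_ensemble(q40p6_like(50, seed = 6))$ensemble
  inst3 <- data.frame(conformation = 1:50, type = "ppii_run", start = 40L,
                      end = 42L, length = 3L, isolated = NA, min_len = 3L)
  expect_equal(nrow(motif_prevalence(inst3, ens_p)), 0)
})

test_that("the ideal helix has full interior helicity and no strands", {
  h <- ideal_helix(12)
  ssr <- assign_ss(h)
  lab <- assign_regions_hard(h)
  expect_true(all(ssr$ss[1, 2:11] == "H"))
  expect_equal(nrow(detect_strands(lab, ssr$hbonds, "beta")), 0)
  expect_equal(nrow(detect_strands(lab, ssr$hbonds, "ppii")), 0)
  expect_equal(nrow(detect_hairpins(lab, ssr, "beta")), 0)
})
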