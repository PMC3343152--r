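# Synthetic conformational ensembles with controlled statistical structure:
# per-residue Ramachandran-region marginals, a latent-Gaussian copula with a
# damped-cosine correlation kernel (independent control of decay length and
# oscillation period), within-region wrapped-Gaussian scatter, and prolyl
# omega cis/trans states. Backbones are reconstructed from dihedrals with
# ideal geometry so hydrogen-bond and Rg analyses work without MD input.

#' Standard backbone geometry constants
#'
#' Ideal bond lengths and angles used by [build_backbone()].
#'
#' @return list of bond lengths (Angstrom) and bond angles (degrees).
#' @export
backbone_geometry <- function() {
  list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
       a_n_ca_c = 111.0, a_ca_c_n = 116.6, a_c_n_ca = 121.7)
}

#' Specification of a synthetic ensemble
#'
#' @param n_conformations,n_residues ensemble dimensions.
#' @param residue_names 3-letter codes; defaults to all GLN.
#' @param region_marginals per-residue probabilities over regions, either a
#'   named length-4 vector (recycled) or an `n_residues x 4` matrix with
#'   columns alphaR, alphaL, PPII, beta; rows must sum to 1.
#' @param kernel list with `a` (correlation amplitude in `[0, 1)`), `lambda`
#'   (decay length, residues) and `period` (oscillation period, residues >= 2)
#'   of the latent damped-cosine kernel
#'   `k(d) = a exp(-d/lambda) cos(2 pi d / period) + (1 - a) [d = 0]`.
#' @param within_sd wrapped-Gaussian scatter (degrees) of (phi, psi) around
#'   the region centers.
#' @param omega_trans_prob probability that a prolyl bond is trans.
#' @param seed integer seed making the ensemble reproducible.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_conformations, n_residues,
                           residue_names = rep("GLN", n_residues),
                           region_marginals = c(alphaR = 0.80, alphaL = 0.05,
                                                PPII = 0.07, beta = 0.08),
                           kernel = list(a = 0, lambda = 1, period = 7),
                           within_sd = 15, omega_trans_prob = 0.85,
                           seed = 1L) {
  if (is.null(dim(region_marginals)))
    region_marginals <- matrix(region_marginals[REGIONS], n_residues, 4,
                               byrow = TRUE, dimnames = list(NULL, REGIONS))
  stopifnot(ncol(region_marginals) == 4,
            nrow(region_marginals) == n_residues,
            all(abs(rowSums(region_marginals) - 1) < 1e-9),
            kernel$a >= 0, kernel$a < 1, kernel$lambda > 0,
            kernel$period >= 2, within_sd > 0,
            length(residue_names) == n_residues)
  structure(list(n_conformations = n_conformations, n_residues = n_residues,
                 residue_names = toupper(residue_names),
                 region_marginals = region_marginals, kernel = kernel,
                 within_sd = within_sd, omega_trans_prob = omega_trans_prob,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

kernel_matrix <- function(n, kernel) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- kernel$a * exp(-d / kernel$lambda) * cos(2 * pi * d / kernel$period)
  K <- K + (1 - kernel$a) * diag(n)
  K
}

#' Sample Ramachandran-region labels from a synthetic spec
#'
#' A latent Gaussian field per conformation is drawn from a stationary
#' process over residue index with the spec's damped-cosine kernel, mapped
#' through the standard-normal CDF to a uniform, and converted to a region
#' label through the per-residue cumulative marginals in the fixed order
#' beta, PPII, alphaL, alphaR.
#'
#' @param spec a [synthetic_spec].
#' @return a `region_labels` object (method `"synthetic"`).
#' @export
sample_regions <- function(spec) {
  n <- spec$n_residues
  K <- kernel_matrix(n, spec$kernel)
  L <- tryCatch(chol(K + 1e-8 * diag(n)),
                error = function(e) stop("kernel covariance is not positive ",
                                         "semidefinite: ", conditionMessage(e)))
  set.seed(spec$seed)
  z <- matrix(rnorm(spec$n_conformations * n), spec$n_conformations, n) %*% L
  u <- pnorm(z / sqrt(diag(K))[col(z)])
  order_cut <- c("beta", "PPII", "alphaL", "alphaR")
  cum <- t(apply(spec$region_marginals[, order_cut, drop = FALSE], 1, cumsum))
  lab <- matrix(NA_character_, spec$n_conformations, n)
  for (i in seq_len(n))
    lab[, i] <- order_cut[1L + findInterval(u[, i], cum[i, 1:3])]
  new_region_labels(lab, "synthetic", spec$residue_names)
}

rwrapnorm <- function(n, mean, sd) wrap_angle(rnorm(n, mean, sd))

#' Sample dihedral angles conditional on region labels
#'
#' (phi, psi) pairs are drawn from a wrapped Gaussian around the canonical
#' center of each residue's region; omega is 180 degrees for non-prolyl bonds
#' and trans/cis (180/0) with probability `omega_trans_prob` for prolyl
#' bonds, all with 5-degree wrapped jitter. Terminal undefined angles are NA.
#'
#' @param labels a `region_labels` object (e.g. from [sample_regions()]).
#' @param spec the [synthetic_spec] that produced the labels.
#' @param centers 4 x 2 matrix of region (phi, psi) centers.
#' @return a [conformation_ensemble] without coordinates.
#' @export
sample_dihedrals <- function(labels, spec,
                             centers = region_boundaries()$centers) {
  lab <- labels$labels
  n_conf <- nrow(lab); n <- ncol(lab)
  set.seed(spec$seed + 1L)
  idx <- match(lab, rownames(centers))
  phi <- matrix(rwrapnorm(length(idx), centers[idx, 1], spec$within_sd),
                n_conf, n)
  psi <- matrix(rwrapnorm(length(idx), centers[idx, 2], spec$within_sd),
                n_conf, n)
  # prolines sit near the PPII basin with restricted phi
  pro <- which(spec$residue_names == "PRO")
  if (length(pro)) {
    phi[, pro] <- rwrapnorm(n_conf * length(pro), -75, 5)
    psi[, pro] <- rwrapnorm(n_conf * length(pro), 150, spec$within_sd)
  }
  omega <- matrix(rwrapnorm(n_conf * n, 180, 5), n_conf, n)
  prolyl_bonds <- pro[pro > 1] - 1L
  for (b in prolyl_bonds) {
    cis <- runif(n_conf) >= spec$omega_trans_prob
    omega[cis, b] <- rwrapnorm(sum(cis), 0, 5)
  }
  phi[, 1] <- NA_real_
  psi[, n] <- NA_real_
  omega[, n] <- NA_real_
  conformation_ensemble(phi, psi, omega, spec$residue_names,
                        peptide_name = "synthetic")
}

# Place atom D given A, B, C, bond length C-D, bond angle B-C-D (deg) and
# torsion A-B-C-D (deg); the torsion satisfies compute_dihedral(A,B,C,D) = chi.
nerf_place <- function(A, B, C, L, theta_deg, chi_deg) {
  th <- theta_deg * pi / 180; ch <- chi_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + L * (-cos(th) * bc + sin(th) * (cos(ch) * m + sin(ch) * n))
}

#' Build backbone coordinates from dihedral angles
#'
#' Sequential natural-extension (torsion-driven) chain construction with
#' fixed ideal geometry. Carbonyl oxygens are placed in the CA-C-N(i+1)
#' plane opposite the nitrogen at 1.231 Angstrom. Terminal undefined angles
#' are replaced by 180 degrees for placement only; the stored dihedrals are
#' unchanged and recomputing them from the coordinates reproduces the inputs
#' to within 1e-4 degrees.
#'
#' @param ens a [conformation_ensemble] (angles only).
#' @param geom geometry constants from [backbone_geometry()].
#' @return the ensemble with `coords` populated.
#' @export
build_backbone <- function(ens, geom = backbone_geometry()) {
  n <- ens$n_residues
  coords <- vector("list", ens$n_conformations)
  for (k in seq_len(ens$n_conformations)) {
    phi <- ens$phi[k, ]; psi <- ens$psi[k, ]; omg <- ens$omega[k, ]
    phi[is.na(phi)] <- 180; psi[is.na(psi)] <- 180; omg[is.na(omg)] <- 180
    arr <- array(NA_real_, c(n, 4, 3),
                 dimnames = list(NULL, BACKBONE_ATOMS, c("x", "y", "z")))
    arr[1, "N", ] <- c(0, 0, 0)
    arr[1, "CA", ] <- c(geom$b_n_ca, 0, 0)
    a <- geom$a_n_ca_c * pi / 180
    arr[1, "C", ] <- arr[1, "CA", ] +
      geom$b_ca_c * c(-cos(a), sin(a), 0)
    for (i in seq_len(n - 1)) {
      arr[i + 1, "N", ] <- nerf_place(arr[i, "N", ], arr[i, "CA", ],
                                      arr[i, "C", ], geom$b_c_n,
                                      geom$a_ca_c_n, psi[i])
      arr[i + 1, "CA", ] <- nerf_place(arr[i, "CA", ], arr[i, "C", ],
                                       arr[i + 1, "N", ], geom$b_n_ca,
                                       geom$a_c_n_ca, omg[i])
      arr[i + 1, "C", ] <- nerf_place(arr[i, "C", ], arr[i + 1, "N", ],
                                      arr[i + 1, "CA", ], geom$b_ca_c,
                                      geom$a_n_ca_c, phi[i + 1])
    }
    # carbonyl oxygens: bisector of C->CA and C->N(i+1), flipped, in-plane
    for (i in seq_len(n)) {
      C <- arr[i, "C", ]; CA <- arr[i, "CA", ]
      ref <- if (i < n) arr[i + 1, "N", ]
             else nerf_place(arr[i, "N", ], CA, C, geom$b_c_n,
                             geom$a_ca_c_n, psi[i])
      u <- (C - ref) / sqrt(sum((C - ref)^2)) + (C - CA) / sqrt(sum((C - CA)^2))
      arr[i, "O", ] <- C + geom$b_c_o * u / sqrt(sum(u^2))
    }
    coords[[k]] <- arr
  }
  ens$coords <- coords
  ens
}

angles_ensemble <- function(phi, psi, residue_names, omega = NULL,
                            n_conf = 1L, name = "fixture") {
  n <- length(residue_names)
  mk <- function(v) matrix(rep(v, each = n_conf), n_conf, n)
  phi <- mk(rep_len(phi, n)); psi <- mk(rep_len(psi, n))
  omg <- if (is.null(omega)) mk(rep(180, n)) else mk(rep_len(omega, n))
  phi[, 1] <- NA; psi[, n] <- NA; omg[, n] <- NA
  conformation_ensemble(phi, psi, omg, residue_names, peptide_name = name)
}

#' Deterministic test fixtures
#'
#' Small engineered ensembles: `ideal_helix(n)` (phi = -57, psi = -47),
#' `extended_beta(n)` (-140, 150), `ppii_helix(n)` (-75, 150),
#' `alpha_tilde_strand(n)` (alternating alphaR/alphaL centers),
#' `beta_hairpin()` (two 4-residue beta strands around an engineered
#' turn that forms cross-strand hydrogen bonds), and the
#' generator-backed `q40_like()` / `q40p6_like()` specs.
#'
#' The label-based fixtures (`ppii_helix`, `alpha_tilde_strand`,
#' `beta_hairpin`) carry one extra bookend residue at each end: terminal
#' residues have an undefined phi or psi and hence no region label, so the
#' designed motif occupies the `n` labelled interior residues.
#'
#' @param n number of residues carrying the designed pattern.
#' @param name fixture label.
#' @return a [conformation_ensemble] with coordinates (fixtures), or a
#'   [synthetic_spec] (`q40_like`, `q40p6_like`).
#' @export
ideal_helix <- function(n = 12, name = "ideal_helix") {
  build_backbone(angles_ensemble(-57, -47, rep("GLN", n), name = name))
}

#' @rdname ideal_helix
#' @export
extended_beta <- function(n = 12, name = "extended_beta") {
  build_backbone(angles_ensemble(-140, 150, rep("GLN", n), name = name))
}

#' @rdname ideal_helix
#' @export
ppii_helix <- function(n = 12, name = "ppii_helix") {
  build_backbone(angles_ensemble(-75, 150, rep("GLN", n + 2), name = name))
}

#' @rdname ideal_helix
#' @export
alpha_tilde_strand <- function(n = 6, name = "alpha_tilde_strand") {
  phi <- rep(c(-63, 57), length.out = n + 2)
  psi <- rep(c(-43, 47), length.out = n + 2)
  build_backbone(angles_ensemble(phi, psi, rep("GLN", n + 2), name = name))
}

#' @rdname ideal_helix
#' @param variant `"bend3"`: two 4-residue beta strands around a 3-residue
#'   bend-coded loop; `"turn2"`: a tighter two-residue type-II turn whose
#'   strands form an antiparallel ladder (E codes). Both loop geometries were
#'   chosen so that cross-strand Kabsch-Sander hydrogen bonds form.
#' @export
beta_hairpin <- function(variant = c("bend3", "turn2"),
                         name = "beta_hairpin") {
  variant <- match.arg(variant)
  if (variant == "bend3") {
    phi <- c(rep(-140, 5), -60, -90, -90, rep(-140, 5))
    psi <- c(rep(150, 5), 0, -120, 0, rep(150, 5))
  } else {
    phi <- c(rep(-140, 5), -60, 80, rep(-140, 5))
    psi <- c(rep(150, 5), 120, 0, rep(150, 5))
  }
  build_backbone(angles_ensemble(phi, psi, rep("GLN", length(phi)),
                                 name = name))
}

#' @rdname ideal_helix
#' @param n_conformations,a,lambda,period,seed generator settings; see
#'   [synthetic_spec()].
#' @export
q40_like <- function(n_conformations = 10000, a = 0, lambda = 1, period = 7,
                     seed = 1L) {
  synthetic_spec(n_conformations, 40,
                 kernel = list(a = a, lambda = lambda, period = period),
                 seed = seed)
}

#' @rdname ideal_helix
#' @export
q40p6_like <- function(n_conformations = 10000, a = 0, lambda = 1, period = 7,
                       seed = 1L) {
  nm <- c(rep("GLN", 40), rep("PRO", 6))
  marg <- matrix(rep(c(0.80, 0.05, 0.07, 0.08), each = 46), 46, 4,
                 dimnames = list(NULL, REGIONS))
  marg[41:46, ] <- matrix(rep(c(0, 0, 1, 0), each = 6), 6, 4)
  synthetic_spec(n_conformations, 46, residue_names = nm,
                 region_marginals = marg,
                 kernel = list(a = a, lambda = lambda, period = period),
                 omega_trans_prob = 0.85, seed = seed)
}

#' Generate a full synthetic ensemble from a spec
#'
#' Convenience wrapper: [sample_regions()], [sample_dihedrals()], and
#' optionally [build_backbone()].
#'
#' @param spec a [synthetic_spec].
#' @param backbone also reconstruct coordinates.
#' @return list with `ensemble` and the generating `labels`.
#' @export
generate_ensemble <- function(spec, backbone = FALSE) {
  labels <- sample_regions(spec)
  ens <- sample_dihedrals(labels, spec)
  if (backbone) ens <- build_backbone(ens)
  list(ensemble = ens, labels = labels)
}
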