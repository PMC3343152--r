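# Small independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Odds ratio via the ratio-of-odds route (n00/n01) / (n10/n11).
oracle_or <- function(n00, n01, n10, n11) (n00 / n01) / (n10 / n11)

# Free-energy score and SE evaluated directly.
oracle_ddg <- function(n00, n01, n10, n11, temperature = 300) {
  kbt <- 0.0019872 * temperature
  list(score = kbt * (log(n00) + log(n11) - log(n01) - log(n10)),
       se = kbt * sqrt(1 / n00 + 1 / n01 + 1 / n10 + 1 / n11))
}

# Brute-force run-length scan for maximal helix segments in one SS string.
oracle_segments <- function(ss, codes = c("H", "G", "I")) {
  segs <- integer(0)
  len <- 0L
  for (c in c(ss, "X")) {
    if (c %in% codes) len <- len + 1L
    else { if (len > 0) segs <- c(segs, len); len <- 0L }
  }
  segs
}

# Brute-force prevalence: fraction of conformations with >= 1 instance.
oracle_prevalence <- function(instances, n_conf) {
  100 * sum(vapply(seq_len(n_conf),
                   function(k) any(instances$conformation == k), TRUE)) / n_conf
}

# Expected alpha-tilde repeat probability for i.i.d. labels, by enumerating
# neighbourhoods. p is a named probability vector over region labels.
oracle_alpha_tilde_prob <- function(p, n_residues) {
  match1 <- function(c, nb) (c == "alphaR" && nb == "alphaL") ||
                            (c == "alphaL" && nb == "alphaR")
  labs <- names(p)
  # interior residue: P(center matches left or right neighbour)
  p_int <- 0
  for (l in labs) for (c in labs) for (r in labs)
    if (match1(c, l) || match1(c, r))
      p_int <- p_int + p[l] * p[c] * p[r]
  # terminal residue: single neighbour
  p_term <- 0
  for (c in labs) for (nb in labs)
    if (match1(c, nb)) p_term <- p_term + p[c] * p[nb]
  unname((2 * p_term + (n_residues - 2) * p_int) / n_residues)
}

# Build an angles-only ensemble from explicit label -> center mapping, with
# zero scatter, for label-level tests.
ens_from_labels <- function(lab_matrix, residue_names = NULL) {
  centers <- rbind(alphaR = c(-63, -43), alphaL = c(57, 47),
                   PPII = c(-75, 150), beta = c(-140, 150))
  n_conf <- nrow(lab_matrix); n <- ncol(lab_matrix)
  if (is.null(residue_names)) residue_names <- rep("GLN", n)
  idx <- match(lab_matrix, rownames(centers))
  phi <- matrix(centers[idx, 1], n_conf, n)
  psi <- matrix(centers[idx, 2], n_conf, n)
  omg <- matrix(180, n_conf, n)
  phi[, 1] <- NA; psi[, n] <- NA; omg[, n] <- NA
  conformation_ensemble(phi, psi, omg, residue_names)
}

labels_object <- function(lab_matrix, residue_names = NULL) {
  if (is.null(residue_names)) residue_names <- rep("GLN", ncol(lab_matrix))
  structure(list(labels = lab_matrix, method = "hard",
                 residue_names = residue_names),
            class = "region_labels")
}
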