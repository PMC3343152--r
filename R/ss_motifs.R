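# DSSP-subset secondary structure and bespoke extended-motif detection.
#
# Hbond convention used internally: HB[d, a] is TRUE when the amide N-H of
# residue d donates to the carbonyl C=O of residue a (Kabsch-Sander
# "Hbond(a, d)").

KS_CUTOFF <- -0.5   # kcal/mol; below this an H-bond is declared
KS_Q <- 0.084 * 332 # coupling constant of the Kabsch-Sander energy, kcal/mol*A

#' Place amide hydrogens on a backbone conformation
#'
#' DSSP convention: H sits 1.0 Angstrom from N along the unit vector opposite
#' the preceding residue's C=O bond. The first residue and prolines get no H.
#'
#' @param conf backbone array `c(n_residues, 4, 3)` (atoms N, CA, C, O).
#' @param residue_names 3-letter codes (prolines are skipped).
#' @return matrix `[n_residues x 3]` of H coordinates, `NA` rows where absent.
#' @export
place_backbone_hydrogen <- function(conf, residue_names) {
  n <- dim(conf)[1]
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (residue_names[i] == "PRO") next
    CO <- conf[i - 1, "O", ] - conf[i - 1, "C", ]
    if (anyNA(CO)) next
    H[i, ] <- conf[i, "N", ] - CO / sqrt(sum(CO^2))
  }
  H
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol, with a
#' bond declared when E < -0.5. Distances are floored at 0.5 Angstrom; a
#' floored pair is flagged and never counted as bonded.
#'
#' @param N,H donor nitrogen and amide hydrogen coordinates (length 3).
#' @param C,O acceptor carbonyl carbon and oxygen coordinates (length 3).
#' @return energy in kcal/mol with attribute `capped` (logical).
#' @export
kabsch_sander_energy <- function(N, H, C, O) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  r <- c(ON = d(O, N), CH = d(C, H), OH = d(O, H), CN = d(C, N))
  capped <- any(r < 0.5)
  r <- pmax(r, 0.5)
  e <- KS_Q * (1 / r["ON"] + 1 / r["CH"] - 1 / r["OH"] - 1 / r["CN"])
  structure(unname(e), capped = capped)
}

# All backbone H-bonds of one conformation. Returns data.frame(donor,
# acceptor, energy) with |donor - acceptor| >= 2 and E < cutoff.
find_hbonds <- function(conf, residue_names, cutoff = KS_CUTOFF) {
  n <- dim(conf)[1]
  H <- place_backbone_hydrogen(conf, residue_names)
  donors <- which(!is.na(H[, 1]))
  acceptors <- which(!is.na(conf[, "O", 1]) & !is.na(conf[, "C", 1]))
  out <- list()
  Nc <- conf[, "N", , drop = FALSE]; dim(Nc) <- c(n, 3)
  Cc <- conf[, "C", , drop = FALSE]; dim(Cc) <- c(n, 3)
  Oc <- conf[, "O", , drop = FALSE]; dim(Oc) <- c(n, 3)
  for (dn in donors) {
    acc <- acceptors[abs(acceptors - dn) >= 2]
    if (!length(acc)) next
    rON <- sqrt(colSums((t(Oc[acc, , drop = FALSE]) - Nc[dn, ])^2))
    rCH <- sqrt(colSums((t(Cc[acc, , drop = FALSE]) - H[dn, ])^2))
    rOH <- sqrt(colSums((t(Oc[acc, , drop = FALSE]) - H[dn, ])^2))
    rCN <- sqrt(colSums((t(Cc[acc, , drop = FALSE]) - Nc[dn, ])^2))
    capped <- rON < 0.5 | rCH < 0.5 | rOH < 0.5 | rCN < 0.5
    e <- KS_Q * (1 / pmax(rON, 0.5) + 1 / pmax(rCH, 0.5) -
                 1 / pmax(rOH, 0.5) - 1 / pmax(rCN, 0.5))
    sel <- e < cutoff & !capped
    if (any(sel))
      out[[length(out) + 1L]] <- data.frame(donor = dn, acceptor = acc[sel],
                                            energy = e[sel])
  }
  if (!length(out))
    return(data.frame(donor = integer(), acceptor = integer(),
                      energy = numeric()))
  do.call(rbind, out)
}

# Rebuild missing carbonyl O atoms with ideal geometry (in the CA-C-N(i+1)
# plane opposite N, 1.231 A from C). Last residue uses the CA-C direction.
rebuild_oxygens <- function(conf) {
  n <- dim(conf)[1]
  for (i in seq_len(n)) {
    if (!anyNA(conf[i, "O", ])) next
    C <- conf[i, "C", ]; CA <- conf[i, "CA", ]
    if (i < n) {
      Nn <- conf[i + 1, "N", ]
      u <- (C - Nn) / sqrt(sum((C - Nn)^2)) + (C - CA) / sqrt(sum((C - CA)^2))
    } else {
      u <- C - CA
    }
    conf[i, "O", ] <- C + 1.231 * u / sqrt(sum(u^2))
  }
  conf
}

# DSSP-subset assignment for one conformation given its H-bond table.
assign_ss_one <- function(conf, hb) {
  n <- dim(conf)[1]
  HB <- matrix(FALSE, n, n)
  if (nrow(hb)) HB[cbind(hb$donor, hb$acceptor)] <- TRUE
  turn <- function(nn) {
    i <- seq_len(max(0L, n - nn))
    i[HB[cbind(i + nn, i)]]
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  ss <- rep("C", n)
  # bends: direction change CA(i-2)->CA(i) vs CA(i)->CA(i+2) above 70 deg
  if (n >= 5) {
    for (i in 3:(n - 2)) {
      u <- conf[i, "CA", ] - conf[i - 2, "CA", ]
      v <- conf[i + 2, "CA", ] - conf[i, "CA", ]
      cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      if (acos(pmin(1, pmax(-1, cosang))) * 180 / pi > 70) ss[i] <- "S"
    }
  }
  # H-bonded turns: residues bracketed by an n-turn
  for (tt in list(list(t3, 3L), list(t4, 4L), list(t5, 5L)))
    for (i in tt[[1]]) ss[(i + 1):(i + tt[[2]] - 1)] <- "T"
  # bridges
  par_b <- antipar_b <- matrix(FALSE, n, n)
  if (n >= 5) for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    if (abs(i - j) < 3 || j <= i) next
    if ((HB[j, i - 1] && HB[i + 1, j]) || (HB[i, j - 1] && HB[j + 1, i]))
      par_b[i, j] <- TRUE
    if ((HB[j, i] && HB[i, j]) ||
        (j + 1 <= n && i - 1 >= 1 && HB[j + 1, i - 1] && HB[i + 1, j - 1]))
      antipar_b[i, j] <- TRUE
  }
  bridges <- which(par_b | antipar_b, arr.ind = TRUE)
  if (nrow(bridges)) {
    in_ladder <- rep(FALSE, nrow(bridges))
    btype <- ifelse(par_b[bridges], "P", "A")
    for (b in seq_len(nrow(bridges))) {
      i <- bridges[b, 1]; j <- bridges[b, 2]
      if (btype[b] == "P") {
        in_ladder[b] <- (par_b[min(i + 1, n), min(j + 1, n)] && i + 1 < j + 1) ||
                        (i - 1 >= 1 && j - 1 >= 1 && par_b[i - 1, j - 1])
      } else {
        in_ladder[b] <- (i + 1 <= n && j - 1 >= 1 && i + 1 < j - 1 &&
                           antipar_b[i + 1, j - 1]) ||
                        (i - 1 >= 1 && j + 1 <= n && antipar_b[i - 1, j + 1])
      }
    }
    for (b in seq_len(nrow(bridges))) {
      code <- if (in_ladder[b]) "E" else "B"
      for (res in bridges[b, ]) {
        cur <- ss[res]
        if (code == "E" || cur %in% c("C", "S", "T")) ss[res] <- code
      }
    }
  }
  # helices: two consecutive n-turns (increasing priority order: G under I/E/H)
  mark <- function(ss, starts, len, code, over) {
    for (i in starts)
      for (r in i:(i + len - 1)) if (ss[r] %in% over) ss[r] <- code
    ss
  }
  gs <- t3[(t3 - 1) %in% t3]  # i such that turn3 at i-1 and i -> G at i..i+2
  is_ <- t5[(t5 - 1) %in% t5]
  hs <- t4[(t4 - 1) %in% t4]
  ss <- mark(ss, gs, 3L, "G", c("C", "S", "T", "B"))
  ss <- mark(ss, is_, 5L, "I", c("C", "S", "T", "B", "G"))
  ss <- mark(ss, hs, 4L, "H", c("C", "S", "T", "B", "G", "I", "E"))
  ss
}

#' DSSP-subset secondary structure assignment
#'
#' Assigns per-residue codes H, G, I (helices), E, B (sheet/bridge), T
#' (H-bonded turn), S (bend) and C (coil) from backbone coordinates using
#' Kabsch-Sander hydrogen bonds, with priority H > E > I > G > B > T > S > C.
#' Missing carbonyl oxygens are rebuilt with ideal geometry.
#'
#' @param ens a [conformation_ensemble] with coordinates (see
#'   [build_backbone()] for dihedral-only ensembles).
#' @return list with `ss`, a character matrix `[conformation x residue]`, and
#'   `hbonds`, a list of per-conformation H-bond tables
#'   (`donor`, `acceptor`, `energy`).
#' @export
assign_ss <- function(ens) {
  if (is.null(ens$coords))
    stop("ensemble has no coordinates; use build_backbone() first")
  n <- ens$n_residues
  ss <- matrix("C", ens$n_conformations, n)
  hbonds <- vector("list", ens$n_conformations)
  for (k in seq_len(ens$n_conformations)) {
    conf <- rebuild_oxygens(ens$coords[[k]])
    hb <- find_hbonds(conf, ens$residue_names)
    hbonds[[k]] <- hb
    if (n >= 3) ss[k, ] <- assign_ss_one(conf, hb)
  }
  list(ss = ss, hbonds = hbonds)
}

#' Helix segment statistics
#'
#' Helical content is the percentage of glutamine residues coded H (alpha) or
#' G (3-10); a helical segment is a maximal run of helix codes (H, G or I).
#' Reports the per-conformation distribution of segment counts and the
#' percentage of conformations containing a segment of at least each length
#' in `long_lengths`.
#'
#' @param ss character matrix of secondary-structure codes.
#' @param residue_names 3-letter codes (content restricted to GLN).
#' @param long_lengths segment lengths for the long-segment percentages.
#' @return list with `alpha_content`, `g310_content`, `helical_content`
#'   (percent), `segment_count_distribution` (percent of conformations with
#'   0, 1, 2, ... segments), `segment_lengths` (table) and `long_segment_pct`.
#' @export
helix_segment_stats <- function(ss, residue_names,
                                long_lengths = c(7, 9)) {
  gln <- residue_names == "GLN"
  helix_codes <- c("H", "G", "I")
  sub <- ss[, gln, drop = FALSE]
  alpha <- 100 * mean(sub == "H")
  g310 <- 100 * mean(sub == "G")
  nseg <- integer(nrow(ss))
  seg_lengths <- integer(0)
  longest <- integer(nrow(ss))
  for (k in seq_len(nrow(ss))) {
    r <- rle(ss[k, ] %in% helix_codes)
    lens <- r$lengths[r$values]
    nseg[k] <- length(lens)
    longest[k] <- if (length(lens)) max(lens) else 0L
    seg_lengths <- c(seg_lengths, lens)
  }
  dist <- 100 * table(factor(nseg, levels = 0:max(nseg))) / nrow(ss)
  long_pct <- vapply(long_lengths, function(L) 100 * mean(longest >= L), 0)
  names(long_pct) <- paste0("ge", long_lengths)
  list(alpha_content = alpha, g310_content = g310,
       helical_content = alpha + g310,
       segment_count_distribution = dist,
       segment_lengths = if (length(seg_lengths)) table(seg_lengths) else table(integer()),
       long_segment_pct = long_pct)
}

#' Classify turns
#'
#' An i -> i+3 hydrogen bond (donor i+3, acceptor i) defines a beta-turn with
#' middle residues i+1 and i+2; an i -> i+2 bond defines a gamma-turn.
#' Beta-turns whose two middle residues are both in the alphaR region are
#' type I; all other combinations are grouped as "other". Residues coded S
#' without a turn H-bond are bends.
#'
#' @param ss_result output of [assign_ss()].
#' @param labels a `region_labels` object for the same ensemble.
#' @return list with `turns` (data frame: conformation, start, turn_type) and
#'   `summary` (percent of glutamine residues in H-bonded turns vs bends, and
#'   beta-turn type percentages).
#' @export
classify_turns <- function(ss_result, labels) {
  ss <- ss_result$ss
  n_conf <- nrow(ss); n <- ncol(ss)
  gln <- labels$residue_names == "GLN"
  rows <- list()
  hb_turn_res <- matrix(FALSE, n_conf, n)
  for (k in seq_len(n_conf)) {
    hb <- ss_result$hbonds[[k]]
    if (!nrow(hb)) next
    b3 <- hb[hb$donor - hb$acceptor == 3, , drop = FALSE]
    b2 <- hb[hb$donor - hb$acceptor == 2, , drop = FALSE]
    for (i in b3$acceptor) {
      mid <- labels$labels[k, c(i + 1, i + 2)]
      type <- if (!anyNA(mid) && all(mid == "alphaR")) "beta_I" else "beta_other"
      rows[[length(rows) + 1L]] <- data.frame(conformation = k, start = i,
                                              turn_type = type)
      hb_turn_res[k, i:(i + 3)] <- TRUE
    }
    for (i in b2$acceptor) {
      rows[[length(rows) + 1L]] <- data.frame(conformation = k, start = i,
                                              turn_type = "gamma")
      hb_turn_res[k, i:(i + 2)] <- TRUE
    }
  }
  turns <- if (length(rows)) do.call(rbind, rows)
           else data.frame(conformation = integer(), start = integer(),
                           turn_type = character())
  gsub_ss <- ss[, gln, drop = FALSE]
  gsub_hb <- hb_turn_res[, gln, drop = FALSE]
  hbonded_pct <- 100 * mean(gsub_ss == "T" | (gsub_hb & gsub_ss %in% c("T", "S", "C")))
  bend_pct <- 100 * mean(gsub_ss == "S" & !gsub_hb)
  nbt <- sum(turns$turn_type %in% c("beta_I", "beta_other"))
  list(turns = turns,
       summary = c(hbonded_turn_pct = hbonded_pct, bend_pct = bend_pct,
                   beta_I_pct = if (nbt) 100 * mean(turns$turn_type == "beta_I") else 0,
                   beta_other_pct = if (nbt) 100 * mean(turns$turn_type == "beta_other") else 0,
                   gamma_count = sum(turns$turn_type == "gamma"),
                   beta_count = nbt))
}

empty_motifs <- function() {
  data.frame(conformation = integer(), type = character(), start = integer(),
             end = integer(), length = integer(), isolated = logical(),
             min_len = integer())
}

# Maximal runs of a per-residue logical pattern; for alpha_tilde, maximal
# strictly alternating alphaR/alphaL stretches.
strand_runs_one <- function(lab, kind) {
  n <- length(lab)
  if (kind == "beta" || kind == "ppii") {
    target <- if (kind == "beta") "beta" else "PPII"
    ok <- !is.na(lab) & lab == target
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    return(data.frame(start = starts[keep], end = ends[keep]))
  }
  # alpha-tilde: alternation alphaR/alphaL in either phase
  helical <- !is.na(lab) & lab %in% c("alphaR", "alphaL")
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!helical[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && helical[j + 1L] && lab[j + 1L] != lab[j]) j <- j + 1L
    runs[[length(runs) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  if (!length(runs)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, runs)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Detect strand motifs
#'
#' Maximal runs of residues whose labels satisfy the strand pattern: a
#' constant beta or PPII label, or strict alphaR/alphaL alternation
#' (alpha-tilde, either phase). A strand is isolated when none of its
#' residues takes part in any backbone hydrogen bond. Runs of length 2 for
#' alpha-tilde are single repeats and are not reported as strands.
#'
#' @param labels a `region_labels` object.
#' @param hbonds list of per-conformation H-bond tables (or `NULL`, in which
#'   case `isolated` is `NA`).
#' @param kind one of `"beta"`, `"alpha_tilde"`, `"ppii"`.
#' @param min_len minimal strand length (3 or 4).
#' @return motif instance data frame (conformation, type, start, end, length,
#'   isolated, min_len).
#' @export
detect_strands <- function(labels, hbonds = NULL,
                           kind = c("beta", "alpha_tilde", "ppii"),
                           min_len = 3) {
  kind <- match.arg(kind)
  type <- unname(c(beta = "beta_strand", alpha_tilde = "alpha_tilde_strand",
                   ppii = "ppii_run")[kind])
  out <- list()
  for (k in seq_len(nrow(labels$labels))) {
    runs <- strand_runs_one(labels$labels[k, ], kind)
    runs <- runs[runs$end - runs$start + 1L >= min_len, , drop = FALSE]
    if (!nrow(runs)) next
    rownames(runs) <- NULL
    iso <- rep(NA, nrow(runs))
    if (!is.null(hbonds)) {
      hb <- hbonds[[k]]
      busy <- unique(c(hb$donor, hb$acceptor))
      iso <- vapply(seq_len(nrow(runs)), function(j)
        !any(seq(runs$start[j], runs$end[j]) %in% busy), TRUE)
    }
    out[[length(out) + 1L]] <- data.frame(
      conformation = k, type = type, start = runs$start, end = runs$end,
      length = runs$end - runs$start + 1L, isolated = iso,
      min_len = as.integer(min_len))
  }
  if (!length(out)) return(empty_motifs())
  do.call(rbind, out)
}

#' Detect hairpin motifs
#'
#' A hairpin is two successive strands of the same kind (each at least
#' `min_len` residues), separated by a connector of 1 to `max_loop` residues
#' that contains at least one turn- or bend-coded residue and no third
#' strand, with at least one hydrogen bond linking a residue of one strand to
#' a residue of the other.
#'
#' @param labels a `region_labels` object.
#' @param ss_result output of [assign_ss()] for the same ensemble.
#' @param kind `"beta"` or `"alpha_tilde"`.
#' @param min_len minimal strand length.
#' @param max_loop maximal connector length (set `Inf` to allow any length).
#' @return motif instance data frame.
#' @export
detect_hairpins <- function(labels, ss_result,
                            kind = c("beta", "alpha_tilde"),
                            min_len = 3, max_loop = 8) {
  kind <- match.arg(kind)
  type <- paste0(kind, "_hairpin")
  out <- list()
  for (k in seq_len(nrow(labels$labels))) {
    runs <- strand_runs_one(labels$labels[k, ], kind)
    runs <- runs[runs$end - runs$start + 1L >= min_len, , drop = FALSE]
    if (nrow(runs) < 2) next
    rownames(runs) <- NULL
    hb <- ss_result$hbonds[[k]]
    ss <- ss_result$ss[k, ]
    for (j in seq_len(nrow(runs) - 1L)) {
      s1 <- runs[j, ]; s2 <- runs[j + 1L, ]
      loop <- seq(s1$end + 1L, s2$start - 1L)
      if (length(loop) < 1 || length(loop) > max_loop) next
      if (!any(ss[loop] %in% c("T", "S"))) next
      cross <- (hb$donor %in% s1$start:s1$end & hb$acceptor %in% s2$start:s2$end) |
               (hb$donor %in% s2$start:s2$end & hb$acceptor %in% s1$start:s1$end)
      if (!any(cross)) next
      out[[length(out) + 1L]] <- data.frame(
        conformation = k, type = type, start = s1$start, end = s2$end,
        length = s2$end - s1$start + 1L, isolated = FALSE,
        min_len = as.integer(min_len))
    }
  }
  if (!length(out)) return(empty_motifs())
  do.call(rbind, out)
}

#' Per-conformation motif prevalence
#'
#' For each motif type (and minimal-length variant), the percentage of
#' conformations containing at least one instance lying entirely within the
#' polyQ portion of the chain (spans touching proline residues are excluded).
#'
#' @param instances a motif instance data frame (possibly several types
#'   row-bound together).
#' @param ens the [conformation_ensemble] the instances refer to.
#' @return data frame with columns `type`, `min_len`, `prevalence_pct`.
#' @export
motif_prevalence <- function(instances, ens) {
  pro <- which(ens$residue_names == "PRO")
  if (nrow(instances) && length(pro)) {
    touches <- vapply(seq_len(nrow(instances)), function(j)
      any(seq(instances$start[j], instances$end[j]) %in% pro), TRUE)
    instances <- instances[!touches, , drop = FALSE]
  }
  if (!nrow(instances))
    return(data.frame(type = character(), min_len = integer(),
                      prevalence_pct = numeric()))
  agg <- unique(instances[, c("type", "min_len")])
  agg$prevalence_pct <- vapply(seq_len(nrow(agg)), function(j) {
    sel <- instances$type == agg$type[j] & instances$min_len == agg$min_len[j]
    100 * length(unique(instances$conformation[sel])) / ens$n_conformations
  }, 0)
  rownames(agg) <- NULL
  agg
}
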