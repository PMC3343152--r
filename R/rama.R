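REGIONS <- c("alphaR", "alphaL", "PPII", "beta")

#' Default Ramachandran region boundaries
#'
#' Four regions of the (phi, psi) torus: alphaR (right-handed helical),
#' alphaL (left-handed helical), PPII (polyproline II) and beta (extended).
#' Each region is a set of half-open rectangles; intervals may wrap across
#' +/-180 and are stored as (lo, width) with membership
#' `((x - lo) mod 360) < width`. Points outside all rectangles are completed
#' to the region of the nearest canonical center under wrapped Euclidean
#' distance, so the four regions always partition the torus.
#'
#' @param rectangles optional data frame overriding the defaults, with columns
#'   `region`, `phi_lo`, `phi_width`, `psi_lo`, `psi_width`.
#' @param centers optional 4 x 2 matrix of canonical (phi, psi) centers with
#'   rownames alphaR, alphaL, PPII, beta.
#' @return an object of class `region_boundaries`.
#' @export
region_boundaries <- function(rectangles = NULL, centers = NULL) {
  if (is.null(rectangles))
    rectangles <- data.frame(
      region    = c("alphaR", "alphaL", "PPII", "beta"),
      phi_lo    = c(-180,       0,      -110,   -180),
      phi_width = c( 180,     180,       110,     70),
      psi_lo    = c(-120,     -50,        50,     50),
      psi_width = c( 170,     170,       190,    190),
      stringsAsFactors = FALSE)
  if (is.null(centers)) {
    centers <- rbind(alphaR = c(-63, -43), alphaL = c(57, 47),
                     PPII = c(-75, 150), beta = c(-140, 150))
    colnames(centers) <- c("phi", "psi")
  }
  stopifnot(all(rectangles$region %in% REGIONS),
            identical(rownames(centers), REGIONS))
  structure(list(rectangles = rectangles, centers = centers),
            class = "region_boundaries")
}

in_interval_wrapped <- function(x, lo, width) ((x - lo) %% 360) < width

wrapped_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Region of nearest canonical center on the torus (vectorised).
nearest_center_region <- function(phi, psi, centers) {
  d2 <- sapply(seq_len(nrow(centers)), function(j)
    wrapped_diff(phi, centers[j, 1])^2 + wrapped_diff(psi, centers[j, 2])^2)
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  rownames(centers)[max.col(-d2, ties.method = "first")]
}

# Classify vectors of (phi, psi) by hard boundaries + nearest-center fill.
classify_hard <- function(phi, psi, bounds) {
  out <- rep(NA_character_, length(phi))
  rect <- bounds$rectangles
  for (j in seq_len(nrow(rect))) {
    hit <- is.na(out) &
      in_interval_wrapped(phi, rect$phi_lo[j], rect$phi_width[j]) &
      in_interval_wrapped(psi, rect$psi_lo[j], rect$psi_width[j])
    out[hit] <- rect$region[j]
  }
  left <- is.na(out)
  if (any(left))
    out[left] <- nearest_center_region(phi[left], psi[left], bounds$centers)
  out
}

new_region_labels <- function(labels, method, residue_names) {
  structure(list(labels = labels, method = method,
                 residue_names = residue_names),
            class = "region_labels")
}

#' @export
print.region_labels <- function(x, ...) {
  cat(sprintf("Ramachandran region labels (%s): %d conformations x %d residues\n",
              x$method, nrow(x$labels), ncol(x$labels)))
  print(round(100 * table(x$labels, useNA = "no") / sum(!is.na(x$labels)), 1))
  invisible(x)
}

#' Assign Ramachandran regions by hard boundaries
#'
#' Each defined (phi, psi) pair falling inside a region rectangle gets that
#' region; points outside all rectangles get the region of the nearest
#' canonical center, so the labels are a full partition. Labels are `NA`
#' exactly where phi or psi is undefined.
#'
#' @param ens a [conformation_ensemble].
#' @param bounds a [region_boundaries] object.
#' @return an object of class `region_labels` with a
#'   `[conformation x residue]` character matrix.
#' @export
assign_regions_hard <- function(ens, bounds = region_boundaries()) {
  lab <- matrix(NA_character_, ens$n_conformations, ens$n_residues)
  ok <- !is.na(ens$phi) & !is.na(ens$psi)
  lab[ok] <- classify_hard(ens$phi[ok], ens$psi[ok], bounds)
  new_region_labels(lab, "hard", ens$residue_names)
}

# Weighted wrapped k-means on (phi, psi) points; returns integer cluster ids.
wrapped_kmeans <- function(phi, psi, w, centers, max_iter = 100) {
  k <- nrow(centers)
  assign_pts <- function(ctr) {
    d2 <- sapply(seq_len(k), function(j)
      wrapped_diff(phi, ctr[j, 1])^2 + wrapped_diff(psi, ctr[j, 2])^2)
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
    max.col(-d2, ties.method = "first")
  }
  cl <- assign_pts(centers)
  for (it in seq_len(max_iter)) {
    ctr <- centers
    for (j in seq_len(k)) {
      sel <- cl == j
      if (!any(sel)) next  # empty cluster keeps its seed
      ww <- w[sel]
      ctr[j, 1] <- atan2(sum(ww * sin(phi[sel] * pi / 180)),
                         sum(ww * cos(phi[sel] * pi / 180))) * 180 / pi
      ctr[j, 2] <- atan2(sum(ww * sin(psi[sel] * pi / 180)),
                         sum(ww * cos(psi[sel] * pi / 180))) * 180 / pi
    }
    cl_new <- assign_pts(ctr)
    centers <- ctr
    if (all(cl_new == cl)) break
    cl <- cl_new
  }
  list(cluster = cl, centers = centers)
}

#' Assign Ramachandran regions by per-residue clustering
#'
#' For each residue, the defined (phi, psi) points are binned on the torus
#' (default 5 degree bins) and partitioned by wrapped k-means with k = 4
#' seeded at the canonical region centers. Clusters are re-identified by
#' their nearest canonical center; if two clusters collapse onto the same
#' center the residue falls back to hard assignment. Ensembles with fewer
#' than 100 defined pairs overall fall back to hard assignment entirely.
#'
#' @inheritParams assign_regions_hard
#' @param grid_deg histogram bin width in degrees; must divide 360.
#' @return an object of class `region_labels`.
#' @export
assign_regions_cluster <- function(ens, bounds = region_boundaries(),
                                   grid_deg = 5) {
  if (360 %% grid_deg != 0) stop("grid_deg must divide 360")
  ok <- !is.na(ens$phi) & !is.na(ens$psi)
  if (sum(ok) < 100) {
    warning("fewer than 100 defined (phi, psi) pairs; falling back to hard assignment")
    return(assign_regions_hard(ens, bounds))
  }
  hard <- assign_regions_hard(ens, bounds)
  lab <- matrix(NA_character_, ens$n_conformations, ens$n_residues)
  # bin index helper: torus bins starting at -180
  nb <- as.integer(360 / grid_deg)
  bin_of <- function(x) pmin(nb - 1L, as.integer(((x + 180) %% 360) / grid_deg))
  for (i in seq_len(ens$n_residues)) {
    sel <- ok[, i]
    if (!any(sel)) next
    phi <- ens$phi[sel, i]; psi <- ens$psi[sel, i]
    bp <- bin_of(phi); bq <- bin_of(psi)
    key <- bp * nb + bq
    tab <- table(key)
    ukey <- as.integer(names(tab))
    cphi <- -180 + (ukey %/% nb) * grid_deg + grid_deg / 2
    cpsi <- -180 + (ukey %% nb) * grid_deg + grid_deg / 2
    km <- wrapped_kmeans(cphi, cpsi, as.numeric(tab), bounds$centers)
    ident <- nearest_center_region(km$centers[, 1], km$centers[, 2],
                                   bounds$centers)
    nonempty <- sort(unique(km$cluster))
    if (anyDuplicated(ident[nonempty])) {
      lab[sel, i] <- hard$labels[sel, i]  # degenerate clustering for residue
      next
    }
    lab[sel, i] <- ident[km$cluster][match(key, ukey)]
  }
  new_region_labels(lab, "cluster", ens$residue_names)
}

#' Per-residue Ramachandran region populations
#'
#' For each residue passing the name filter, the percentage of conformations
#' (with a defined label) assigned to each region. Prolines are excluded by
#' default: the filter keeps glutamine residues only.
#'
#' @param labels a `region_labels` object.
#' @param residue_filter character set of 3-letter codes to keep.
#' @return data frame with columns `residue`, `residue_name`, one column per
#'   region (percentages), and `n_defined`.
#' @export
region_population_profile <- function(labels, residue_filter = "GLN") {
  keep <- which(labels$residue_names %in% residue_filter)
  if (!length(keep)) stop("no residues match the filter")
  out <- data.frame(residue = keep, residue_name = labels$residue_names[keep])
  for (rg in REGIONS) out[[rg]] <- NA_real_
  out$n_defined <- NA_integer_
  for (j in seq_along(keep)) {
    col <- labels$labels[, keep[j]]
    col <- col[!is.na(col)]
    out$n_defined[j] <- length(col)
    for (rg in REGIONS)
      out[[rg]][j] <- if (length(col)) 100 * mean(col == rg) else NA_real_
  }
  out
}

#' Alpha-sheet repeat mask
#'
#' A residue is part of an alpha-tilde repeat when its label is alphaR and an
#' adjacent residue (index +/- 1) is alphaL, or vice versa, regardless of
#' order. Terminal residues use their single neighbour; undefined neighbours
#' never match.
#'
#' @param labels a `region_labels` object.
#' @return binary integer matrix `[conformation x residue]`; `NA` where the
#'   residue's own label is undefined.
#' @export
alpha_tilde_mask <- function(labels) {
  lab <- labels$labels
  n <- ncol(lab)
  is_r <- lab == "alphaR"
  is_l <- lab == "alphaL"
  is_r[is.na(is_r)] <- FALSE; is_l[is.na(is_l)] <- FALSE
  pad <- function(m, side) {
    z <- matrix(FALSE, nrow(m), 1)
    if (side == "left") cbind(z, m[, -n, drop = FALSE])
    else cbind(m[, -1, drop = FALSE], z)
  }
  nb_l <- pad(is_l, "left") | pad(is_l, "right")   # any adjacent alphaL
  nb_r <- pad(is_r, "left") | pad(is_r, "right")   # any adjacent alphaR
  mask <- matrix(0L, nrow(lab), n)
  mask[(is_r & nb_l) | (is_l & nb_r)] <- 1L
  mask[is.na(lab)] <- NA_integer_
  mask
}

#' Ensemble-average region populations
#'
#' Averages the per-residue region percentages over glutamine residues and
#' adds the alpha-tilde repeat percentage (fraction of defined glutamine
#' cells whose alpha-tilde mask is 1). The four region percentages sum to
#' 100 up to rounding.
#'
#' @param labels a `region_labels` object.
#' @param residue_filter residues included in the averages (default GLN).
#' @return named numeric vector: alphaR, alphaL, PPII, beta, alpha_tilde.
#' @export
mean_region_populations <- function(labels, residue_filter = "GLN") {
  prof <- region_population_profile(labels, residue_filter)
  means <- vapply(REGIONS, function(rg) mean(prof[[rg]], na.rm = TRUE), 0)
  mask <- alpha_tilde_mask(labels)
  keep <- labels$residue_names %in% residue_filter
  cells <- mask[, keep, drop = FALSE]
  at <- 100 * mean(cells[!is.na(cells)] == 1L)
  c(means, alpha_tilde = at)
}
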