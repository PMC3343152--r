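# Odds-ratio association statistics over binary residue properties, mapped to
# free-energy units via kB*T*ln(OR), with asymptotic standard errors.

KB_KCAL <- 0.0019872  # Boltzmann constant, kcal/mol/K

#' 2x2 contingency table
#'
#' Counts of the four joint outcomes of two binary residue properties X and
#' Y; `nxy` counts events with X = x and Y = y.
#'
#' @param n00,n01,n10,n11 non-negative counts.
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(n00, n01, n10, n11) {
  n <- c(n00 = n00, n01 = n01, n10 = n10, n11 = n11)
  if (any(n < 0) || any(n != round(n) & abs(n - round(n)) > 1e-9))
    stop("counts must be non-negative")
  if (sum(n) < 1) stop("all cells are zero")
  structure(as.list(n), class = "contingency_table")
}

#' Odds ratio of a 2x2 table
#'
#' `OR = (n00 * n11) / (n01 * n10)`. With `correction = TRUE` and any zero
#' cell, the Haldane-Anscombe +0.5 is added to every cell (result carries
#' attribute `corrected = TRUE`). Without correction, a zero denominator
#' yields `Inf` and a zero numerator 0.
#'
#' @param t a [contingency_table].
#' @param correction apply the Haldane-Anscombe correction on zero cells.
#' @return positive numeric (possibly `Inf` or 0).
#' @export
odds_ratio <- function(t, correction = FALSE) {
  n <- as.numeric(t[c("n00", "n01", "n10", "n11")])
  corrected <- FALSE
  if (correction && any(n == 0)) { n <- n + 0.5; corrected <- TRUE }
  num <- n[1] * n[4]; den <- n[2] * n[3]
  or <- if (den == 0) { if (num == 0) NaN else Inf } else num / den
  structure(or, corrected = corrected)
}

#' Free-energy association score of a 2x2 table
#'
#' `score = kB*T*ln(OR)` in kcal/mol (0.5962 kcal/mol per ln-unit at 300 K);
#' positive scores mean positive association. The asymptotic standard error
#' is `kB*T*sqrt(1/n00 + 1/n01 + 1/n10 + 1/n11)`.
#'
#' @param t a [contingency_table].
#' @param temperature temperature in kelvin.
#' @param correction apply Haldane-Anscombe +0.5 on zero cells; without it a
#'   zero cell is an error.
#' @return list with `score`, `se` (kcal/mol), `or`, `corrected`.
#' @export
delta_delta_g <- function(t, temperature = 300, correction = FALSE) {
  n <- as.numeric(t[c("n00", "n01", "n10", "n11")])
  corrected <- FALSE
  if (any(n == 0)) {
    if (!correction) {
      cell <- c("n00", "n01", "n10", "n11")[which(n == 0)[1]]
      stop("zero cell ", cell, "; use correction = TRUE")
    }
    n <- n + 0.5
    corrected <- TRUE
  }
  kbt <- KB_KCAL * temperature
  or <- n[1] * n[4] / (n[2] * n[3])
  list(score = kbt * log(or), se = kbt * sqrt(sum(1 / n)), or = or,
       corrected = corrected)
}

#' Binary mask of membership in one Ramachandran region
#'
#' @param labels a `region_labels` object.
#' @param region one of alphaR, alphaL, PPII, beta.
#' @return integer matrix `[conformation x residue]` with 1/0 and `NA` where
#'   the label is undefined.
#' @export
region_mask <- function(labels, region) {
  if (!region %in% REGIONS)
    stop("unknown region '", region, "'; expected one of ",
         paste(REGIONS, collapse = ", "))
  m <- matrix(NA_integer_, nrow(labels$labels), ncol(labels$labels))
  ok <- !is.na(labels$labels)
  m[ok] <- as.integer(labels$labels[ok] == region)
  m
}

new_correlation_profile <- function(df, statistic_kind, region = NA,
                                    trim = NA) {
  structure(df, class = c("correlation_profile", "data.frame"),
            statistic_kind = statistic_kind, region = region, trim = trim)
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("Correlation profile (%s%s), trim = %s:\n",
              attr(x, "statistic_kind"),
              if (!is.na(attr(x, "region"))) paste0(", ", attr(x, "region")) else "",
              attr(x, "trim")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

default_trim <- function(n_residues) if (n_residues >= 30) 5L else 2L

#' Odds-ratio correlation profile over sequence distance
#'
#' For each sequence separation r, residue pairs (i, i + r) with both indices
#' inside the trimmed window (and glutamine names, if `residue_names` given)
#' are collected. In `pooled` mode one 2x2 table is accumulated over all
#' pairs and conformations and converted by [delta_delta_g()]; `per_pair`
#' mode averages per-pair scores with inverse-variance weights. Cells with an
#' undefined mask value are skipped.
#'
#' @param mask binary matrix `[conformation x residue]` (1/0/NA), e.g. from
#'   [region_mask()] or [alpha_tilde_mask()].
#' @param r_max largest separation; defaults to the widest separation that
#'   fits inside the trimmed window.
#' @param trim residues omitted at each end to reduce end effects; default 5
#'   for chains of at least 30 residues, 2 otherwise.
#' @param pooling `"pooled"` or `"per_pair"`.
#' @param residue_names optional 3-letter codes; when given, only GLN columns
#'   enter the profile.
#' @param temperature kelvin, for the kcal/mol conversion.
#' @param statistic_kind,region metadata recorded on the returned profile.
#' @return a `correlation_profile`: data frame (r, value, se, n_pairs) with
#'   attributes; r values with no eligible pairs are dropped.
#' @export
or_profile <- function(mask, r_max = NULL, trim = NULL,
                       pooling = c("pooled", "per_pair"),
                       residue_names = NULL, temperature = 300,
                       statistic_kind = "or_region", region = NA) {
  pooling <- match.arg(pooling)
  n <- ncol(mask)
  if (is.null(trim)) trim <- default_trim(n)
  if (trim >= n / 2) stop("trim must be smaller than half the residue count")
  lo <- trim + 1L; hi <- n - trim
  eligible <- lo:hi
  if (!is.null(residue_names))
    eligible <- eligible[residue_names[eligible] == "GLN"]
  if (is.null(r_max)) r_max <- hi - lo
  rows <- list()
  for (r in seq_len(r_max)) {
    is_ <- eligible[(eligible + r) %in% eligible]
    if (!length(is_)) next
    a <- mask[, is_, drop = FALSE]
    b <- mask[, is_ + r, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    av <- a[ok]; bv <- b[ok]
    if (pooling == "pooled") {
      tt <- contingency_table(sum(!av & !bv), sum(!av & bv),
                              sum(av & !bv), sum(av & bv))
      d <- delta_delta_g(tt, temperature, correction = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        r = r, value = d$score, se = d$se, n_pairs = length(is_),
        corrected = d$corrected)
    } else {
      scores <- ses <- numeric(0)
      for (j in seq_along(is_)) {
        aj <- mask[, is_[j]]; bj <- mask[, is_[j] + r]
        okj <- !is.na(aj) & !is.na(bj)
        if (!any(okj)) next
        tt <- contingency_table(sum(!aj[okj] & !bj[okj]), sum(!aj[okj] & bj[okj]),
                                sum(aj[okj] & !bj[okj]), sum(aj[okj] & bj[okj]))
        d <- delta_delta_g(tt, temperature, correction = TRUE)
        scores <- c(scores, d$score); ses <- c(ses, d$se)
      }
      if (!length(scores)) next
      w <- 1 / ses^2
      rows[[length(rows) + 1L]] <- data.frame(
        r = r, value = sum(w * scores) / sum(w), se = sqrt(1 / sum(w)),
        n_pairs = length(scores), corrected = NA)
    }
  }
  if (!length(rows)) stop("no eligible residue pairs at any separation")
  new_correlation_profile(do.call(rbind, rows), statistic_kind, region, trim)
}

#' Pearson correlation profile of shifted psi angles
#'
#' Psi angles are shifted by `shift_deg` under periodic boundary conditions
#' (the default +100 degrees moves the wrap point into the sparsely populated
#' band between the alphaL and PPII basins), then for each separation r the
#' Pearson correlation of pooled (psi'_i, psi'_(i+r)) pairs is computed with
#' the same end trimming as [or_profile()].
#'
#' @param ens a [conformation_ensemble].
#' @param shift_deg angular shift in degrees.
#' @inheritParams or_profile
#' @return a `correlation_profile` with `se = NA`; separations with constant
#'   series give `NA` values.
#' @export
pearson_psi_profile <- function(ens, shift_deg = 100, r_max = NULL,
                                trim = NULL) {
  n <- ens$n_residues
  if (is.null(trim)) trim <- default_trim(n)
  lo <- trim + 1L; hi <- n - trim
  eligible <- (lo:hi)[ens$residue_names[lo:hi] == "GLN"]
  if (is.null(r_max)) r_max <- hi - lo
  psi <- wrap_angle(ens$psi + shift_deg)
  rows <- list()
  for (r in seq_len(r_max)) {
    is_ <- eligible[(eligible + r) %in% eligible]
    if (!length(is_)) next
    a <- as.vector(psi[, is_, drop = FALSE])
    b <- as.vector(psi[, is_ + r, drop = FALSE])
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3) next
    v <- if (sd(a[ok]) == 0 || sd(b[ok]) == 0) NA_real_
         else stats::cor(a[ok], b[ok])
    rows[[length(rows) + 1L]] <- data.frame(r = r, value = v, se = NA_real_,
                                            n_pairs = length(is_),
                                            corrected = NA)
  }
  if (!length(rows)) stop("no eligible residue pairs at any separation")
  new_correlation_profile(do.call(rbind, rows), "pearson_psi", NA, trim)
}

#' Similarity of two correlation profiles
#'
#' Pearson correlation between the profile values over the shared grid of
#' separations.
#'
#' @param p1,p2 `correlation_profile` objects.
#' @return Pearson correlation coefficient.
#' @export
profile_similarity <- function(p1, p2) {
  shared <- intersect(p1$r, p2$r)
  v1 <- p1$value[match(shared, p1$r)]
  v2 <- p2$value[match(shared, p2$r)]
  ok <- !is.na(v1) & !is.na(v2)
  if (sum(ok) < 3) stop("fewer than 3 shared separations")
  stats::cor(v1[ok], v2[ok])
}

#' Dominant oscillation period of a profile
#'
#' Linearly detrends the profile values over r >= r_min and locates the
#' periodogram maximum (4x zero-padded) among periods between 3 residues and
#' half the profile extent. The power fraction is the share of the maximum in
#' the total detrended power; a flat profile returns a small fraction.
#'
#' @param p a `correlation_profile`.
#' @param r_min smallest separation entering the periodogram.
#' @return list with `period` (residues) and `power_fraction`.
#' @export
dominant_period <- function(p, r_min = 2) {
  d <- p[p$r >= r_min & !is.na(p$value), ]
  if (nrow(d) < 2 * r_min) stop("profile too short for period estimation")
  res <- resid(lm(value ~ r, data = d))
  # resample onto the integer grid (gaps filled by linear interpolation)
  grid <- seq(min(d$r), max(d$r))
  y <- stats::approx(d$r, res, xout = grid)$y
  n <- length(y); m <- 4L * n
  pw <- Mod(fft(c(y, rep(0, m - n))))^2
  freq <- (seq_len(m) - 1) / m
  keep <- freq > 0 & freq <= 0.5
  per <- 1 / freq
  cand <- keep & per >= 3 & per <= max(p$r) / 2
  if (!any(cand)) stop("no candidate periods in [3, r_max/2]")
  kbest <- which(cand)[which.max(pw[cand])]
  list(period = per[kbest], power_fraction = pw[kbest] / sum(pw[keep]))
}

#' Long-range correlation diagnostic
#'
#' Tests whether the profile fails to decay at large separations: the flag is
#' raised when the magnitude of the mean profile value over r >= r_tail
#' exceeds twice the mean standard error over the same tail. The signed tail
#' mean is reported alongside.
#'
#' @param p a `correlation_profile` with standard errors.
#' @param r_tail first separation of the tail window.
#' @return list with `flag`, `tail_mean`, `threshold`.
#' @export
long_range_flag <- function(p, r_tail = 10) {
  tail <- p[p$r >= r_tail & !is.na(p$value), ]
  if (!nrow(tail)) stop("profile does not extend beyond r_tail")
  tm <- mean(tail$value)
  thr <- 2 * mean(tail$se)
  list(flag = is.finite(thr) && abs(tm) > thr, tail_mean = tm,
       threshold = thr)
}
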