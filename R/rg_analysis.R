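# Radius-of-gyration distributions, Gaussian-mixture decomposition and
# prolyl cis/trans sub-ensembles.

#' Radius of gyration of a point set
#'
#' Root-mean-square distance of the points from their centroid (unweighted).
#'
#' @param pts numeric matrix `[n x 3]` of coordinates in Angstrom.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(pts) {
  pts <- as.matrix(pts)
  if (!nrow(pts)) stop("empty point selection")
  ctr <- colMeans(pts)
  sqrt(mean(rowSums((pts - rep(ctr, each = nrow(pts)))^2)))
}

#' Per-conformation Rg over glutamine C-alpha atoms
#'
#' Proline segments are excluded so that polyQ stretches of different
#' constructs are compared on an equal footing.
#'
#' @param ens a [conformation_ensemble] with coordinates.
#' @return numeric vector of Rg values, one per conformation.
#' @export
rg_ensemble <- function(ens) {
  if (is.null(ens$coords)) stop("ensemble has no coordinates")
  sel <- which(ens$residue_names == "GLN")
  if (!length(sel)) stop("no glutamine residues")
  vapply(ens$coords, function(cc) {
    ca <- cc[sel, "CA", , drop = FALSE]
    dim(ca) <- c(length(sel), 3)
    radius_of_gyration(ca)
  }, 0)
}

#' Histogram of Rg values
#'
#' Left-closed bins of fixed width aligned to zero; returns raw counts and a
#' density normalisation.
#'
#' @param values numeric vector (Angstrom).
#' @param window bin width in Angstrom.
#' @return list with `mids`, `counts`, `density`, `window`, `n`.
#' @export
rg_histogram <- function(values, window = 0.5) {
  if (!length(values)) stop("empty input")
  if (window <= 0) stop("window must be positive")
  bin <- floor(values / window)
  rng <- min(bin):max(bin)
  counts <- tabulate(bin - min(bin) + 1L, nbins = length(rng))
  list(mids = (rng + 0.5) * window, counts = counts,
       density = counts / (sum(counts) * window), window = window,
       n = length(values))
}

#' Gaussian-mixture fit of an Rg histogram
#'
#' Least-squares fit of `sum_j w_j N(mu_j, sigma_j)` to the histogram bin
#' densities by Levenberg-Marquardt, initialised from quantile-spaced means,
#' the pooled standard deviation and equal weights. Weights are renormalised
#' to sum to one and components are sorted by mean. Reduced chi-square is
#' computed with per-bin Poisson variance `max(count, 1)` converted to
#' density units and `dof = bins - (3k - 1)`; an unweighted variant is
#' reported alongside.
#'
#' @param hist output of [rg_histogram()].
#' @param k number of components.
#' @param init optional list with numeric vectors `w`, `mean`, `sd` seeding
#'   the optimiser.
#' @param sigma_floor smallest admissible component sd; defaults to half the
#'   bin width. Fits collapsing below it are refit at the floor and flagged.
#' @return object of class `rg_mixture_fit`: list with `k`, `weights`,
#'   `means`, `sds`, `reduced_chi2`, `reduced_chi2_unweighted`, `converged`,
#'   `sigma_floored`, and the histogram.
#' @export
fit_gaussian_mixture <- function(hist, k, init = NULL, sigma_floor = NULL) {
  stopifnot(k >= 1)
  x <- hist$mids; y <- hist$density
  if (sum(hist$counts > 0) < 3 * k + 1)
    stop("histogram has fewer than 3k + 1 nonempty bins")
  if (is.null(sigma_floor)) sigma_floor <- hist$window / 2
  if (is.null(init)) {
    cum <- cumsum(hist$counts) / sum(hist$counts)
    qs <- vapply(seq_len(k), function(j)
      x[which(cum >= (j - 0.5) / k)[1]], 0)
    pooled_sd <- sqrt(sum(hist$counts * (x - sum(hist$counts * x) /
                                           sum(hist$counts))^2) /
                        sum(hist$counts))
    init <- list(w = rep(1 / k, k), mean = qs,
                 sd = rep(max(pooled_sd / k, sigma_floor), k))
  }
  # model the bin-averaged density (integral of the mixture over each bin
  # divided by the width); midpoint evaluation biases sub-bin-width features
  lo <- x - hist$window / 2; up <- x + hist$window / 2
  model <- function(par) {
    w <- par[seq_len(k)]; mu <- par[k + seq_len(k)]
    sg <- pmax(abs(par[2 * k + seq_len(k)]), 1e-6)
    rowSums(vapply(seq_len(k), function(j)
      w[j] * (pnorm(up, mu[j], sg[j]) - pnorm(lo, mu[j], sg[j])) / hist$window,
      numeric(length(x))))
  }
  # Poisson error bars per bin, in density units; LM minimises chi-square
  sig <- sqrt(pmax(hist$counts, 1)) / (hist$n * hist$window)
  par0 <- c(init$w, init$mean, init$sd)
  fit <- minpack.lm::nls.lm(par = par0, fn = function(p) (y - model(p)) / sig,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info == 9)
    stop("Levenberg-Marquardt did not converge within 500 iterations")
  par <- fit$par
  w <- abs(par[seq_len(k)]); mu <- par[k + seq_len(k)]
  sg <- abs(par[2 * k + seq_len(k)])
  floored <- any(sg < sigma_floor)
  if (floored) {
    sg <- pmax(sg, sigma_floor)
    fit2 <- minpack.lm::nls.lm(
      par = c(w, mu, sg),
      fn = function(p) {
        p[2 * k + seq_len(k)] <- pmax(abs(p[2 * k + seq_len(k)]), sigma_floor)
        (y - model(p)) / sig
      },
      control = minpack.lm::nls.lm.control(maxiter = 500))
    par <- fit2$par
    w <- abs(par[seq_len(k)]); mu <- par[k + seq_len(k)]
    sg <- pmax(abs(par[2 * k + seq_len(k)]), sigma_floor)
  }
  w <- w / sum(w)
  ord <- order(mu)
  w <- w[ord]; mu <- mu[ord]; sg <- sg[ord]
  yhat <- model(c(w, mu, sg))
  dof <- length(x) - (3 * k - 1)
  var_density <- pmax(hist$counts, 1) / (hist$n * hist$window)^2
  chi2_w <- sum((y - yhat)^2 / var_density) / dof
  chi2_u <- sum((y - yhat)^2) / (dof * mean(var_density))
  structure(list(k = k, weights = w, means = mu, sds = sg,
                 reduced_chi2 = chi2_w, reduced_chi2_unweighted = chi2_u,
                 converged = TRUE, sigma_floored = floored,
                 histogram = hist),
            class = "rg_mixture_fit")
}

#' @export
print.rg_mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit, k = %d (reduced chi2 = %.3f):\n",
              x$k, x$reduced_chi2))
  print(data.frame(weight = round(x$weights, 4), mean = round(x$means, 3),
                   sd = round(x$sds, 3)))
  invisible(x)
}

#' Gaussian-mixture fit by EM (cross-check)
#'
#' Maximum-likelihood fit of a k-component univariate Gaussian mixture to the
#' raw Rg values by expectation-maximisation, as an independent cross-check
#' of the histogram-based Levenberg-Marquardt route (which is bin-width
#' sensitive).
#'
#' @param values numeric vector of Rg values.
#' @param k number of components.
#' @param max_iter,tol EM iteration controls (log-likelihood convergence).
#' @return list with `weights`, `means`, `sds` sorted by mean, plus
#'   `loglik` and `iterations`.
#' @export
fit_gaussian_mixture_em <- function(values, k, max_iter = 500, tol = 1e-8) {
  x <- as.numeric(values)
  n <- length(x)
  qs <- quantile(x, (seq_len(k) - 0.5) / k, names = FALSE)
  w <- rep(1 / k, k); mu <- qs; sg <- rep(sd(x) / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sg[j]),
                   numeric(n))
    tot <- rowSums(dens)
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(vapply(seq_len(k), function(j)
      sum(resp[, j] * (x - mu[j])^2) / nk[j], 0))
    sg <- pmax(sg, 1e-6)
    if (abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(weights = w[ord], means = mu[ord], sds = sg[ord], loglik = ll,
       iterations = it)
}

#' Chain-length scaling exponent of Rg
#'
#' Under `Rg ~ N^nu`, each pair of chain lengths gives
#' `nu_ij = ln(Rg_i/Rg_j) / ln(N_i/N_j)`; the pooled estimate is the
#' least-squares slope of `ln Rg` on `ln N`.
#'
#' @param rg_by_length data frame with columns `N` (residue counts) and `rg`
#'   (mean Rg, Angstrom).
#' @param pairs optional 2-column matrix of row indices for pairwise
#'   estimates; defaults to all pairs.
#' @return list with `pairwise` (data frame N1, N2, nu) and `pooled`
#'   (slope, with `se` from the regression).
#' @export
scaling_exponent <- function(rg_by_length, pairs = NULL) {
  d <- rg_by_length
  if (nrow(d) < 2) stop("at least two chain lengths required")
  if (any(d$rg <= 0)) stop("Rg values must be positive")
  if (is.null(pairs)) pairs <- t(utils::combn(nrow(d), 2))
  if (any(d$N[pairs[, 1]] == d$N[pairs[, 2]]))
    stop("pairs with equal lengths are undefined")
  nu <- log(d$rg[pairs[, 1]] / d$rg[pairs[, 2]]) /
        log(d$N[pairs[, 1]] / d$N[pairs[, 2]])
  fit <- lm(log(rg) ~ log(N), data = d)
  list(pairwise = data.frame(N1 = d$N[pairs[, 1]], N2 = d$N[pairs[, 2]],
                             nu = nu),
       pooled = c(nu = unname(coef(fit)[2]),
                  se = if (nrow(d) > 2)
                         suppressWarnings(summary(fit)$coefficients[2, 2])
                       else NA_real_))
}

#' Prolyl cis/trans isomer states and sub-ensembles
#'
#' The peptide bond preceding a proline at position j is the omega torsion
#' stored at residue j - 1; it is cis when `|omega| < 90` degrees and trans
#' otherwise (the 90-degree boundary is assigned to trans). Returns per-bond
#' trans content and the split into all-trans and cis-containing
#' sub-ensembles for downstream Rg analysis.
#'
#' @param ens a [conformation_ensemble] containing at least one proline.
#' @return list with `states` (logical matrix `[conformation x bond]`, TRUE =
#'   trans), `bond_residue` (index of the residue preceding each proline),
#'   `trans_content_pct` (per bond), `all_trans` (logical vector),
#'   `all_trans_fraction`, and sub-ensembles `ens_all_trans`, `ens_cis`.
#' @export
prolyl_isomers <- function(ens) {
  pro <- which(ens$residue_names == "PRO")
  pro <- pro[pro > 1]
  if (!length(pro))
    stop("no prolines: prolyl isomer analysis is undefined for this peptide")
  bonds <- pro - 1L
  om <- ens$omega[, bonds, drop = FALSE]
  if (anyNA(om)) stop("omega undefined for some prolyl bonds")
  trans <- abs(om) >= 90
  all_trans <- apply(trans, 1, all)
  subset_ens <- function(keep) {
    if (!any(keep)) return(NULL)
    conformation_ensemble(ens$phi[keep, , drop = FALSE],
                          ens$psi[keep, , drop = FALSE],
                          ens$omega[keep, , drop = FALSE],
                          ens$residue_names,
                          peptide_name = ens$peptide_name,
                          coords = if (is.null(ens$coords)) NULL
                                   else ens$coords[keep])
  }
  list(states = trans, bond_residue = bonds,
       trans_content_pct = 100 * colMeans(trans),
       all_trans = all_trans,
       all_trans_fraction = mean(all_trans),
       ens_all_trans = subset_ens(all_trans),
       ens_cis = subset_ens(!all_trans))
}
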