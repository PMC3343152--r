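# Assembly of per-peptide summary reports and peptide-to-peptide contrasts.

#' Analysis configuration
#'
#' Validated container of the tunable analysis parameters; unknown arguments
#' are rejected.
#'
#' @param trim residues omitted per end in correlation profiles (`NULL` =
#'   automatic: 5 for chains >= 30 residues, 2 otherwise).
#' @param r_max largest sequence separation (`NULL` = maximal).
#' @param shift_deg psi shift for the Pearson profile, degrees.
#' @param temperature_K temperature for kcal/mol conversion.
#' @param window Rg histogram bin width, Angstrom.
#' @param min_len_variants strand minimal-length variants.
#' @param max_loop hairpin connector cap, residues.
#' @param pooling contingency pooling mode for [or_profile()].
#' @param correction Haldane-Anscombe correction on zero cells.
#' @param grid_deg Ramachandran histogram bin width for clustering.
#' @param assignment `"hard"` or `"cluster"` region assignment.
#' @param mixture_k components for the Rg mixture fit (0 = skip).
#' @param long_lengths helix segment lengths reported.
#' @param r_tail tail start for the long-range diagnostic.
#' @param seed seed recorded with every report.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(trim = NULL, r_max = NULL, shift_deg = 100,
                            temperature_K = 300, window = 0.5,
                            min_len_variants = c(3, 4), max_loop = 8,
                            pooling = c("pooled", "per_pair"),
                            correction = TRUE, grid_deg = 5,
                            assignment = c("hard", "cluster"),
                            mixture_k = 0, long_lengths = c(7, 9),
                            r_tail = 10, seed = 1L) {
  pooling <- match.arg(pooling)
  assignment <- match.arg(assignment)
  stopifnot(is.null(trim) || (trim >= 0 && trim == round(trim)),
            shift_deg > -360, shift_deg < 360, temperature_K > 0,
            window > 0, all(min_len_variants %in% 2:10), max_loop >= 1,
            grid_deg > 0, 360 %% grid_deg == 0, mixture_k >= 0,
            r_tail >= 1)
  structure(list(trim = trim, r_max = r_max, shift_deg = shift_deg,
                 temperature_K = temperature_K, window = window,
                 min_len_variants = min_len_variants, max_loop = max_loop,
                 pooling = pooling, correction = correction,
                 grid_deg = grid_deg, assignment = assignment,
                 mixture_k = mixture_k, long_lengths = long_lengths,
                 r_tail = r_tail, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Full per-peptide summary
#'
#' Runs the whole pipeline on one ensemble: region assignment and population
#' table, alpha-tilde repeats, DSSP-subset secondary structure with helix and
#' turn statistics, extended-motif detection at both minimal-length variants
#' with per-conformation prevalence, odds-ratio correlation profiles for the
#' four regions and the alpha-tilde mask, the Pearson psi profile, the
#' dominant oscillation period and long-range diagnostic of the alphaR
#' profile, and Rg statistics (with prolyl sub-ensembles when prolines are
#' present). The configuration and seed are echoed in the report.
#'
#' @param ens a [conformation_ensemble]; a backbone is reconstructed when
#'   coordinates are absent.
#' @param cfg an [analysis_config].
#' @return object of class `peptide_summary`.
#' @export
run_summary <- function(ens, cfg = analysis_config()) {
  if (is.null(ens$coords)) ens <- build_backbone(ens)
  labels <- if (cfg$assignment == "cluster")
    assign_regions_cluster(ens, grid_deg = cfg$grid_deg)
  else assign_regions_hard(ens)
  pop_profile <- region_population_profile(labels)
  pops <- mean_region_populations(labels)
  at_mask <- alpha_tilde_mask(labels)
  ssr <- assign_ss(ens)
  helix <- helix_segment_stats(ssr$ss, ens$residue_names,
                               long_lengths = cfg$long_lengths)
  turns <- classify_turns(ssr, labels)
  gln <- ens$residue_names == "GLN"
  ss_gln <- ssr$ss[, gln, drop = FALSE]
  ss_pops <- c(helix_pct = 100 * mean(ss_gln %in% c("H", "G", "I")),
               turn_pct = 100 * mean(ss_gln %in% c("T", "S")),
               other_pct = 100 * mean(ss_gln %in% c("C", "B", "E")))
  motifs <- do.call(rbind, c(
    lapply(cfg$min_len_variants, function(ml) rbind(
      detect_strands(labels, ssr$hbonds, "beta", ml),
      detect_strands(labels, ssr$hbonds, "alpha_tilde", ml),
      detect_strands(labels, ssr$hbonds, "ppii", ml),
      detect_hairpins(labels, ssr, "beta", ml, cfg$max_loop),
      detect_hairpins(labels, ssr, "alpha_tilde", ml, cfg$max_loop)))))
  prevalence <- motif_prevalence(motifs, ens)
  iso <- motifs[!is.na(motifs$isolated) & motifs$isolated, , drop = FALSE]
  iso_prev <- motif_prevalence(iso, ens)
  profiles <- list()
  for (rg in REGIONS)
    profiles[[rg]] <- or_profile(region_mask(labels, rg), r_max = cfg$r_max,
                                 trim = cfg$trim, pooling = cfg$pooling,
                                 residue_names = ens$residue_names,
                                 temperature = cfg$temperature_K,
                                 statistic_kind = "or_region", region = rg)
  profiles$alpha_tilde <- or_profile(at_mask, r_max = cfg$r_max,
                                     trim = cfg$trim, pooling = cfg$pooling,
                                     residue_names = ens$residue_names,
                                     temperature = cfg$temperature_K,
                                     statistic_kind = "or_alpha_tilde")
  profiles$pearson_psi <- pearson_psi_profile(ens, shift_deg = cfg$shift_deg,
                                              r_max = cfg$r_max,
                                              trim = cfg$trim)
  period <- tryCatch(dominant_period(profiles$alphaR),
                     error = function(e) list(period = NA_real_,
                                              power_fraction = NA_real_))
  lrf <- tryCatch(long_range_flag(profiles$alphaR, r_tail = cfg$r_tail),
                  error = function(e) list(flag = NA, tail_mean = NA_real_,
                                           threshold = NA_real_))
  rg_vals <- rg_ensemble(ens)
  rg_stats <- list(mean = mean(rg_vals), sd = sd(rg_vals),
                   histogram = rg_histogram(rg_vals, cfg$window))
  if (cfg$mixture_k >= 1)
    rg_stats$mixture <- fit_gaussian_mixture(rg_stats$histogram, cfg$mixture_k)
  prolyl <- NULL
  if (any(ens$residue_names == "PRO")) {
    prolyl <- prolyl_isomers(ens)
    if (!is.null(prolyl$ens_all_trans))
      prolyl$rg_all_trans <- mean(rg_ensemble(prolyl$ens_all_trans))
    if (!is.null(prolyl$ens_cis))
      prolyl$rg_cis <- mean(rg_ensemble(prolyl$ens_cis))
    prolyl$ens_all_trans <- prolyl$ens_cis <- NULL
  }
  structure(list(peptide_name = ens$peptide_name,
                 n_conformations = ens$n_conformations,
                 region_populations = pops, population_profile = pop_profile,
                 ss_populations = ss_pops, helix = helix, turns = turns,
                 prevalence = prevalence, isolated_prevalence = iso_prev,
                 profiles = profiles, dominant_period = period,
                 long_range = lrf, rg = rg_stats, prolyl = prolyl,
                 config = cfg, seed = cfg$seed),
            class = "peptide_summary")
}

#' @export
print.peptide_summary <- function(x, ...) {
  cat(sprintf("Summary of '%s' (%d conformations)\n", x$peptide_name,
              x$n_conformations))
  cat("Region populations (% of Gln residues):\n")
  print(round(x$region_populations, 2))
  cat("Secondary structure (% of Gln residues):\n")
  print(round(x$ss_populations, 2))
  cat(sprintf("Helical content: %.2f%% (alpha %.2f%%, 3-10 %.2f%%)\n",
              x$helix$helical_content, x$helix$alpha_content,
              x$helix$g310_content))
  if (nrow(x$prevalence)) {
    cat("Motif prevalence (% of conformations):\n")
    print(x$prevalence, row.names = FALSE, digits = 3)
  }
  cat(sprintf("alphaR profile: dominant period %.2f residues, long-range flag %s (tail mean %.4f kcal/mol)\n",
              x$dominant_period$period, x$long_range$flag,
              x$long_range$tail_mean))
  cat(sprintf("Rg: %.2f +/- %.2f Angstrom\n", x$rg$mean, x$rg$sd))
  invisible(x)
}

#' Contrast two or more peptide summaries
#'
#' Side-by-side differences of the headline summary quantities relative to
#' the first report, with pooled standard errors for the correlation-profile
#' tail means.
#'
#' @param reports list of `peptide_summary` objects.
#' @return data frame of quantities (rows) by peptide (columns), plus
#'   difference columns versus the first peptide.
#' @export
compare_peptides <- function(reports) {
  if (length(reports) < 2) stop("at least two reports required")
  cfgs <- lapply(reports, function(r) r$config[setdiff(names(r$config), "seed")])
  if (!all(vapply(cfgs[-1], identical, TRUE, cfgs[[1]])))
    warning("reports were produced under different configurations")
  grab <- function(r) {
    pv <- function(type, ml) {
      m <- r$prevalence[r$prevalence$type == type & r$prevalence$min_len == ml, ]
      if (nrow(m)) m$prevalence_pct else 0
    }
    c(r$region_populations,
      r$ss_populations,
      helical_content = r$helix$helical_content,
      beta_strand_3 = pv("beta_strand", 3),
      beta_strand_4 = pv("beta_strand", 4),
      alpha_tilde_strand_3 = pv("alpha_tilde_strand", 3),
      ppii_run_3 = pv("ppii_run", 3),
      beta_hairpin_3 = pv("beta_hairpin", 3),
      alpha_tilde_hairpin_3 = pv("alpha_tilde_hairpin", 3),
      tail_mean = r$long_range$tail_mean,
      tail_se = r$long_range$threshold / 2,
      long_range_flag = as.numeric(r$long_range$flag),
      dominant_period = r$dominant_period$period,
      rg_mean = r$rg$mean, rg_sd = r$rg$sd)
  }
  vals <- vapply(reports, grab, grab(reports[[1]]))
  colnames(vals) <- vapply(reports, function(r) r$peptide_name, "")
  out <- as.data.frame(vals)
  for (j in 2:ncol(vals))
    out[[paste0("diff_", colnames(vals)[j], "_vs_", colnames(vals)[1])]] <-
      vals[, j] - vals[, 1]
  pooled_se <- sqrt(sum(vals["tail_se", c(1, 2)]^2))
  attr(out, "tail_mean_diff_pooled_se") <- pooled_se
  out
}
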