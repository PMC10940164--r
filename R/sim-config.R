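#' Configuration for the synthetic allelic-series experiment
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' the emulated study: a five-genotype ER-phagy receptor deletion series
#' (WT, DKO, TKO, QKO, PKO) measured in one TMT plex with three biological
#' replicates per genotype, 359 ER proteins among 8,000 quantified proteins
#' (the depth of a deep TMT proteome, so the ER set is a small fraction of
#' the total signal, as in real data),
#' receptor deletions imprinted as a -2.5 log2 step effect, an ER-wide mean
#' step-1 (WT to DKO) effect of 0.21 log2 units with ER-membrane proteins
#' enriched two-fold over other ER classes, and Gaussian replicate noise of
#' 0.25 log2 units.
#'
#' @param n_proteins Total number of simulated proteins (receptors included).
#' @param genotypes Ordered genotype series; the first label is the
#'   reference (wild type), each later label adds one deletion step.
#' @param replicates Biological replicates per genotype (>= 2; residual
#'   variance and t-tests need at least two).
#' @param peptides_mean Mean number of PSMs per protein; per-protein counts
#'   are `1 + Poisson(peptides_mean - 1)` so every protein has at least one.
#' @param noise_sigma Replicate noise standard deviation on the log2 scale.
#' @param effect_sparsity Probability that a protein carries a nonzero
#'   background effect at any given deletion step.
#' @param effect_scale Standard deviation (log2 units) of background effects.
#' @param frac_fail_snr,frac_fail_purity Fractions of PSMs drawn to fail the
#'   summed signal-to-noise (<= 200) and isolation-purity (<= 0.5) filters.
#' @param n_er Number of ER proteins (receptors count towards this).
#' @param er_membrane_frac,er_lumen_frac Fractions of ER proteins assigned to
#'   the ER-membrane and ER-lumen classes; the remainder is ER-associated.
#' @param er_step1_mean Expected mean step-1 (WT to DKO) log2 effect over the
#'   ER proteome. Set to 0 for a null simulation.
#' @param er_membrane_enrich Ratio of the ER-membrane step-1 effect mean to
#'   the other ER classes' mean.
#' @param er_step4_mean Mean step-4 (QKO to PKO) log2 effect over ER-lumen
#'   proteins. Set to 0 for a null simulation.
#' @param er_effect_sd Standard deviation of the ER signature effects.
#' @param receptors Data frame of designated receptor deletions with columns
#'   `protein_id`, `step` (1-based deletion step) and `effect` (log2), or
#'   `NULL` for none. See [default_receptors()].
#' @param peptide_share_sdlog Log-sd of the lognormal peptide share weights.
#' @param qc_perturb_range Multiplicative per-channel perturbation range
#'   applied to QC-failing PSMs, so filtering is consequential.
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical outputs.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_proteins = 200, n_er = 40, seed = 7)
#' cfg$genotypes
#' @export
sim_config <- function(n_proteins = 8000,
                       genotypes = c("WT", "DKO", "TKO", "QKO", "PKO"),
                       replicates = 3,
                       peptides_mean = 3,
                       noise_sigma = 0.25,
                       effect_sparsity = 0.2,
                       effect_scale = 0.5,
                       frac_fail_snr = 0.05,
                       frac_fail_purity = 0.05,
                       n_er = 359,
                       er_membrane_frac = 0.5,
                       er_lumen_frac = 0.25,
                       er_step1_mean = 0.21,
                       er_membrane_enrich = 2,
                       er_step4_mean = 0.2,
                       er_effect_sd = 0.25,
                       receptors = default_receptors(),
                       peptide_share_sdlog = 1,
                       qc_perturb_range = c(0.1, 10),
                       seed = 1L) {
  check_scalar(n_proteins, "n_proteins", lower = 1, integer = TRUE)
  if (!is.character(genotypes) || length(genotypes) < 2L ||
      anyDuplicated(genotypes)) {
    abort("invalid configuration field `genotypes`: need >= 2 unique labels")
  }
  check_scalar(replicates, "replicates", lower = 2, integer = TRUE)
  check_scalar(peptides_mean, "peptides_mean", lower = 1)
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  check_scalar(effect_sparsity, "effect_sparsity", lower = 0, upper = 1)
  check_scalar(effect_scale, "effect_scale", lower = 0)
  check_scalar(frac_fail_snr, "frac_fail_snr", lower = 0, upper = 1)
  check_scalar(frac_fail_purity, "frac_fail_purity", lower = 0, upper = 1)
  check_scalar(n_er, "n_er", lower = 0, integer = TRUE)
  if (n_er > n_proteins) {
    abort("invalid configuration field `n_er`: cannot exceed n_proteins")
  }
  check_scalar(er_membrane_frac, "er_membrane_frac", lower = 0, upper = 1)
  check_scalar(er_lumen_frac, "er_lumen_frac", lower = 0, upper = 1)
  if (er_membrane_frac + er_lumen_frac > 1) {
    abort("er_membrane_frac + er_lumen_frac must be <= 1")
  }
  check_scalar(er_step1_mean, "er_step1_mean")
  check_scalar(er_membrane_enrich, "er_membrane_enrich", lower = 0)
  check_scalar(er_step4_mean, "er_step4_mean")
  check_scalar(er_effect_sd, "er_effect_sd", lower = 0)
  check_scalar(peptide_share_sdlog, "peptide_share_sdlog", lower = 0)
  if (!is.numeric(qc_perturb_range) || length(qc_perturb_range) != 2L ||
      any(qc_perturb_range <= 0) || diff(qc_perturb_range) < 0) {
    abort("invalid configuration field `qc_perturb_range`")
  }
  check_scalar(seed, "seed", integer = TRUE)
  n_steps <- length(genotypes) - 1L
  if (!is.null(receptors)) {
    check_columns(receptors, c("protein_id", "step", "effect"), "receptors")
    if (anyDuplicated(receptors$protein_id)) {
      abort("receptors has duplicated protein_id values")
    }
    if (any(receptors$step < 1 | receptors$step > n_steps)) {
      abort(paste0("receptor step must be in 1..", n_steps))
    }
    if (nrow(receptors) > n_er) {
      abort("more designated receptors than ER proteins (n_er)")
    }
    receptors <- tibble::as_tibble(receptors)
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      genotypes = genotypes,
      replicates = as.integer(replicates),
      peptides_mean = peptides_mean,
      noise_sigma = noise_sigma,
      effect_sparsity = effect_sparsity,
      effect_scale = effect_scale,
      frac_fail_snr = frac_fail_snr,
      frac_fail_purity = frac_fail_purity,
      n_er = as.integer(n_er),
      er_membrane_frac = er_membrane_frac,
      er_lumen_frac = er_lumen_frac,
      er_step1_mean = er_step1_mean,
      er_membrane_enrich = er_membrane_enrich,
      er_step4_mean = er_step4_mean,
      er_effect_sd = er_effect_sd,
      receptors = receptors,
      peptide_share_sdlog = peptide_share_sdlog,
      qc_perturb_range = qc_perturb_range,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default designated ER-phagy receptor deletions
#'
#' The allelic series deletes FAM134A and FAM134C first (DKO), then FAM134B
#' (TKO), then TEX264 (QKO), then CCPG1 (PKO). Each deletion is imprinted as
#' a -2.5 log2 effect at its step and zero at every other step, so a deleted
#' receptor drops once and then stays at its reduced abundance.
#'
#' @return Tibble with columns `protein_id`, `step`, `effect`.
#' @export
default_receptors <- function() {
  tibble::tibble(
    protein_id = c("FAM134A", "FAM134C", "FAM134B", "TEX264", "CCPG1"),
    step = c(1L, 1L, 2L, 3L, 4L),
    effect = -2.5
  )
}

#' Fully null variant of a simulation configuration
#'
#' Convenience for calibration studies: zeroes the background effect
#' sparsity, the ER signature means and removes designated receptors, so
#' every true effect is exactly zero.
#'
#' @param ... Passed to [sim_config()].
#' @return A `sim_config` with all true effects zero.
#' @export
sim_config_null <- function(...) {
  sim_config(..., effect_sparsity = 0, er_step1_mean = 0, er_step4_mean = 0,
             receptors = NULL)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  series: ", paste(x$genotypes, collapse = " -> "),
      " (", x$replicates, " replicates each)\n", sep = "")
  cat("  proteins: ", x$n_proteins, " (", x$n_er, " ER",
      if (!is.null(x$receptors)) paste0(", ", nrow(x$receptors), " receptors"),
      ")\n", sep = "")
  cat("  noise_sigma: ", x$noise_sigma, " log2; effect sparsity ",
      x$effect_sparsity, ", scale ", x$effect_scale, "\n", sep = "")
  cat("  QC failure fractions: snr ", x$frac_fail_snr, ", purity ",
      x$frac_fail_purity, "\n", sep = "")
  cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}
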