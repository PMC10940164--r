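#' Generate the ground-truth table for a synthetic allelic series
#'
#' Draws one row per protein: a baseline log2 abundance, the true per-step
#' log2 effects (`beta1`..`beta4` for a five-genotype series), an ER
#' compartment class and receptor annotations. Effects have three layers:
#' sparse mean-zero background effects for every protein, an ER remodelling
#' signature (step-1 effects over all ER proteins, membrane-enriched;
#' step-4 effects over ER-lumen proteins), and the designated receptor
#' deletions, which overwrite the receptor rows with their configured
#' effect at the deletion step and zero elsewhere.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `protein_id`, `baseline_log2`,
#'   `beta1`..`beta<K-1>`, `er_class`, `organelle`, `is_receptor`,
#'   `deleted_step`.
#' @examples
#' truth <- generate_truth(sim_config(n_proteins = 100, n_er = 20, seed = 1))
#' head(truth)
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  n_steps <- length(config$genotypes) - 1L

  receptors <- config$receptors
  n_rec <- if (is.null(receptors)) 0L else nrow(receptors)

  # Identifiers: designated receptors keep their gene names, the rest get
  # synthetic accessions.
  ids <- sprintf("P%05d", seq_len(n))
  if (n_rec > 0L) ids[seq_len(n_rec)] <- receptors$protein_id

  # Compartment assignment: the first n_er proteins are ER (receptors are
  # ER-membrane by construction); membrane / lumen / associated split by the
  # configured fractions, shuffled among the non-receptor ER proteins.
  er_class <- rep("none", n)
  if (config$n_er > 0L) {
    n_free <- config$n_er - n_rec
    n_mem <- max(0L, round(config$er_membrane_frac * config$n_er) - n_rec)
    n_mem <- min(n_mem, n_free)
    n_lum <- min(n_free - n_mem, round(config$er_lumen_frac * config$n_er))
    n_ass <- n_free - n_mem - n_lum
    free_classes <- sample(rep(
      c("ER-membrane", "ER-lumen", "ER-associated"),
      times = c(n_mem, n_lum, n_ass)
    ))
    er_class[seq_len(config$n_er)] <-
      c(rep("ER-membrane", n_rec), free_classes)
  }
  is_er <- er_class != "none"

  baseline_log2 <- rnorm(n, mean = 10, sd = 1.5)

  # Layer 1: sparse background effects, mean zero, every protein/step.
  beta <- matrix(0, nrow = n, ncol = n_steps)
  if (config$effect_sparsity > 0 && config$effect_scale > 0) {
    active <- matrix(
      rbinom(n * n_steps, 1L, config$effect_sparsity) == 1L,
      nrow = n
    )
    beta[active] <- rnorm(sum(active), 0, config$effect_scale)
  }

  # Layer 2: ER remodelling signature. Step-1 means are scaled so the
  # ER-proteome-wide expectation equals er_step1_mean with the configured
  # membrane enrichment; step 4 shifts ER-lumen proteins only.
  if (any(is_er) && config$er_step1_mean != 0) {
    f_mem <- mean(er_class[is_er] == "ER-membrane")
    denom <- f_mem * config$er_membrane_enrich + (1 - f_mem)
    mu_other <- config$er_step1_mean / denom
    mu <- ifelse(er_class == "ER-membrane",
                 config$er_membrane_enrich * mu_other, mu_other)
    beta[is_er, 1L] <- beta[is_er, 1L] +
      rnorm(sum(is_er), mu[is_er], config$er_effect_sd)
  }
  lum <- er_class == "ER-lumen"
  if (any(lum) && config$er_step4_mean != 0 && n_steps >= 4L) {
    beta[lum, n_steps] <- beta[lum, n_steps] +
      rnorm(sum(lum), config$er_step4_mean, config$er_effect_sd)
  }

  # Layer 3: designated receptor deletions overwrite their rows.
  deleted_step <- rep(NA_integer_, n)
  if (n_rec > 0L) {
    for (i in seq_len(n_rec)) {
      beta[i, ] <- 0
      beta[i, receptors$step[i]] <- receptors$effect[i]
      deleted_step[i] <- as.integer(receptors$step[i])
    }
  }

  out <- tibble::tibble(
    protein_id = ids,
    baseline_log2 = baseline_log2,
    er_class = er_class,
    organelle = ifelse(is_er, "ER", "other"),
    is_receptor = seq_len(n) <= n_rec,
    deleted_step = deleted_step
  )
  beta_df <- tibble::as_tibble(as.data.frame(beta))
  names(beta_df) <- paste0("beta", seq_len(n_steps))
  dplyr::bind_cols(out[, 1:2], beta_df, out[, -(1:2)])
}

#' Plex design for a synthetic allelic-series TMT experiment
#'
#' One channel per genotype x replicate, in series order.
#'
#' @param config A [sim_config()].
#' @param condition Condition label stored for every channel.
#' @return Tibble with columns `channel`, `sample_id`, `genotype`,
#'   `replicate`, `condition`.
#' @export
plex_design <- function(config, condition = "base") {
  stopifnot(inherits(config, "sim_config"))
  genotype <- rep(config$genotypes, each = config$replicates)
  replicate <- rep(seq_len(config$replicates), times = length(config$genotypes))
  tibble::tibble(
    channel = sprintf("ch%02d", seq_along(genotype)),
    sample_id = paste(genotype, replicate, sep = "_"),
    genotype = genotype,
    replicate = replicate,
    condition = condition
  )
}

#' Simulate the protein x sample intensity matrix
#'
#' The log2 intensity of protein p in sample s is
#' `baseline_log2(p) + sum_k beta_k(p) * x_k(genotype(s)) + eps`, with
#' `x_k` the cumulative deletion indicators of the allelic series and
#' `eps ~ Normal(0, noise_sigma^2)` independent per cell. Intensities are
#' returned on the linear scale.
#'
#' @param truth Output of [generate_truth()].
#' @param config The matching [sim_config()].
#' @return Tibble with `protein_id` and one intensity column per sample; the
#'   plex design is attached as attribute `"design"`.
#' @export
simulate_protein_matrix <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  check_columns(truth, c("protein_id", "baseline_log2"), "truth")
  design <- plex_design(config)
  if (!all(design$genotype %in% config$genotypes)) {
    abort("design contains genotype labels outside the configured series")
  }
  n_steps <- length(config$genotypes) - 1L
  beta_cols <- paste0("beta", seq_len(n_steps))
  check_columns(truth, beta_cols, "truth")

  set.seed(config$seed + 1L)
  # Staircase indicators per sample: x_k = 1 iff the genotype lies beyond
  # deletion step k in the series.
  g_idx <- match(design$genotype, config$genotypes)
  X <- outer(g_idx, seq_len(n_steps), function(g, k) as.numeric(g > k))
  beta <- as.matrix(truth[, beta_cols])
  log2_mean <- truth$baseline_log2 + beta %*% t(X)  # proteins x samples
  eps <- matrix(rnorm(length(log2_mean), 0, config$noise_sigma),
                nrow = nrow(log2_mean))
  intensity <- 2^(log2_mean + eps)
  colnames(intensity) <- design$sample_id

  out <- dplyr::bind_cols(
    tibble::tibble(protein_id = truth$protein_id),
    tibble::as_tibble(intensity)
  )
  attr(out, "design") <- design
  out
}

# Random peptide-like sequence strings (identifiers only).
random_peptides <- function(n, min_len = 8L, max_len = 15L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  len <- sample(min_len:max_len, n, replace = TRUE)
  vapply(len, function(l) paste(sample(aa, l, replace = TRUE), collapse = ""),
         character(1))
}

#' Simulate a PSM-level quantification table
#'
#' Splits every protein's per-channel intensity across one or more PSMs with
#' lognormal share weights that are identical across channels, so summing
#' the PSMs of a protein reproduces its intensities exactly. Summed
#' signal-to-noise and isolation-purity attributes are drawn so that the
#' configured fractions fall at or below the 200 and 0.5 filter thresholds,
#' and QC-failing PSMs have each channel perturbed multiplicatively so that
#' filtering is consequential.
#'
#' @param pq Output of [simulate_protein_matrix()].
#' @param config The matching [sim_config()].
#' @param design Plex design; defaults to the one attached to `pq`.
#' @return Tibble with columns `protein_id`, `peptide`, one intensity column
#'   per sample, `summed_snr`, `isolation_purity`.
#' @export
simulate_psm_table <- function(pq, config, design = attr(pq, "design")) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(design)) abort("no plex design supplied or attached to `pq`")
  cols <- intensity_cols(pq, design)

  set.seed(config$seed + 2L)
  n_prot <- nrow(pq)
  n_pep <- 1L + rpois(n_prot, config$peptides_mean - 1)
  total <- sum(n_pep)
  # Lognormal shares per protein, normalised to sum to one.
  shares <- rlnorm(total, 0, config$peptide_share_sdlog)
  prot_of <- rep(seq_len(n_prot), times = n_pep)
  shares <- shares / ave(shares, prot_of, FUN = sum)

  mat <- as.matrix(pq[, cols])
  psm_int <- mat[prot_of, , drop = FALSE] * shares

  fail_snr <- rbinom(total, 1L, config$frac_fail_snr) == 1L
  fail_pur <- rbinom(total, 1L, config$frac_fail_purity) == 1L
  summed_snr <- ifelse(fail_snr,
                       runif(total, 0, 200),
                       200 * exp(runif(total, 0.01, 3)))
  isolation_purity <- ifelse(fail_pur,
                             runif(total, 0, 0.5),
                             runif(total, 0.55, 1))
  bad <- which(fail_snr | fail_pur)
  if (length(bad) > 0L) {
    pr <- config$qc_perturb_range
    pert <- matrix(runif(length(bad) * length(cols), pr[1], pr[2]),
                   nrow = length(bad))
    psm_int[bad, ] <- psm_int[bad, ] * pert
  }

  out <- dplyr::bind_cols(
    tibble::tibble(
      protein_id = pq$protein_id[prot_of],
      peptide = random_peptides(total)
    ),
    tibble::as_tibble(psm_int)
  )
  out$summed_snr <- summed_snr
  out$isolation_purity <- isolation_purity
  attr(out, "design") <- design
  out
}

#' Simulate gated Keima flow-cytometry events
#'
#' Generates positive acidic (561-nm excitation) and neutral (445-nm
#' excitation) intensities whose population mean ratio converges to
#' `true_ratio`. With `bafa = TRUE` the acidified signal collapses to the
#' lysosome-inhibited baseline `bafa_ratio`, emulating bafilomycin-A1
#' treatment, so the sample can serve as the normalization denominator.
#'
#' @param true_ratio Target raw acidic/neutral population ratio (> 0).
#' @param n_events Number of events (>= 1).
#' @param bafa Logical; simulate a BAFA-treated control.
#' @param bafa_ratio Baseline raw ratio under lysosomal inhibition.
#' @param condition Condition label; defaults to `"BAFA"` for BAFA samples
#'   and `"ratio_<r>"` otherwise.
#' @param seed Integer seed.
#' @param sdlog_neutral Log-sd of the neutral intensity distribution.
#' @param sdlog_ratio Log-sd of the per-event ratio noise (mean-one
#'   lognormal, so the population ratio is unbiased).
#' @return Tibble with columns `event_id`, `acidic_561`, `neutral_445`,
#'   `condition`.
#' @export
simulate_flow_events <- function(true_ratio, n_events, bafa = FALSE,
                                 bafa_ratio = 0.25, condition = NULL,
                                 seed = 1L, sdlog_neutral = 0.5,
                                 sdlog_ratio = 0.3) {
  check_scalar(true_ratio, "true_ratio")
  if (true_ratio <= 0) {
    abort("invalid configuration field `true_ratio`: must be > 0")
  }
  check_scalar(n_events, "n_events", lower = 1, integer = TRUE)
  check_scalar(bafa_ratio, "bafa_ratio")
  if (bafa_ratio <= 0) {
    abort("invalid configuration field `bafa_ratio`: must be > 0")
  }
  set.seed(seed)
  r <- if (bafa) bafa_ratio else true_ratio
  neutral <- rlnorm(n_events, meanlog = log(1000), sdlog = sdlog_neutral)
  # Mean-one lognormal noise keeps E[acidic]/E[neutral] = r exactly.
  noise <- exp(rnorm(n_events, 0, sdlog_ratio) - sdlog_ratio^2 / 2)
  acidic <- r * neutral * noise
  if (is.null(condition)) {
    condition <- if (bafa) "BAFA" else sprintf("ratio_%g", true_ratio)
  }
  tibble::tibble(
    event_id = seq_len(n_events),
    acidic_561 = acidic,
    neutral_445 = neutral,
    condition = condition
  )
}

#' Annotation table for a synthetic truth table
#'
#' Builds an organelle annotation table in the convention where the number
#' of transmembrane segments is appended to the protein name as `_1`, `_2`
#' and so on. ER-membrane proteins (receptors included) get a TM-segment
#' suffix; lumenal, associated and non-ER proteins carry none.
#'
#' @param truth Output of [generate_truth()].
#' @param curvature_frac Fraction of non-receptor ER-membrane proteins
#'   flagged as curvature-inducing (reticulon-homology-domain-like).
#' @param seed Integer seed for the TM-segment counts.
#' @return Tibble with columns `name`, `organelle`, `er_class`,
#'   `is_curvature`, `is_receptor`.
#' @export
sim_annotations <- function(truth, curvature_frac = 0.2, seed = 1L) {
  check_columns(truth, c("protein_id", "er_class", "organelle", "is_receptor"),
                "truth")
  set.seed(seed)
  mem <- truth$er_class == "ER-membrane"
  tm <- integer(nrow(truth))
  tm[mem] <- 1L + rpois(sum(mem), 1.5)
  name <- ifelse(mem, paste0(truth$protein_id, "_", tm), truth$protein_id)
  is_curv <- mem & !truth$is_receptor &
    runif(nrow(truth)) < curvature_frac
  tibble::tibble(
    name = name,
    organelle = truth$organelle,
    er_class = truth$er_class,
    is_curvature = is_curv,
    is_receptor = truth$is_receptor
  )
}
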