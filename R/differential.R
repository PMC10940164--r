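#' Log2-transform and centre on the reference genotype
#'
#' Converts a linear-scale protein quantification to log2 and subtracts, per
#' protein, the mean over the reference-genotype replicates, so that the
#' reference mean of every row is exactly zero (geometric-mean centring on
#' the linear scale). Proteins without a positive reference intensity are
#' excluded and reported via the `"excluded"` attribute.
#'
#' @param pq Protein tibble (`protein_id` + linear-scale sample columns).
#' @param design Plex design mapping `sample_id` to `genotype`.
#' @param reference Reference genotype label (default `"WT"`).
#' @return Tibble of reference-centred log2 values with the same shape as
#'   `pq`; attribute `"excluded"` lists dropped proteins.
#' @examples
#' cfg <- sim_config(n_proteins = 50, n_er = 10, seed = 1)
#' pq <- simulate_protein_matrix(generate_truth(cfg), cfg)
#' centred <- center_log2(pq, plex_design(cfg))
#' rowMeans(centred[, paste0("WT_", 1:3)])  # all zero
#' @export
center_log2 <- function(pq, design = attr(pq, "design"), reference = "WT") {
  check_columns(pq, "protein_id", "pq")
  if (is.null(design)) abort("a plex design is required")
  check_columns(design, c("sample_id", "genotype"), "design")
  cols <- intensity_cols(pq, design)
  ref_cols <- design$sample_id[design$genotype == reference]
  ref_cols <- intersect(ref_cols, cols)
  if (length(ref_cols) == 0L) {
    abort(paste0("no samples of reference genotype '", reference, "'"))
  }
  mat <- log2(as.matrix(pq[, cols]))
  ref_mean <- rowMeans(mat[, ref_cols, drop = FALSE])
  usable <- is.finite(ref_mean)
  if (!all(usable)) {
    inform(paste0(
      sum(!usable),
      " protein(s) excluded: no finite reference quantification"
    ))
  }
  centred <- mat[usable, , drop = FALSE] - ref_mean[usable]
  out <- dplyr::bind_cols(
    tibble::tibble(protein_id = pq$protein_id[usable]),
    tibble::as_tibble(centred)
  )
  attr(out, "design") <- design
  attr(out, "reference") <- reference
  attr(out, "excluded") <- pq$protein_id[!usable]
  out
}

#' Per-protein two-sample t-tests between genotypes
#'
#' For every protein, compares the mutant genotype's centred log2 values to
#' the reference's with a two-sided Student's t-test (pooled variance by
#' default; Welch optionally). The log2 fold change is the difference of
#' group means. P-values are Benjamini-Hochberg adjusted across all tested
#' proteins within this comparison.
#'
#' Degenerate cases are flagged rather than dropped: proteins with fewer
#' than two finite replicates in either group get `NA` statistics and flag
#' `"insufficient_replicates"`; zero pooled variance yields p = 1 when the
#' means are equal and the smallest representable double otherwise, with
#' flag `"zero_variance"`.
#'
#' @param centred Centred log2 tibble from [center_log2()].
#' @param design Plex design.
#' @param mutant Mutant genotype label.
#' @param reference Reference genotype label (default `"WT"`).
#' @param welch Use Welch's unequal-variance t instead of pooled variance.
#' @return Tibble: `protein_id`, `comparison`, `log2fc`, `t_statistic`,
#'   `df`, `p_value`, `p_adjusted`, `n_reference`, `n_mutant`, `flag`.
#' @export
diff_test <- function(centred, design = attr(centred, "design"),
                      mutant, reference = "WT", welch = FALSE) {
  check_columns(centred, "protein_id", "centred")
  if (is.null(design)) abort("a plex design is required")
  mut_cols <- design$sample_id[design$genotype == mutant]
  ref_cols <- design$sample_id[design$genotype == reference]
  mut_cols <- intersect(mut_cols, names(centred))
  ref_cols <- intersect(ref_cols, names(centred))
  if (length(mut_cols) == 0L) abort(paste0("no samples of genotype '", mutant, "'"))
  if (length(ref_cols) == 0L) abort(paste0("no samples of genotype '", reference, "'"))

  m <- as.matrix(centred[, mut_cols, drop = FALSE])
  r <- as.matrix(centred[, ref_cols, drop = FALSE])
  n1 <- rowSums(is.finite(m))
  n0 <- rowSums(is.finite(r))
  mean1 <- rowMeans(m, na.rm = TRUE)
  mean0 <- rowMeans(r, na.rm = TRUE)
  var1 <- apply(m, 1L, stats::var, na.rm = TRUE)
  var0 <- apply(r, 1L, stats::var, na.rm = TRUE)
  log2fc <- mean1 - mean0

  if (welch) {
    se2 <- var1 / n1 + var0 / n0
    df <- se2^2 / ((var1 / n1)^2 / (n1 - 1) + (var0 / n0)^2 / (n0 - 1))
    tstat <- log2fc / sqrt(se2)
  } else {
    df <- n1 + n0 - 2
    sp2 <- ((n1 - 1) * var1 + (n0 - 1) * var0) / df
    tstat <- log2fc / sqrt(sp2 * (1 / n1 + 1 / n0))
  }
  p <- 2 * pt(-abs(tstat), df)

  flag <- rep(NA_character_, nrow(centred))
  insuff <- n1 < 2 | n0 < 2
  zerovar <- !insuff & is.finite(log2fc) & !is.finite(tstat)
  flag[insuff] <- "insufficient_replicates"
  flag[zerovar] <- "zero_variance"
  p[zerovar] <- ifelse(log2fc[zerovar] == 0, 1, .Machine$double.xmin)
  tstat[zerovar] <- ifelse(log2fc[zerovar] == 0, 0, Inf * sign(log2fc[zerovar]))
  p[insuff] <- NA_real_
  log2fc[insuff] <- NA_real_

  padj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  padj[ok] <- p.adjust(p[ok], method = "BH")

  tibble::tibble(
    protein_id = centred$protein_id,
    comparison = paste(mutant, "vs", reference),
    log2fc = log2fc,
    t_statistic = tstat,
    df = df,
    p_value = p,
    p_adjusted = padj,
    n_reference = n0,
    n_mutant = n1,
    flag = flag
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment: `p(i) * m / i` with
#' cumulative minima from the largest rank, capped at 1, returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("p must be numeric")
  bad <- is.finite(p) & (p < 0 | p > 1)
  if (any(bad) || any(is.nan(p))) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}
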