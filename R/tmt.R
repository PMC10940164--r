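#' Filter PSMs on summed signal-to-noise and isolation purity
#'
#' Retains exactly the PSMs whose summed reporter signal-to-noise across the
#' plex is strictly greater than `min_snr` and whose precursor isolation
#' purity is strictly greater than `min_purity`, in input order. Both
#' inequalities are strict: a PSM sitting exactly at a threshold is removed.
#'
#' @param psms PSM tibble with `summed_snr` and `isolation_purity` columns.
#' @param min_snr Summed signal-to-noise threshold (default 200).
#' @param min_purity Isolation purity threshold (default 0.5).
#' @return The retained PSMs, with a `"provenance"` attribute recording the
#'   thresholds and the counts removed. An empty result raises a warning,
#'   not an error.
#' @examples
#' cfg <- sim_config(n_proteins = 50, n_er = 10, seed = 1)
#' psms <- simulate_psm_table(simulate_protein_matrix(generate_truth(cfg), cfg), cfg)
#' filtered <- filter_psms(psms)
#' attr(filtered, "provenance")
#' @export
filter_psms <- function(psms, min_snr = 200, min_purity = 0.5) {
  check_columns(psms, c("summed_snr", "isolation_purity"), "psms")
  check_scalar(min_snr, "min_snr", lower = 0)
  check_scalar(min_purity, "min_purity", lower = 0)
  keep <- psms$summed_snr > min_snr & psms$isolation_purity > min_purity
  out <- psms[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warn("all PSMs removed by QC filtering")
  }
  attr(out, "design") <- attr(psms, "design")
  attr(out, "provenance") <- list(
    min_snr = min_snr,
    min_purity = min_purity,
    n_input = nrow(psms),
    n_removed_snr = sum(psms$summed_snr <= min_snr),
    n_removed_purity = sum(psms$isolation_purity <= min_purity),
    n_removed = sum(!keep),
    n_retained = sum(keep)
  )
  out
}

#' Sum-normalize reporter channels to the median channel total
#'
#' All PSM intensities are summed per channel and each channel is rescaled
#' by `factor_c = median(totals) / total_c`, so that after normalization
#' every channel total equals the median of the original totals. For an even
#' number of channels the median is the midpoint of the two central totals.
#'
#' The same operation applies unchanged to a protein-level matrix, since
#' summation and rescaling commute.
#'
#' @param x PSM (or protein) tibble with intensity columns.
#' @param design Optional plex design used to locate intensity columns.
#' @return `x` with normalized intensities; per-channel factors are attached
#'   as attribute `"norm_factors"`.
#' @export
normalize_channels <- function(x, design = attr(x, "design")) {
  cols <- intensity_cols(x, design)
  if (nrow(x) == 0L) abort("cannot normalize an empty table")
  totals <- vapply(x[cols], sum, numeric(1))
  zero <- totals == 0
  if (any(zero)) {
    abort(paste0(
      "channel(s) with zero total intensity: ",
      paste(cols[zero], collapse = ", ")
    ))
  }
  factors <- median(totals) / totals
  for (i in seq_along(cols)) {
    x[[cols[i]]] <- x[[cols[i]]] * factors[i]
  }
  attr(x, "norm_factors") <- setNames(factors, cols)
  x
}

#' Roll PSM intensities up to proteins
#'
#' Each protein x channel value is the sum of that protein's PSM intensities
#' in the channel — summing input-normalized reporter intensities acts as an
#' abundance-weighted average over the constituent peptides. Proteins with
#' no PSMs are absent from the output (no zero rows); rows are ordered by
#' accession. An optional allow-list drops PSMs from unlisted proteins with
#' a message.
#'
#' @param psms Filtered, normalized PSM tibble.
#' @param design Optional plex design used to locate intensity columns.
#' @param proteins Optional character allow-list of protein accessions.
#' @return Protein-by-sample tibble (`protein_id` + one column per channel).
#' @export
rollup_proteins <- function(psms, design = attr(psms, "design"),
                            proteins = NULL) {
  check_columns(psms, "protein_id", "psms")
  cols <- intensity_cols(psms, design)
  if (!is.null(proteins)) {
    drop <- !psms$protein_id %in% proteins
    if (any(drop)) {
      inform(paste0(
        sum(drop), " PSM(s) dropped: protein not in allow-list"
      ))
      psms <- psms[!drop, , drop = FALSE]
    }
  }
  out <- psms |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(cols), sum),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$protein_id)
  attr(out, "design") <- design
  out
}
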