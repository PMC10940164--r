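#' Parse an ER/organelle annotation table
#'
#' Reads an annotation table in the convention where the number of
#' transmembrane segments is appended to the protein name as `_1`, `_2`
#' and so on: the numeric suffix is stripped from the identifier and stored
#' as `tm_count` (0 when absent). Proteins with a non-`none` ER class are
#' required to carry the ER organelle label. Duplicate identifiers after
#' suffix stripping are an error.
#'
#' @param x Path to a delimited file (TSV/CSV) or a data frame with at
#'   least a `name` column; `organelle`, `er_class`, `is_curvature` and
#'   `is_receptor` are carried through when present.
#' @return Tibble: `protein_id`, `tm_count`, `organelle`, `er_class`,
#'   `is_curvature`, `is_receptor`.
#' @examples
#' parse_annotations(data.frame(name = c("VAPA_1", "CALR"),
#'                              er_class = c("ER-membrane", "ER-lumen")))
#' @export
parse_annotations <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    delim <- if (grepl("\\.csv$", x, ignore.case = TRUE)) "," else "\t"
    x <- readr::read_delim(x, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  }
  check_columns(x, "name", "annotation table")
  name <- as.character(x$name)
  has_tm <- grepl("_[0-9]+$", name)
  tm_count <- integer(length(name))
  tm_count[has_tm] <- as.integer(sub("^.*_([0-9]+)$", "\\1", name[has_tm]))
  protein_id <- ifelse(has_tm, sub("_[0-9]+$", "", name), name)

  dup <- unique(protein_id[duplicated(protein_id)])
  if (length(dup) > 0L) {
    abort(paste0(
      "duplicated protein id(s) in annotation: ", paste(dup, collapse = ", ")
    ))
  }

  er_class <- if ("er_class" %in% names(x)) as.character(x$er_class) else
    rep("none", length(name))
  er_class[is.na(er_class)] <- "none"
  organelle <- if ("organelle" %in% names(x)) as.character(x$organelle) else
    ifelse(er_class != "none", "ER", NA_character_)
  bad <- er_class != "none" & !is.na(organelle) & organelle != "ER"
  if (any(bad)) {
    abort(paste0(
      "protein(s) with an ER class but a non-ER organelle: ",
      paste(protein_id[bad], collapse = ", ")
    ))
  }
  organelle[er_class != "none"] <- "ER"

  tibble::tibble(
    protein_id = protein_id,
    tm_count = tm_count,
    organelle = organelle,
    er_class = er_class,
    is_curvature = if ("is_curvature" %in% names(x)) as.logical(x$is_curvature)
      else rep(FALSE, length(name)),
    is_receptor = if ("is_receptor" %in% names(x)) as.logical(x$is_receptor)
      else rep(FALSE, length(name))
  )
}

#' Randomized-selection Kolmogorov-Smirnov null test
#'
#' Compares the value distribution of a protein group (for example the
#' beta coefficients of the ER proteome) against randomized selections of
#' the same number of proteins drawn uniformly without replacement from the
#' quantified background (group members may be redrawn). Each of the
#' `iterations` draws is tested against the group with a two-sided
#' two-sample Kolmogorov-Smirnov test; the full set of iteration p-values
#' is returned together with their median, the fraction below `alpha`, and
#' a single pooled test of the group against all draws concatenated.
#'
#' Because draws can share members with the group, tied values are
#' expected; the asymptotic two-sided p-value is used and the tie warning
#' is suppressed.
#'
#' @param values Named numeric vector (names = protein ids), or a data
#'   frame with `protein_id` and `value` columns, covering the quantified
#'   background.
#' @param group_ids Character vector of group member ids.
#' @param iterations Number of randomized selections (default 100).
#' @param seed Optional integer seed.
#' @param alpha Significance level for the iteration summary.
#' @param group_label Label stored in the result.
#' @return A `ks_null` object; see [tidy()] and [glance()] methods.
#' @export
randomized_null_ks <- function(values, group_ids, iterations = 100L,
                               seed = NULL, alpha = 0.05,
                               group_label = "group") {
  if (is.data.frame(values)) {
    check_columns(values, c("protein_id", "value"), "values")
    values <- setNames(values$value, values$protein_id)
  }
  if (is.null(names(values))) abort("values must be named by protein id")
  values <- values[is.finite(values)]
  if (length(unique(group_ids)) > length(values)) {
    abort("group larger than the quantified background")
  }
  group_ids <- intersect(group_ids, names(values))
  m <- length(group_ids)
  if (m < 2L) abort("group must contain >= 2 quantified proteins")
  if (m > length(values)) abort("group larger than the quantified background")
  check_scalar(iterations, "iterations", lower = 1, integer = TRUE)
  if (!is.null(seed)) set.seed(seed)

  group_values <- values[group_ids]
  p_values <- numeric(iterations)
  draws <- vector("list", iterations)
  for (i in seq_len(iterations)) {
    draw <- sample(values, m)
    draws[[i]] <- draw
    p_values[i] <- suppressWarnings(
      ks.test(group_values, draw, alternative = "two.sided")$p.value
    )
  }
  pooled_p <- suppressWarnings(
    ks.test(group_values, unlist(draws), alternative = "two.sided")$p.value
  )
  structure(
    list(
      group_label = group_label,
      n_group = m,
      n_background = length(values),
      iterations = iterations,
      p_values = p_values,
      median_p = median(p_values),
      frac_significant = mean(p_values < alpha),
      pooled_p = pooled_p,
      alpha = alpha
    ),
    class = "ks_null"
  )
}

#' @export
print.ks_null <- function(x, ...) {
  cat("<ks_null> ", x$group_label, ": n = ", x$n_group, " vs background ",
      x$n_background, ", ", x$iterations, " randomized selections\n",
      sep = "")
  cat("  median p = ", signif(x$median_p, 3),
      "; fraction p < ", x$alpha, " = ", signif(x$frac_significant, 3),
      "; pooled p = ", signif(x$pooled_p, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname randomized_null_ks
#' @param x A `ks_null` object.
#' @param ... Unused.
#' @method tidy ks_null
#' @export
tidy.ks_null <- function(x, ...) {
  tibble::tibble(
    group = x$group_label,
    iteration = seq_len(x$iterations),
    p.value = x$p_values
  )
}

#' @rdname randomized_null_ks
#' @method glance ks_null
#' @export
glance.ks_null <- function(x, ...) {
  tibble::tibble(
    group = x$group_label,
    n_group = x$n_group,
    n_background = x$n_background,
    iterations = x$iterations,
    median_p = x$median_p,
    frac_significant = x$frac_significant,
    pooled_p = x$pooled_p
  )
}

#' One-sample Wilcoxon signed-rank test of coefficients against zero
#'
#' Tests whether a compartment's beta coefficients depart from zero with a
#' one-sided (default: greater) Wilcoxon signed-rank test, Bonferroni
#' adjusted for the number of comparisons in the panel. Zero values are
#' dropped (signed-rank convention); the exact distribution is used for
#' n <= 25 without ties, the normal approximation with continuity
#' correction otherwise. If every value is zero, p = 1 with a degenerate
#' flag.
#'
#' @param beta Numeric vector of coefficients.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param n_comparisons Bonferroni multiplier (default 1).
#' @return One-row tibble: `statistic`, `p_value`, `p_adjusted`, `n`,
#'   `n_zero_dropped`, `alternative`, `degenerate`.
#' @examples
#' wilcoxon_beta_vs_zero(c(1, 2, 3, 4, 5))  # exact p = 1/32
#' @export
wilcoxon_beta_vs_zero <- function(beta, alternative = "greater",
                                  n_comparisons = 1L) {
  if (!is.numeric(beta)) abort("beta must be numeric")
  check_scalar(n_comparisons, "n_comparisons", lower = 1, integer = TRUE)
  beta <- beta[is.finite(beta)]
  nz <- beta[beta != 0]
  n_dropped <- length(beta) - length(nz)
  if (length(nz) == 0L) {
    return(tibble::tibble(
      statistic = NA_real_, p_value = 1, p_adjusted = 1,
      n = 0L, n_zero_dropped = n_dropped,
      alternative = alternative, degenerate = TRUE
    ))
  }
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(
    wilcox.test(nz, mu = 0, alternative = alternative, exact = exact,
                correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    p_adjusted = min(1, wt$p.value * n_comparisons),
    n = length(nz),
    n_zero_dropped = n_dropped,
    alternative = alternative,
    degenerate = FALSE
  )
}

#' Paired Wilcoxon test between two genotypes
#'
#' Two-sided Wilcoxon signed-rank test on per-protein differences between
#' two genotypes' values, paired by protein. All-zero differences give
#' p = 1 with a degenerate flag.
#'
#' @param values_a,values_b Numeric vectors of per-protein values, aligned
#'   (same protein order).
#' @return One-row tibble: `statistic`, `p_value`, `n_pairs`,
#'   `n_zero_dropped`, `degenerate`.
#' @export
paired_wilcoxon_genotypes <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    abort("values_a and values_b must have the same length (paired)")
  }
  ok <- is.finite(values_a) & is.finite(values_b)
  d <- values_a[ok] - values_b[ok]
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    return(tibble::tibble(
      statistic = NA_real_, p_value = 1, n_pairs = length(d),
      n_zero_dropped = length(d), degenerate = TRUE
    ))
  }
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(
    wilcox.test(values_a[ok], values_b[ok], paired = TRUE,
                alternative = "two.sided", exact = exact, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n_pairs = length(d),
    n_zero_dropped = length(d) - length(nz),
    degenerate = FALSE
  )
}
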