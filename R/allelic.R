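#' Build the cumulative-indicator design for a sequential-knockout series
#'
#' Each deletion step k of the series gets an indicator column that is 1 for
#' every sample whose genotype lies at or beyond the k-th deletion and 0
#' otherwise, so the rows follow the staircase pattern (0,0,0,0) for WT,
#' (1,0,0,0) for DKO, (1,1,0,0) for TKO, (1,1,1,0) for QKO and (1,1,1,1)
#' for PKO. There is no intercept column: the model is fitted on
#' reference-centred values, so the wild-type mean is pinned at zero and
#' each coefficient is the mean log2 fold change between adjacent
#' genotypes.
#'
#' @param design Plex design tibble (`sample_id`, `genotype`).
#' @param series Ordered genotype labels, reference first.
#' @return An `allelic_design`: list with the indicator matrix `X`
#'   (samples x steps, step-labelled columns), `sample_id`, `genotype` and
#'   `series`.
#' @examples
#' cfg <- sim_config(n_proteins = 10, n_er = 2, seed = 1)
#' ad <- build_design(plex_design(cfg), cfg$genotypes)
#' unique(ad$X)
#' @export
build_design <- function(design,
                         series = c("WT", "DKO", "TKO", "QKO", "PKO")) {
  check_columns(design, c("sample_id", "genotype"), "design")
  if (length(series) < 2L || anyDuplicated(series)) {
    abort("series must contain >= 2 unique genotype labels")
  }
  unknown <- setdiff(unique(design$genotype), series)
  if (length(unknown) > 0L) {
    abort(paste0(
      "genotype(s) outside the series: ", paste(unknown, collapse = ", ")
    ))
  }
  n_steps <- length(series) - 1L
  mutants <- series[-1L]
  missing <- setdiff(mutants, design$genotype)
  if (length(missing) > 0L) {
    abort(paste0(
      "design is rank-deficient: no samples for mutant genotype(s) ",
      paste(missing, collapse = ", ")
    ))
  }
  g_idx <- match(design$genotype, series)
  X <- outer(g_idx, seq_len(n_steps), function(g, k) as.numeric(g > k))
  rownames(X) <- design$sample_id
  colnames(X) <- paste(series[-length(series)], series[-1L], sep = "->")
  structure(
    list(X = X, sample_id = design$sample_id, genotype = design$genotype,
         series = series),
    class = "allelic_design"
  )
}

# Closed-form estimate for the staircase design: beta_k is the difference
# between the (k+1)-th and k-th genotype sample means. On reference-centred
# values the reference sample mean is exactly zero, so beta_1 is simply the
# first mutant's mean. Used as the interpretation contract; the fit itself
# solves the normal equations.
beta_closed_form <- function(y, genotype, series) {
  means <- vapply(series, function(g) mean(y[genotype == g]), numeric(1))
  diff(means)
}

#' Fit the allelic-series linear model to every protein
#'
#' Solves, per protein, the least-squares problem `y = X beta + eps` on
#' reference-centred log2 values, where `X` is the cumulative-indicator
#' staircase of [build_design()]. Every coefficient is the mean log2 fold
#' change between adjacent genotypes; p-values are two-sided t and are
#' Benjamini-Hochberg adjusted across proteins separately for each step
#' (optionally pooled over all steps).
#'
#' Because the reference centring subtracts an *estimated* wild-type mean,
#' the default fit (`intercept = "nuisance"`) keeps an intercept nuisance
#' term alongside the staircase. The term's estimate is numerically zero on
#' centred data, so the coefficients are unchanged, but it propagates the
#' reference-mean uncertainty into the standard errors: without it, the
#' variance of the first-step coefficient is understated two-fold at equal
#' replication and one residual degree of freedom too many is claimed,
#' which makes step-1 p-values anti-conservative. `intercept = "none"`
#' drops the term and reproduces exactly the pinned-reference fit
#' (`lm(y ~ X - 1)` on centred values, se from `RSS/(n - k)` and
#' `(X'X)^{-1}`).
#'
#' Proteins with missing values are fitted on their finite samples when
#' every mutant genotype is still represented, and flagged
#' `"rank_deficient"` otherwise. Zero-residual fits (for example noise-free
#' synthetic data) are flagged `"zero_residual"`: coefficients are exact
#' but no inference is available, so p is 1 where the coefficient is 0 and
#' the smallest representable double otherwise. When `n - k <= 0` the
#' coefficients are returned with flag `"no_inference"` and `NA` p-values.
#'
#' @param centred Reference-centred log2 tibble from [center_log2()].
#' @param design Plex design.
#' @param series Ordered genotype series, reference first.
#' @param adjust `"per_step"` (default) or `"pooled"` Benjamini-Hochberg.
#' @param intercept `"nuisance"` (default: reference-mean uncertainty is
#'   propagated into the inference) or `"none"` (pinned reference).
#' @param extra_genotypes How to treat design samples whose genotype is not
#'   in the series: `"drop"` (default, with a message) or `"error"`.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @return An `allelic_fit` object; see [tidy()] and [glance()] methods.
#' @examples
#' cfg <- sim_config(n_proteins = 60, n_er = 12, seed = 3)
#' pq <- simulate_protein_matrix(generate_truth(cfg), cfg)
#' fit <- center_log2(pq, plex_design(cfg)) |> fit_allelic(plex_design(cfg))
#' tidy(fit)
#' @export
fit_allelic <- function(centred, design = attr(centred, "design"),
                        series = c("WT", "DKO", "TKO", "QKO", "PKO"),
                        adjust = c("per_step", "pooled"),
                        intercept = c("nuisance", "none"),
                        extra_genotypes = c("drop", "error"),
                        alpha = 0.05) {
  adjust <- match.arg(adjust)
  intercept <- match.arg(intercept)
  extra_genotypes <- match.arg(extra_genotypes)
  check_columns(centred, "protein_id", "centred")
  if (is.null(design)) abort("a plex design is required")
  check_columns(design, c("sample_id", "genotype"), "design")

  extra <- !design$genotype %in% series
  if (any(extra)) {
    if (extra_genotypes == "error") {
      abort(paste0(
        "genotype(s) outside the series: ",
        paste(unique(design$genotype[extra]), collapse = ", ")
      ))
    }
    inform(paste0(
      sum(extra), " sample(s) with genotypes outside the series dropped"
    ))
    design <- design[!extra, , drop = FALSE]
  }
  design <- design[design$sample_id %in% names(centred), , drop = FALSE]
  ad <- build_design(design, series)

  X <- ad$X
  k <- ncol(X)
  n <- nrow(X)
  Y <- as.matrix(centred[, ad$sample_id, drop = FALSE])
  p_ids <- centred$protein_id
  np <- length(p_ids)

  # Fitting matrix: optionally an intercept nuisance column ahead of the
  # staircase. Only the staircase columns are reported.
  nuis <- intercept == "nuisance"
  Xf <- if (nuis) cbind(`(ref)` = 1, X) else X
  sc <- if (nuis) 1L + seq_len(k) else seq_len(k)
  kf <- ncol(Xf)
  if (nuis && !ad$series[1L] %in% ad$genotype) {
    abort("intercept = \"nuisance\" needs reference-genotype samples")
  }
  # genotypes that must be present among a protein's finite samples
  required <- if (nuis) ad$series else ad$series[-1L]

  XtX_inv <- solve(crossprod(Xf))
  hat <- Xf %*% XtX_inv           # n x kf
  dfree <- n - kf

  beta <- matrix(NA_real_, np, k)
  se <- matrix(NA_real_, np, k)
  df_res <- rep(NA_integer_, np)
  flag <- rep(NA_character_, np)

  complete <- rowSums(is.finite(Y)) == n
  if (any(complete)) {
    B <- Y[complete, , drop = FALSE] %*% hat
    res <- Y[complete, , drop = FALSE] - B %*% t(Xf)
    rss <- rowSums(res^2)
    beta[complete, ] <- B[, sc, drop = FALSE]
    df_res[complete] <- dfree
    if (dfree > 0) {
      s2 <- rss / dfree
      se[complete, ] <- sqrt(outer(s2, diag(XtX_inv)[sc]))
      # zero-residual fits: exact coefficients, degenerate inference
      scale <- pmax(1, rowSums(Y[complete, , drop = FALSE]^2))
      flag[complete][rss <= 1e-12 * scale] <- "zero_residual"
    } else {
      flag[complete] <- "no_inference"
    }
  }

  # Incomplete proteins: refit on finite samples if every required
  # genotype is still represented.
  for (i in which(!complete)) {
    ok <- is.finite(Y[i, ])
    if (all(required %in% ad$genotype[ok]) && sum(ok) >= kf) {
      Xi <- Xf[ok, , drop = FALSE]
      XtXi <- solve(crossprod(Xi))
      b <- drop(XtXi %*% crossprod(Xi, Y[i, ok]))
      beta[i, ] <- b[sc]
      dfi <- sum(ok) - kf
      df_res[i] <- dfi
      if (dfi > 0) {
        rss_i <- sum((Y[i, ok] - drop(Xi %*% b))^2)
        se[i, ] <- sqrt(rss_i / dfi * diag(XtXi)[sc])
        if (rss_i <= 1e-12 * max(1, sum(Y[i, ok]^2))) {
          flag[i] <- "zero_residual"
        }
      } else {
        flag[i] <- "no_inference"
      }
    } else {
      flag[i] <- "rank_deficient"
    }
  }

  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df_res)
  degen <- which(flag %in% "zero_residual")
  if (length(degen) > 0L) {
    # coefficients numerically zero (below float round-off) count as zero
    p[degen, ] <- ifelse(abs(beta[degen, , drop = FALSE]) < 1e-10,
                         1, .Machine$double.xmin)
  }

  padj <- matrix(NA_real_, np, k)
  if (adjust == "per_step") {
    for (j in seq_len(k)) {
      ok <- !is.na(p[, j])
      padj[ok, j] <- p.adjust(p[ok, j], method = "BH")
    }
  } else {
    ok <- !is.na(p)
    padj[ok] <- p.adjust(p[ok], method = "BH")
  }

  steps <- colnames(X)
  dimnames(beta) <- dimnames(se) <- dimnames(p) <- dimnames(padj) <-
    list(p_ids, steps)
  structure(
    list(
      protein_id = p_ids,
      beta = beta, se = se, statistic = tstat, p = p, p_adjusted = padj,
      df_residual = df_res, flag = flag,
      steps = steps, series = series, adjust = adjust,
      intercept = intercept, alpha = alpha,
      n_samples = n, design = ad
    ),
    class = "allelic_fit"
  )
}

#' @export
print.allelic_fit <- function(x, ...) {
  cat("<allelic_fit> ", length(x$protein_id), " proteins, series ",
      paste(x$series, collapse = " -> "), "\n", sep = "")
  nsig <- colSums(x$p_adjusted < x$alpha, na.rm = TRUE)
  cat("  significant (adjusted p < ", x$alpha, ") per step:\n", sep = "")
  print(nsig)
  invisible(x)
}

#' Tidy an allelic-series fit into one row per protein and step
#'
#' @param x An `allelic_fit`.
#' @param ... Unused.
#' @return Tibble: `protein_id`, `step` (ordered factor), `estimate`,
#'   `std.error`, `statistic`, `p.value`, `p.adjusted`, `significant`,
#'   `flag`.
#' @method tidy allelic_fit
#' @export
tidy.allelic_fit <- function(x, ...) {
  k <- length(x$steps)
  tibble::tibble(
    protein_id = rep(x$protein_id, each = k),
    step = factor(rep(x$steps, times = length(x$protein_id)),
                  levels = x$steps, ordered = TRUE),
    estimate = as.vector(t(x$beta)),
    std.error = as.vector(t(x$se)),
    statistic = as.vector(t(x$statistic)),
    p.value = as.vector(t(x$p)),
    p.adjusted = as.vector(t(x$p_adjusted)),
    significant = as.vector(t(x$p_adjusted)) < x$alpha,
    flag = rep(x$flag, each = k)
  )
}

#' One-row summary of an allelic-series fit
#'
#' @param x An `allelic_fit`.
#' @param ... Unused.
#' @return Tibble with protein, sample and significance counts.
#' @method glance allelic_fit
#' @export
glance.allelic_fit <- function(x, ...) {
  tibble::tibble(
    n_proteins = length(x$protein_id),
    n_samples = x$n_samples,
    n_steps = length(x$steps),
    df_residual = x$n_samples - length(x$steps) -
      as.integer(x$intercept == "nuisance"),
    adjust = x$adjust,
    n_significant = sum(x$p_adjusted < x$alpha, na.rm = TRUE),
    n_flagged = sum(!is.na(x$flag))
  )
}

#' Mean beta coefficients per annotation group
#'
#' Joins fitted coefficients to an annotation table and returns, for every
#' group x step combination, the arithmetic mean coefficient and the number
#' of proteins behind it. Fitted proteins missing from the annotation are
#' kept under the group label `"unannotated"`, so counts are conserved.
#'
#' @param fit An `allelic_fit`.
#' @param annotations Annotation tibble with `protein_id` (e.g. from
#'   [parse_annotations()]).
#' @param group Name of the annotation column to group by.
#' @return Tibble: group column, `step`, `mean_beta`, `n`.
#' @export
summarize_beta <- function(fit, annotations, group = "er_class") {
  stopifnot(inherits(fit, "allelic_fit"))
  check_columns(annotations, c("protein_id", group), "annotations")
  td <- tidy(fit)
  ann <- annotations[, c("protein_id", group)]
  joined <- dplyr::left_join(td, ann, by = "protein_id")
  joined[[group]][is.na(joined[[group]])] <- "unannotated"
  joined |>
    dplyr::filter(is.finite(.data$estimate)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group, "step")))) |>
    dplyr::summarise(
      mean_beta = mean(.data$estimate),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Rank proteins on a coefficient or fold change
#'
#' Orders proteins by the chosen step's coefficient (or any value column of
#' a tabular result), descending, with ties broken by accession, and
#' returns the top accumulated and bottom depleted proteins. Significance
#' at adjusted p < 0.05 is marked with an asterisk.
#'
#' @param x An `allelic_fit` or a data frame of per-protein results.
#' @param ... Method arguments.
#' @return Tibble with `protein_id`, the ranking value, adjusted p,
#'   `label` (asterisked id), `direction` (`"top"`/`"bottom"`) and `rank`.
#' @export
rank_top <- function(x, ...) UseMethod("rank_top")

#' @rdname rank_top
#' @param step Deletion step to rank on (index or step label).
#' @param n_top,n_bottom Numbers of accumulated / depleted proteins.
#' @export
rank_top.allelic_fit <- function(x, step = 1L, n_top = 25L, n_bottom = 5L,
                                 ...) {
  if (is.character(step)) step <- match(step, x$steps)
  if (is.na(step) || step < 1L || step > length(x$steps)) {
    abort("unknown step")
  }
  tbl <- tibble::tibble(
    protein_id = x$protein_id,
    value = x$beta[, step],
    p_adjusted = x$p_adjusted[, step]
  )
  rank_top(tbl, value = "value", n_top = n_top, n_bottom = n_bottom)
}

#' @rdname rank_top
#' @param value Name of the value column to rank on (e.g. `"log2fc"`).
#' @param id Name of the identifier column.
#' @param padj Name of the adjusted-p column (optional).
#' @export
rank_top.data.frame <- function(x, value = "log2fc", id = "protein_id",
                                padj = "p_adjusted", n_top = 25L,
                                n_bottom = 5L, ...) {
  check_columns(x, c(id, value), "x")
  x <- x[is.finite(x[[value]]), , drop = FALSE]
  if (nrow(x) < n_top + n_bottom) {
    abort("fewer proteins than n_top + n_bottom")
  }
  ord <- order(-x[[value]], x[[id]])
  x <- x[ord, , drop = FALSE]
  pa <- if (padj %in% names(x)) x[[padj]] else rep(NA_real_, nrow(x))
  out <- tibble::tibble(
    protein_id = x[[id]],
    value = x[[value]],
    p_adjusted = pa,
    label = paste0(x[[id]], ifelse(!is.na(pa) & pa < 0.05, "*", "")),
    rank = seq_len(nrow(x))
  )
  top <- head(out, n_top)
  bottom <- tail(out, n_bottom)
  top$direction <- "top"
  bottom$direction <- "bottom"
  dplyr::bind_rows(top, bottom)
}
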