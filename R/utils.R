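# Shared helpers for column bookkeeping across PSM and protein tables.

# Reserved (non-intensity) columns in PSM / protein tables.
.reserved_cols <- c("protein_id", "peptide", "summed_snr", "isolation_purity")

#' Identify intensity columns of a quantification table
#'
#' Intensity columns are taken from the plex design's `sample_id` when a
#' design is supplied, otherwise every numeric column that is not one of the
#' reserved bookkeeping columns (`protein_id`, `peptide`, `summed_snr`,
#' `isolation_purity`).
#'
#' @param x A PSM or protein quantification tibble.
#' @param design Optional plex design tibble with a `sample_id` column.
#' @return Character vector of intensity column names, in table order.
#' @keywords internal
intensity_cols <- function(x, design = NULL) {
  if (!is.null(design)) {
    cols <- intersect(names(x), design$sample_id)
    if (length(cols) == 0L) {
      abort("none of the design's sample_id values match columns of the table")
    }
    return(cols)
  }
  num <- names(x)[vapply(x, is.numeric, logical(1))]
  cols <- setdiff(num, .reserved_cols)
  if (length(cols) == 0L) {
    abort("no intensity columns found; supply a plex design")
  }
  cols
}

# Stop unless x is a data frame containing all of `cols`.
check_columns <- function(x, cols, what = "input") {
  if (!is.data.frame(x)) abort(paste0(what, " must be a data frame"))
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0L) {
    abort(paste0(
      what, " is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

# Scalar validators used by configuration objects.
check_scalar <- function(value, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  ok <- is.numeric(value) && length(value) == 1L && is.finite(value) &&
    value >= lower && value <= upper && (!integer || value == trunc(value))
  if (!ok) {
    abort(paste0(
      "invalid configuration field `", name, "`: must be a ",
      if (integer) "whole number" else "finite number",
      if (is.finite(lower) || is.finite(upper)) {
        paste0(" in [", lower, ", ", upper, "]")
      } else "",
      " (got ", deparse(value), ")"
    ))
  }
  invisible(value)
}
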