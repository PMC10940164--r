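#' Raw Keima flux ratio per condition
#'
#' The acidic-to-neutral excitation ratio is the mean of the 561-nm excited
#' (acidic) intensities divided by the mean of the 445-nm excited (neutral)
#' intensities over a condition's gated events — the ratio of channel
#' means, not the mean of per-event ratios. A geometric-mean variant is
#' available.
#'
#' @param events Flow event tibble with `acidic_561`, `neutral_445` and
#'   `condition` columns.
#' @param mean_fun `"arithmetic"` (default, the literal reading) or
#'   `"geometric"`.
#' @return Tibble: `condition`, `raw_ratio`, `n_events`.
#' @examples
#' ev <- simulate_flow_events(3, 1000, seed = 2)
#' keima_ratio(ev)
#' @export
keima_ratio <- function(events, mean_fun = c("arithmetic", "geometric")) {
  mean_fun <- match.arg(mean_fun)
  check_columns(events, c("acidic_561", "neutral_445", "condition"), "events")
  if (nrow(events) == 0L) abort("events table is empty")
  if (any(events$acidic_561 < 0 | events$neutral_445 < 0, na.rm = TRUE)) {
    abort("intensities must be nonnegative")
  }
  avg <- if (mean_fun == "arithmetic") {
    function(v) mean(v)
  } else {
    function(v) exp(mean(log(v)))
  }
  out <- events |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      mean_acidic = avg(.data$acidic_561),
      mean_neutral = avg(.data$neutral_445),
      n_events = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$mean_neutral == 0)) {
    abort(paste0(
      "zero mean neutral intensity for condition(s): ",
      paste(out$condition[out$mean_neutral == 0], collapse = ", ")
    ))
  }
  out |>
    dplyr::transmute(
      condition = .data$condition,
      raw_ratio = .data$mean_acidic / .data$mean_neutral,
      n_events = .data$n_events
    )
}

#' Normalize flux ratios to the matched BAFA control
#'
#' Divides each condition's raw acidic/neutral ratio by the raw ratio of
#' its bafilomycin-A1-treated control, so the BAFA sample itself is exactly
#' 1. Pairing is explicit: either a single BAFA condition for all samples
#' or a pairing table.
#'
#' @param ratios Tibble from [keima_ratio()].
#' @param bafa Name of the BAFA condition used for every sample, or a
#'   pairing data frame with columns `condition`, `bafa_condition`.
#' @return `ratios` with a `normalized_ratio` column.
#' @export
normalize_to_bafa <- function(ratios, bafa = "BAFA") {
  check_columns(ratios, c("condition", "raw_ratio"), "ratios")
  if (is.data.frame(bafa)) {
    check_columns(bafa, c("condition", "bafa_condition"), "pairings")
    pairing <- setNames(bafa$bafa_condition, bafa$condition)
    bafa_of <- unname(pairing[ratios$condition])
    missing_pair <- ratios$condition[is.na(bafa_of) &
                                       !ratios$condition %in% pairing]
    if (length(missing_pair) > 0L) {
      abort(paste0(
        "no BAFA pairing for condition(s): ",
        paste(missing_pair, collapse = ", ")
      ))
    }
  } else {
    bafa_of <- rep(bafa, nrow(ratios))
  }
  idx <- match(bafa_of, ratios$condition)
  if (anyNA(idx)) {
    abort(paste0(
      "matched BAFA condition(s) absent from the ratio table: ",
      paste(unique(bafa_of[is.na(idx)]), collapse = ", ")
    ))
  }
  denom <- ratios$raw_ratio[idx]
  if (any(denom <= 0)) abort("BAFA ratio must be > 0")
  ratios$normalized_ratio <- ratios$raw_ratio / denom
  ratios
}
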