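# Thin readers/writers for the delimited interchange formats. PSM tables,
# plex designs, protein matrices and annotations are TSV; flow event
# tables are CSV.

#' Read and write pipeline tables
#'
#' `read_psm_table()`/`read_plex_design()` expect tab-separated files;
#' `read_flow_events()` expects comma-separated files with columns
#' `event_id`, `acidic_561`, `neutral_445`, `condition`. A design passed to
#' `read_psm_table()` is attached as the `"design"` attribute so downstream
#' verbs pick it up automatically. `write_sim_data()` writes a simulated
#' experiment (truth, design, protein matrix, PSM table, annotations) as
#' plain-text tables into a directory.
#'
#' @param path File path.
#' @param design Optional plex design to attach.
#' @return A tibble (readers) or the directory path, invisibly (writer).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_psm_table <- function(path, design = NULL) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(out, c("protein_id", "summed_snr", "isolation_purity"),
                "PSM table")
  attr(out, "design") <- design
  out
}

#' @rdname pipeline_io
#' @export
read_plex_design <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(out, c("channel", "sample_id", "genotype", "replicate"),
                "plex design")
  if (anyDuplicated(out$channel)) abort("duplicate channel labels in design")
  out
}

#' @rdname pipeline_io
#' @export
read_flow_events <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(out, c("acidic_561", "neutral_445", "condition"),
                "flow events")
  out
}

#' @rdname pipeline_io
#' @param config A [sim_config()].
#' @param dir Output directory (created if absent).
#' @export
write_sim_data <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- generate_truth(config)
  design <- plex_design(config)
  pq <- simulate_protein_matrix(truth, config)
  psms <- simulate_psm_table(pq, config)
  ann <- sim_annotations(truth, seed = config$seed)
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(design, file.path(dir, "plex_design.tsv"))
  readr::write_tsv(pq, file.path(dir, "protein_matrix.tsv"))
  readr::write_tsv(psms, file.path(dir, "psm_table.tsv"))
  readr::write_tsv(ann, file.path(dir, "annotations.tsv"))
  invisible(dir)
}
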