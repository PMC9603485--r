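#' Sample metadata
#'
#' Metadata is a tibble with one row per sample: `sample_id`, `habitat`
#' (`soil` or `gut`), `treatment` (`HM` = high manure, `HML` = high manure
#' plus lime), the derived `group_label` (`HMs`, `HMe`, `HMLs`, `HMLe`), and
#' the environmental covariates pH, OM (g/kg), TN (g/kg), TP (g/kg),
#' TK (g/kg), and MC (%).
#'
#' @param sample_id character vector of sample ids.
#' @param habitat character, `soil` or `gut`, recycled to length.
#' @param treatment character, `HM` or `HML`, recycled to length.
#' @param env optional data frame of covariates (one row per sample).
#' @return a metadata tibble with `group_label` derived from
#'   habitat x treatment.
#' @export
sample_metadata <- function(sample_id, habitat, treatment, env = NULL) {
  meta <- tibble(
    sample_id = as.character(sample_id),
    habitat = rep_len(habitat, length(sample_id)),
    treatment = rep_len(treatment, length(sample_id))
  )
  meta$group_label <- group_label(meta$habitat, meta$treatment)
  if (!is.null(env)) meta <- dplyr::bind_cols(meta, as_tibble(env))
  validate_metadata(meta)
}

#' Derive the group label from habitat and treatment
#'
#' The label is a pure function of (habitat, treatment): soil samples get the
#' `s` suffix, gut samples the `e` suffix (for earthworm), appended to the
#' treatment code.
#'
#' @param habitat `soil` or `gut`.
#' @param treatment `HM` or `HML`.
#' @return character vector of group labels (`HMs`, `HMe`, `HMLs`, `HMLe`).
#' @export
group_label <- function(habitat, treatment) {
  paste0(treatment, ifelse(habitat == "soil", "s", "e"))
}

validate_metadata <- function(meta, context = "metadata") {
  meta <- as_tibble(meta)
  need <- c("sample_id", "habitat", "treatment")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    abort(sprintf("%s lacks columns: %s", context, paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) abort(sprintf("%s has duplicate sample ids", context))
  bad <- setdiff(unique(meta$habitat), c("soil", "gut"))
  if (length(bad)) abort(sprintf("%s: unknown habitat value(s): %s", context,
                                 paste(bad, collapse = ", ")))
  if (!"group_label" %in% names(meta)) {
    meta$group_label <- group_label(meta$habitat, meta$treatment)
  } else {
    expected <- group_label(meta$habitat, meta$treatment)
    if (any(meta$group_label != expected)) {
      abort(sprintf("%s: group_label is not consistent with habitat x treatment", context))
    }
  }
  meta
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample_id`, `habitat`, `treatment` and (optionally) the
#' covariates `pH`, `OM`, `TN`, `TP`, `TK`, `MC`. `group_label` is derived.
#'
#' @param path file path.
#' @return a metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_metadata(meta, context = path)
}

#' Write sample metadata to TSV
#'
#' @param meta a metadata tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  readr::write_tsv(validate_metadata(meta), path, progress = FALSE)
  invisible(path)
}

# Check that every sample column of `x` has exactly one metadata record.
match_metadata <- function(x, meta) {
  sids <- sample_ids(x)
  missing <- setdiff(sids, meta$sample_id)
  if (length(missing)) {
    abort(sprintf("metadata is missing sample(s): %s", paste(missing, collapse = ", ")))
  }
  meta[match(sids, meta$sample_id), , drop = FALSE]
}
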