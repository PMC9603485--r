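#' OTU count tables
#'
#' An OTU table is an ordinary wide tibble: one row per OTU with an `otu_id`
#' column, a `taxonomy` column holding the 7-rank semicolon-delimited lineage
#' (`kingdom;phylum;class;order;family;genus;species`, ranks may be empty),
#' and one non-negative integer count column per sample. All pipeline
#' functions take this tibble first, so calls chain with the pipe.
#'
#' @param counts integer matrix, rows = OTUs (rownames are OTU ids),
#'   columns = samples (colnames are sample ids).
#' @param taxonomy optional character vector of lineages, one per OTU;
#'   normalized to exactly 7 semicolon-separated ranks.
#' @return a tibble with columns `otu_id`, `taxonomy`, then one column per
#'   sample.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, dimnames = list(c("OTU1", "OTU2"), c("s1", "s2")))
#' otu_table(m, c("Bacteria;Proteobacteria", "Bacteria"))
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("OTU_%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  }
  taxonomy <- if (is.null(taxonomy)) {
    rep(normalize_lineage(""), nrow(counts))
  } else {
    normalize_lineage(taxonomy)
  }
  out <- tibble(
    otu_id = rownames(counts),
    taxonomy = taxonomy
  )
  out <- dplyr::bind_cols(out, as_tibble(counts, .name_repair = "minimal"))
  validate_otu_table(out)
}

#' Normalize a taxonomy lineage to exactly 7 ranks
#'
#' Pads short lineages with empty ranks and truncates overly long ones, so
#' every lineage has the form `kingdom;phylum;class;order;family;genus;species`.
#'
#' @param x character vector of semicolon-delimited lineages (`NA` allowed).
#' @return character vector of 7-field lineages.
#' @examples
#' normalize_lineage("Bacteria;Proteobacteria")
#' @export
normalize_lineage <- function(x) {
  x[is.na(x)] <- ""
  vapply(x, function(s) {
    parts <- stringr::str_split_1(s, ";")
    parts <- stringr::str_trim(parts)
    parts <- c(parts, rep("", 7L))[1:7]
    paste(parts, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

# Names of the sample (count) columns of an OTU table.
sample_ids <- function(x) setdiff(names(x), c("otu_id", "taxonomy"))

#' Extract the count matrix from an OTU table
#'
#' @param x an OTU table tibble (see [otu_table()]).
#' @return integer matrix, rows = OTUs, columns = samples.
#' @export
otu_counts <- function(x) {
  sids <- sample_ids(x)
  m <- as.matrix(x[, sids, drop = FALSE])
  rownames(m) <- x$otu_id
  storage.mode(m) <- "double"
  m
}

# Validate structure: unique ids, integer non-negative counts, 7-rank
# lineages. Returns the (possibly lineage-normalized) tibble invisibly cast
# to a plain tibble.
validate_otu_table <- function(x, context = "OTU table") {
  if (!is.data.frame(x) || !all(c("otu_id", "taxonomy") %in% names(x))) {
    abort(paste0(context, " must be a data frame with otu_id and taxonomy columns"))
  }
  x <- as_tibble(x)
  if (anyDuplicated(x$otu_id)) {
    dups <- unique(x$otu_id[duplicated(x$otu_id)])
    abort(sprintf("%s has duplicate OTU ids: %s", context,
                  paste(head(dups, 5), collapse = ", ")))
  }
  sids <- sample_ids(x)
  if (anyDuplicated(sids)) {
    abort(sprintf("%s has duplicate sample ids", context))
  }
  for (s in sids) {
    v <- x[[s]]
    if (!is.numeric(v)) {
      abort(sprintf("%s: sample column '%s' is not numeric", context, s))
    }
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      abort(sprintf(
        "%s: non-integer or negative count at row '%s', column '%s' (value %s)",
        context, x$otu_id[bad[1]], s, format(v[bad[1]])
      ))
    }
  }
  nrank <- stringr::str_count(x$taxonomy, ";")
  if (any(nrank != 6L)) x$taxonomy <- normalize_lineage(x$taxonomy)
  x
}

#' Read an OTU table from TSV
#'
#' Expects a tab-separated file whose header row holds sample ids, whose
#' first column is the OTU id (conventionally named `#OTU_ID`), and whose
#' optional final column `taxonomy` carries semicolon-delimited lineages.
#' Missing taxonomy yields 7 empty ranks.
#'
#' @param path file path.
#' @return an OTU table tibble.
#' @export
read_otu_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("OTU table must have at least one sample column")
  names(raw)[1] <- "otu_id"
  has_tax <- tolower(names(raw)[ncol(raw)]) == "taxonomy"
  tax <- if (has_tax) raw[[ncol(raw)]] else rep("", nrow(raw))
  counts <- raw[, setdiff(seq_along(raw), c(1L, if (has_tax) ncol(raw))), drop = FALSE]
  for (s in names(counts)) {
    v <- suppressWarnings(as.numeric(counts[[s]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      abort(sprintf(
        "parse error in '%s': non-integer or negative count at row '%s', column '%s' (value '%s')",
        path, raw$otu_id[bad[1]], s, counts[[s]][bad[1]]
      ))
    }
    counts[[s]] <- v
  }
  out <- dplyr::bind_cols(
    tibble(otu_id = raw$otu_id, taxonomy = normalize_lineage(tax)),
    counts
  )
  validate_otu_table(out, context = path)
}

#' Write an OTU table to TSV
#'
#' Inverse of [read_otu_table()]: first column `#OTU_ID`, one column per
#' sample, final column `taxonomy`. UTF-8, tab-separated, no quoting.
#'
#' @param x an OTU table tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  x <- validate_otu_table(x)
  sids <- sample_ids(x)
  out <- x[, c("otu_id", sids, "taxonomy")]
  names(out)[1] <- "#OTU_ID"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
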