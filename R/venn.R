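#' Shared and unique OTU partition between two sample groups
#'
#' An OTU belongs to a group when its summed count over that group's samples
#' is positive (presence in any replicate). The shared set, the two unique
#' sets, and the union are an exact partition; the shared percentage is
#' `100 * |shared| / |union|`, reported rounded half-up to one decimal while
#' full precision is retained internally.
#'
#' @param x an OTU table tibble.
#' @param meta metadata tibble.
#' @param group_a,group_b group labels to compare.
#' @param group_col metadata column holding the labels (default
#'   `group_label`).
#' @return an object of class `venn_partition` with elements `shared`,
#'   `unique_a`, `unique_b` (character vectors of OTU ids), `union_size`,
#'   `shared_pct` (full precision) and `shared_pct_reported`.
#' @export
venn_partition <- function(x, meta, group_a, group_b, group_col = "group_label") {
  x <- validate_otu_table(x)
  meta <- match_metadata(x, meta)
  known <- unique(meta[[group_col]])
  for (g in c(group_a, group_b)) {
    if (!g %in% known) {
      abort(sprintf("unknown group label '%s' (known: %s)", g,
                    paste(known, collapse = ", ")))
    }
  }
  m <- otu_counts(x)
  members <- function(g) {
    cols <- meta$sample_id[meta[[group_col]] == g]
    rownames(m)[rowSums(m[, cols, drop = FALSE]) > 0]
  }
  a <- members(group_a)
  b <- members(group_b)
  shared <- intersect(a, b)
  un <- union(a, b)
  pct <- if (length(un)) 100 * length(shared) / length(un) else 0
  structure(
    list(
      group_a = group_a, group_b = group_b,
      shared = shared,
      unique_a = setdiff(a, b),
      unique_b = setdiff(b, a),
      union_size = length(un),
      shared_pct = pct,
      shared_pct_reported = round_half_up(pct, 1)
    ),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf(
    "Venn partition %s vs %s: %d shared / %d union (%.1f%%); unique: %d vs %d\n",
    x$group_a, x$group_b, length(x$shared), x$union_size,
    x$shared_pct_reported, length(x$unique_a), length(x$unique_b)
  ))
  invisible(x)
}

#' @rdname venn_partition
#' @param x a `venn_partition` object.
#' @param ... unused.
#' @export
tidy.venn_partition <- function(x, ...) {
  tibble(
    group_a = x$group_a, group_b = x$group_b,
    n_shared = length(x$shared),
    n_unique_a = length(x$unique_a),
    n_unique_b = length(x$unique_b),
    union_size = x$union_size,
    shared_pct = x$shared_pct_reported
  )
}
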