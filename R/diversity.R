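#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample column without replacement (multivariate
#' hypergeometric draw, via [vegan::rrarefy()]) so that every column sums
#' exactly to `depth`. The seed is a required argument: the same seed always
#' yields the identical table.
#'
#' @param x an OTU table tibble.
#' @param depth target depth; defaults to the minimum per-sample total.
#' @param seed integer seed for the subsampling.
#' @return a rarefied OTU table tibble (same OTU rows, possibly with zeros).
#' @export
rarefy <- function(x, depth = NULL, seed) {
  if (missing(seed)) abort("rarefy() requires an explicit seed")
  x <- validate_otu_table(x)
  m <- otu_counts(x)
  totals <- colSums(m)
  depth <- depth %||% min(totals)
  low <- names(totals)[totals < depth]
  if (length(low)) {
    abort(sprintf(
      "rarefaction depth %d exceeds the total of sample(s): %s",
      depth, paste(sprintf("%s (%d)", low, totals[low]), collapse = ", ")
    ))
  }
  rar <- withr::with_seed(as.integer(seed), {
    # vegan heuristically warns when all counts are large; that is the
    # normal case for deep libraries, so muffle just that message
    withCallingHandlers(
      t(vegan::rrarefy(t(m), sample = depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  })
  out <- x
  out[, sample_ids(x)] <- as_tibble(rar, .name_repair = "minimal")
  out
}

#' Chao1 richness estimator
#'
#' Classic Chao1: `S_obs + F1^2 / (2 F2)` where `F1`/`F2` are the singleton
#' and doubleton counts, with the bias-corrected fallback
#' `S_obs + F1 (F1 - 1) / 2` only when `F2 = 0`. Equals `S_obs` exactly when
#' there are no singletons.
#'
#' @param counts non-negative integer vector of per-OTU counts for one sample.
#' @return the Chao1 estimate (scalar).
#' @examples
#' chao1(c(1, 1, 2, 3)) # 4 + 2^2/(2*1) = 6
#' @export
chao1 <- function(counts) {
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Alpha diversity indices per sample
#'
#' Computes, for every sample column: observed richness `S_obs`, Shannon
#' entropy `H = -sum p_i ln p_i` (nats), classic Chao1, and Pielou evenness
#' `J = H / ln S_obs` (missing when `S_obs <= 1`). The caller is expected to
#' have rarefied the table to even depth; a warning is emitted when column
#' sums are unequal.
#'
#' @param x an OTU table tibble.
#' @return a tibble with columns `sample_id`, `richness`, `shannon`, `chao1`,
#'   `evenness`.
#' @export
alpha_diversity <- function(x) {
  x <- validate_otu_table(x)
  m <- otu_counts(x)
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(sprintf("all-zero sample(s): %s",
                  paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  if (length(unique(totals)) > 1) {
    warn("samples have unequal totals; consider rarefy() before alpha_diversity()")
  }
  purrr::map_dfr(colnames(m), function(s) {
    v <- m[, s]
    s_obs <- sum(v > 0)
    h <- unname(vegan::diversity(v, index = "shannon"))
    tibble(
      sample_id = s,
      richness = s_obs,
      shannon = h,
      chao1 = chao1(v),
      evenness = if (s_obs > 1) h / log(s_obs) else NA_real_
    )
  })
}

#' Per-group sequencing depth summary
#'
#' Tallies total and mean reads per sample group, the arithmetic reported in
#' sequencing summaries (e.g. total reads over 12 soil samples and the
#' per-sample average).
#'
#' @param x an OTU table tibble.
#' @param meta metadata tibble.
#' @param by metadata column to group by (default `habitat`).
#' @return tibble with `group`, `n_samples`, `total_reads`, `mean_reads`.
#' @export
depth_summary <- function(x, meta, by = "habitat") {
  x <- validate_otu_table(x)
  meta <- match_metadata(x, meta)
  totals <- colSums(otu_counts(x))
  tibble(group = meta[[by]], reads = unname(totals)) %>%
    group_by(.data$group) %>%
    summarise(
      n_samples = dplyr::n(),
      total_reads = sum(.data$reads),
      mean_reads = mean(.data$reads),
      .groups = "drop"
    )
}
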