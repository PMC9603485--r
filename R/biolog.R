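#' Biolog plate readings
#'
#' A plate is a long tibble with one row per sample, well, and reading time:
#' `sample_id`, `well_id`, `carbon_source`, `category`, `is_control`
#' (logical; exactly one control well -- the no-carbon water blank -- per
#' sample), `time_h` (hours on a shared grid), `od590` (blank-uncorrected
#' absorbance).
#'
#' @param path CSV file with the columns above.
#' @return a validated plate tibble.
#' @export
read_biolog <- function(path) {
  plate <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_biolog(plate, context = path)
}

#' Write Biolog plate readings as CSV
#'
#' @param plate a plate tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_biolog <- function(plate, path) {
  readr::write_csv(validate_biolog(plate), path, progress = FALSE)
  invisible(path)
}

validate_biolog <- function(plate, context = "Biolog plate") {
  need <- c("sample_id", "well_id", "carbon_source", "category", "is_control",
            "time_h", "od590")
  missing <- setdiff(need, names(plate))
  if (length(missing)) {
    abort(sprintf("%s lacks columns: %s", context, paste(missing, collapse = ", ")))
  }
  plate <- as_tibble(plate)
  plate$is_control <- as.logical(plate$is_control)
  ctrl <- plate %>%
    distinct(.data$sample_id, .data$well_id, .data$is_control) %>%
    filter(.data$is_control) %>%
    count(.data$sample_id)
  bad <- unique(c(
    setdiff(unique(plate$sample_id), ctrl$sample_id),
    ctrl$sample_id[ctrl$n != 1]
  ))
  if (length(bad)) {
    abort(sprintf("%s: sample(s) without exactly one control well: %s",
                  context, paste(bad, collapse = ", ")))
  }
  grids <- plate %>%
    group_by(.data$sample_id, .data$well_id) %>%
    summarise(grid = paste(sort(.data$time_h), collapse = ","), .groups = "drop")
  if (length(unique(grids$grid)) != 1) {
    abort(sprintf("%s: wells do not share a common time grid", context))
  }
  plate
}

#' The default carbon-source catalog
#'
#' The 71-substrate plate layout used by the synthetic generator, mapping
#' each well to a carbon source and one of the reported categories (amino
#' acids, monosaccharides, carboxylic acids, esters, fatty acids, hexonic
#' acid, hexosephosphate, other) plus the water control well. The mapping is
#' a synthetic, editable default -- the plate vendor's exact category
#' assignment is not bundled -- and lives in
#' `inst/extdata/carbon_source_catalog_synthetic.csv`.
#'
#' @return tibble with `well_id`, `carbon_source`, `category`, `is_control`.
#' @export
biolog_catalog <- function() {
  path <- system.file("extdata", "carbon_source_catalog_synthetic.csv",
                      package = "wormnet", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Average well color development at one time point
#'
#' `AWCD(t) = (1/n_substrate) sum_i max(OD_i(t) - OD_control(t), 0)`:
#' the mean blank-corrected absorbance over substrate wells, with negative
#' blank-corrected values clamped to zero before averaging. Per-category
#' AWCD averages only that category's wells, so the category values,
#' weighted by their well counts, average exactly to the overall AWCD.
#'
#' @param plate a plate tibble.
#' @param t a time point present on the grid.
#' @return tibble with `sample_id`, `time_h`, `category` (`overall` plus
#'   each category present), `awcd`, `n_wells`.
#' @export
awcd <- function(plate, t) {
  plate <- validate_biolog(plate)
  at_t <- filter(plate, .data$time_h == t)
  if (nrow(at_t) == 0) abort(sprintf("time point %s is not on the grid", format(t)))
  ctrl <- filter(at_t, .data$is_control)
  miss <- setdiff(unique(at_t$sample_id), ctrl$sample_id)
  if (length(miss)) {
    abort(sprintf("missing control reading at t = %s for sample(s): %s",
                  format(t), paste(miss, collapse = ", ")))
  }
  sub <- at_t %>%
    filter(!.data$is_control) %>%
    left_join(select(ctrl, "sample_id", control_od = "od590"), by = "sample_id") %>%
    mutate(dev = pmax(.data$od590 - .data$control_od, 0))
  overall <- sub %>%
    group_by(.data$sample_id) %>%
    summarise(category = "overall", awcd = mean(.data$dev),
              n_wells = dplyr::n(), .groups = "drop")
  per_cat <- sub %>%
    group_by(.data$sample_id, .data$category) %>%
    summarise(awcd = mean(.data$dev), n_wells = dplyr::n(), .groups = "drop")
  bind_rows(overall, per_cat) %>%
    mutate(time_h = t) %>%
    select("sample_id", "time_h", "category", "awcd", "n_wells") %>%
    arrange(.data$sample_id, .data$category)
}

#' AWCD over the full incubation
#'
#' Evaluates [awcd()] at every time point on the grid and extracts the
#' reference-time scalar per sample (the single AWCD value a study reports).
#'
#' @param plate a plate tibble with at least 2 time points.
#' @param reference_time time point for the reported scalar; defaults to the
#'   final time point.
#' @return an object of class `awcd_result`: list with `curve` (long
#'   tibble), `reference` (tibble `sample_id`, `awcd`), `reference_time`.
#' @export
awcd_curve <- function(plate, reference_time = NULL) {
  plate <- validate_biolog(plate)
  times <- sort(unique(plate$time_h))
  if (length(times) < 2) abort("awcd_curve() needs at least 2 time points")
  reference_time <- reference_time %||% max(times)
  if (!reference_time %in% times) {
    abort(sprintf("reference time %s is not on the grid", format(reference_time)))
  }
  curve <- purrr::map_dfr(times, function(t) awcd(plate, t))
  reference <- curve %>%
    filter(.data$time_h == reference_time, .data$category == "overall") %>%
    select("sample_id", "awcd")
  structure(
    list(curve = curve, reference = reference, reference_time = reference_time),
    class = "awcd_result"
  )
}

#' @export
print.awcd_result <- function(x, ...) {
  cat(sprintf("awcd_result: %d samples, reference time %s h\n",
              nrow(x$reference), format(x$reference_time)))
  print(x$reference)
  invisible(x)
}

#' @rdname awcd_curve
#' @param x an `awcd_result` object.
#' @param ... unused.
#' @export
tidy.awcd_result <- function(x, ...) x$curve

#' @rdname awcd_curve
#' @export
glance.awcd_result <- function(x, ...) {
  tibble(n_samples = nrow(x$reference),
         reference_time = x$reference_time,
         mean_awcd = mean(x$reference$awcd))
}
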