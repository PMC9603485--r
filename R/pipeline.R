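#' Pipeline run configuration
#'
#' Collects inputs and thresholds for [run_all()]. Inputs may be file paths
#' (read with the package readers) or in-memory tibbles.
#'
#' @param otu_table OTU table tibble or TSV path.
#' @param metadata metadata tibble or TSV path.
#' @param biolog optional plate tibble or CSV path.
#' @param group_col metadata column defining the network groups
#'   (default `group_label`); one network is built per group, plus a pooled
#'   network over all samples when `pooled = TRUE`.
#' @param pooled also build a pooled all-sample network (default TRUE).
#' @param rarefaction_depth depth for [rarefy()]; default the minimum sample
#'   total.
#' @param prevalence_fraction prevalence filter fraction (default 2/3).
#' @param r_threshold,q_threshold network thresholds (defaults 0.8, 0.01).
#' @param z_threshold,p_threshold keystone role thresholds
#'   (defaults 2.5, 0.62).
#' @param n_null null removals for the stability test (default 199).
#' @param reference_time Biolog reference time (default last time point).
#' @param venn_pairs list of 2-vectors of group labels to compare
#'   (default the soil/gut pair within each treatment).
#' @param seed master seed (default 1).
#' @param output_dir optional directory for artifacts.
#' @return a list of class `run_config`.
#' @export
run_config <- function(otu_table, metadata, biolog = NULL,
                       group_col = "group_label", pooled = TRUE,
                       rarefaction_depth = NULL,
                       prevalence_fraction = 2 / 3,
                       r_threshold = 0.8, q_threshold = 0.01,
                       z_threshold = 2.5, p_threshold = 0.62,
                       n_null = 199L,
                       reference_time = NULL,
                       venn_pairs = list(c("HMs", "HMe"), c("HMLs", "HMLe")),
                       seed = 1L, output_dir = NULL) {
  if (prevalence_fraction <= 0 || prevalence_fraction > 1) {
    abort("prevalence_fraction must be in (0, 1]")
  }
  if (r_threshold < 0 || r_threshold > 1) abort("r_threshold must be in [0, 1]")
  if (q_threshold <= 0 || q_threshold > 1) abort("q_threshold must be in (0, 1]")
  if (n_null < 99) abort("n_null must be at least 99")
  for (p in list(otu_table, metadata, biolog)) {
    if (is.character(p) && !file.exists(p)) {
      abort(sprintf("input path does not exist: %s", p))
    }
  }
  structure(as.list(environment())[
    c("otu_table", "metadata", "biolog", "group_col", "pooled",
      "rarefaction_depth", "prevalence_fraction", "r_threshold",
      "q_threshold", "z_threshold", "p_threshold", "n_null",
      "reference_time", "venn_pairs", "seed", "output_dir")
  ], class = "run_config")
}

resolve_inputs <- function(config) {
  tab <- config$otu_table
  if (is.character(tab)) tab <- read_otu_table(tab)
  meta <- config$metadata
  if (is.character(meta)) meta <- read_sample_metadata(meta)
  plate <- config$biolog
  if (is.character(plate)) plate <- read_biolog(plate)
  list(table = validate_otu_table(tab), meta = validate_metadata(meta),
       biolog = plate)
}

#' Validate a pipeline input bundle
#'
#' Checks table/metadata sample-id agreement, count integrality, group
#' sizes, and Biolog control-well presence, distinguishing warnings from
#' errors. Nothing is computed.
#'
#' @param config a [run_config()].
#' @return tibble with columns `level` (`error`/`warning`) and `message`;
#'   zero rows for a fully consistent bundle.
#' @export
validate_inputs <- function(config) {
  issues <- tibble(level = character(), message = character())
  add <- function(level, msg) {
    issues <<- bind_rows(issues, tibble(level = level, message = msg))
  }
  inp <- tryCatch(resolve_inputs(config), error = function(e) {
    add("error", conditionMessage(e))
    NULL
  })
  if (is.null(inp)) return(issues)
  sids <- sample_ids(inp$table)
  missing <- setdiff(sids, inp$meta$sample_id)
  if (length(missing)) {
    add("error", sprintf("metadata is missing sample(s): %s",
                         paste(missing, collapse = ", ")))
  }
  unused <- setdiff(inp$meta$sample_id, sids)
  if (length(unused)) {
    add("warning", sprintf("metadata sample(s) absent from the table: %s",
                           paste(unused, collapse = ", ")))
  }
  in_tab <- inp$meta[inp$meta$sample_id %in% sids, ]
  sizes <- dplyr::count(in_tab, .data[[config$group_col]])
  singles <- sizes[[config$group_col]][sizes$n < 2]
  if (length(singles)) {
    add("warning", sprintf(
      "group(s) with a single sample (diversity ok, Tukey disabled): %s",
      paste(singles, collapse = ", ")))
  }
  if (!is.null(inp$biolog)) {
    res <- tryCatch({validate_biolog(inp$biolog); NULL},
                    error = function(e) conditionMessage(e))
    if (!is.null(res)) add("error", res)
    miss_b <- setdiff(sids, unique(inp$biolog$sample_id))
    if (length(miss_b)) {
      add("warning", sprintf("no Biolog plate for sample(s): %s",
                             paste(miss_b, collapse = ", ")))
    }
  }
  issues
}

#' Run the full keystone-taxa pipeline
#'
#' Executes the stages in order -- rarefaction, alpha diversity with group
#' comparison, shared/unique OTU partitions, per-group (and pooled)
#' co-occurrence networks with module detection and Zi-Pi roles, the
#' keystone report, the keystone-removal stability test, AWCD scoring, and
#' keystone-environment correlation -- and assembles a machine-readable
#' report holding every statistic, threshold, and seed. All randomness
#' derives from the single config seed via per-stage child seeds, so the
#' run (and each stage) is reproducible; rerunning the same config yields
#' an identical report.
#'
#' @param config a [run_config()].
#' @return an object of class `wormnet_run`: list with `report` (plain
#'   nested list, JSON-ready) and the intermediate objects (`diversity`,
#'   `networks`, `topologies`, `keystones`, `stability`, `awcd`,
#'   `env_correlation`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- resolve_inputs(config)
  issues <- validate_inputs(config)
  if (any(issues$level == "error")) {
    abort(paste0("invalid inputs:\n",
                 paste(issues$message[issues$level == "error"], collapse = "\n")))
  }
  table <- inp$table
  meta <- match_metadata(table, inp$meta)

  depth_tab <- depth_summary(table, meta, by = "habitat")
  rare <- rarefy(table, depth = config$rarefaction_depth,
                 seed = derive_seed(config$seed, "rarefy"))
  div <- alpha_diversity(rare)
  div <- left_join(div, select(meta, "sample_id", "habitat", "treatment",
                               "group_label"), by = "sample_id")
  can_tukey <- all(dplyr::count(meta, .data$group_label)$n >= 2)
  div_tests <- if (can_tukey) {
    lapply(setNames(nm = c("shannon", "chao1", "richness", "evenness")),
           function(v) {
             d <- div[!is.na(div[[v]]), ]
             group_compare(d, !!sym(v), group_label)
           })
  } else NULL

  venns <- purrr::map(config$venn_pairs, function(pr) {
    venn_partition(table, meta, pr[1], pr[2], group_col = config$group_col)
  })

  group_levels <- unique(meta[[config$group_col]])
  nets <- list()
  for (g in group_levels) {
    cols <- meta$sample_id[meta[[config$group_col]] == g]
    sub <- table[, c("otu_id", "taxonomy", cols)]
    filt <- suppressWarnings(prevalence_filter(sub, config$prevalence_fraction))
    nets[[g]] <- build_network(filt, config$r_threshold, config$q_threshold)
  }
  if (isTRUE(config$pooled)) {
    filt <- suppressWarnings(prevalence_filter(table, config$prevalence_fraction))
    nets[["pooled"]] <- build_network(filt, config$r_threshold, config$q_threshold)
  }

  partitions <- purrr::map(nets, detect_modules)
  topologies <- purrr::map2(nets, partitions, function(nw, pt) {
    zi_pi(nw, pt, config$z_threshold, config$p_threshold)
  })

  group_topos <- topologies[setdiff(names(topologies), "pooled")]
  keystones <- keystone_report(group_topos, table, meta,
                               group_col = config$group_col)

  stability <- purrr::imap(nets, function(nw, g) {
    keys <- topologies[[g]]$otu_id[is_keystone(topologies[[g]]$role)]
    if (length(keys) >= nrow(nw$nodes)) keys <- head(keys, nrow(nw$nodes) - 1)
    removal_stability(nw, keys, n_null = config$n_null,
                      seed = derive_seed(config$seed, paste0("removal_", g)))
  })

  awcd_res <- NULL
  if (!is.null(inp$biolog)) {
    awcd_res <- awcd_curve(inp$biolog, reference_time = config$reference_time)
  }

  env_cor <- keystone_env_correlation(keystones, meta, awcd = awcd_res)

  report <- list(
    params = list(
      seed = config$seed,
      rarefaction_depth = config$rarefaction_depth %||% min(colSums(otu_counts(table))),
      prevalence_fraction = config$prevalence_fraction,
      r_threshold = config$r_threshold, q_threshold = config$q_threshold,
      z_threshold = config$z_threshold, p_threshold = config$p_threshold,
      n_null = config$n_null, group_col = config$group_col,
      networks = c(group_levels, if (isTRUE(config$pooled)) "pooled"),
      package_version = as.character(utils::packageVersion("wormnet"))
    ),
    depth_summary = depth_tab,
    diversity = list(
      per_sample = div,
      tukey = if (can_tukey) {
        purrr::map(div_tests, function(gc) {
          list(anova = gc$glance, letters = gc$letters)
        })
      }
    ),
    venn = purrr::map(venns, tidy),
    networks = purrr::imap(nets, function(nw, g) {
      list(
        group = g,
        n_nodes = nrow(nw$nodes), n_isolated = sum(nw$nodes$isolated),
        n_edges = nrow(nw$edges),
        n_positive = sum(nw$edges$sign == "+"),
        n_negative = sum(nw$edges$sign == "-"),
        modularity = partitions[[g]]$modularity,
        n_modules = partitions[[g]]$n_modules,
        n_keystone = sum(is_keystone(topologies[[g]]$role))
      )
    }),
    keystones = list(
      taxa = keystones$taxa,
      shared = keystones$shared,
      per_network = keystones$counts,
      pooled_n = keystones$pooled_n
    ),
    stability = purrr::map(stability, glance),
    env_correlation = env_cor,
    awcd = if (!is.null(awcd_res)) {
      left_join(awcd_res$reference,
                select(meta, "sample_id", "group_label"), by = "sample_id")
    }
  )

  run <- structure(
    list(report = report, table = rare, diversity = div, venns = venns,
         networks = nets, partitions = partitions, topologies = topologies,
         keystones = keystones, stability = stability, awcd = awcd_res,
         env_correlation = env_cor),
    class = "wormnet_run"
  )
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

#' @export
print.wormnet_run <- function(x, ...) {
  cat("wormnet_run\n")
  cat(sprintf("  networks: %s\n", paste(names(x$networks), collapse = ", ")))
  cat(sprintf("  pooled keystone taxa: %d (shared: %d)\n",
              x$keystones$pooled_n, length(x$keystones$shared)))
  invisible(x)
}

# Write the artifacts of a finished run.
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(run$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_tsv(run$diversity, file.path(dir, "diversity.tsv"), progress = FALSE)
  if (nrow(run$keystones$taxa)) {
    readr::write_tsv(run$keystones$taxa, file.path(dir, "keystone_taxa.tsv"),
                     progress = FALSE)
  }
  for (g in names(run$networks)) {
    write_edge_list(run$networks[[g]], file.path(dir, sprintf("edges_%s.csv", g)))
    write_graphml(run$networks[[g]], file.path(dir, sprintf("network_%s.graphml", g)),
                  topology = run$topologies[[g]])
    write_removal_json(run$stability[[g]],
                       file.path(dir, sprintf("stability_%s.json", g)))
  }
  readr::write_csv(run$env_correlation, file.path(dir, "env_correlation.csv"),
                   progress = FALSE)
  if (!is.null(run$awcd)) {
    readr::write_csv(run$awcd$curve, file.path(dir, "awcd_curve.csv"),
                     progress = FALSE)
  }
  invisible(dir)
}
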