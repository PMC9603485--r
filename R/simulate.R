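#' Simulation configuration
#'
#' Bundles every knob of the synthetic community and Biolog generators with
#' the study-design defaults: a 2 treatment x 2 habitat x 6 replicate design
#' (24 samples in groups HMs, HMe, HMLs, HMLe), 300 taxa of which 4 planted
#' modules of 20 member taxa plus 2 hub taxa each carry correlation
#' structure, a gut diversity deficit, a shared core, environmental
#' covariates coupled to the community factor (pH negatively, OM
#' positively), per-habitat sequencing depths echoing typical soil/gut
#' libraries, and per-group Biolog asymptotes.
#'
#' The correlation structure is planted in the *realized* sample paths:
#' factor scores are orthonormalized within each habitat block, so planted
#' correlations hold exactly in the sample and survive the hard edge
#' thresholds of the network stage. Hub taxa load on their own module factor
#' and, with fraction `hub_cross_loading`, across all other module factors,
#' which makes them emerge as high-participation connector nodes.
#'
#' @param n_per_group samples per group label (default 6; 24 total).
#' @param n_taxa total taxa (default 300).
#' @param n_modules planted modules (default 4; 0 gives a fully independent
#'   community).
#' @param taxa_per_module member taxa per module (default 20).
#' @param n_hubs hub taxa per module (default 2).
#' @param hub_cross_loading fraction of a hub's factor loading spread over
#'   the other modules (default 2/3).
#' @param member_loading correlation of a member taxon with its module
#'   factor (default 0.95).
#' @param factor_cor correlation between module factors through the shared
#'   community component (default 0.82).
#' @param hub_noise residual fraction of hub latents (default 0.1).
#' @param latent_scale log-abundance scale of the planted latents
#'   (default 1.2).
#' @param signal_weight relative weight of signal taxa in the community
#'   (default 0.33; keeps the planted block a minor share of total
#'   abundance so compositional closure does not distort it).
#' @param background_sd log-normal spread of background taxa (default 1.2).
#' @param shared_core_fraction fraction of taxa present in both habitats
#'   (default 0.3; always includes the planted taxa).
#' @param gut_diversity_deficit fraction of non-core background taxa
#'   retained in the gut pool (default 0.6; 1 = no deficit).
#' @param depth_mean named per-habitat mean sequencing depth
#'   (default soil 24200, gut 40200).
#' @param depth_cv coefficient of variation of per-sample depths
#'   (default 0.15).
#' @param nb_size negative-binomial size (inverse overdispersion,
#'   default 100).
#' @param env_profile tibble of per-group covariate means and their SD; see
#'   default.
#' @param env_coupling named effect sizes (correlation with the community
#'   factor) for coupled covariates; default `c(pH = -0.65, OM = 0.65)`.
#' @param biolog_asymptote named per-group AWCD plateau means
#'   (default HMs 0.71, HMe 0.51, HMLs 0.72, HMLe 0.38).
#' @param biolog_rate logistic growth rate per hour (default 0.1).
#' @param biolog_midpoint logistic midpoint in hours (default 48).
#' @param biolog_baseline blank optical density (default 0.05).
#' @param biolog_noise_sd multiplicative well effect and additive reading
#'   noise scale (default 0.02; 0 gives noiseless plates).
#' @param biolog_times reading time grid in hours (default every 12 h to
#'   120 h).
#' @param seed integer master seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 6L,
                       n_taxa = 300L,
                       n_modules = 4L,
                       taxa_per_module = 20L,
                       n_hubs = 2L,
                       hub_cross_loading = 2 / 3,
                       member_loading = 0.95,
                       factor_cor = 0.82,
                       hub_noise = 0.1,
                       latent_scale = 1.2,
                       signal_weight = 0.33,
                       background_sd = 1.2,
                       shared_core_fraction = 0.3,
                       gut_diversity_deficit = 0.6,
                       depth_mean = c(soil = 24200, gut = 40200),
                       depth_cv = 0.15,
                       nb_size = 100,
                       env_profile = default_env_profile(),
                       env_coupling = c(pH = -0.65, OM = 0.65),
                       biolog_asymptote = c(HMs = 0.71, HMe = 0.51,
                                            HMLs = 0.72, HMLe = 0.38),
                       biolog_rate = 0.1,
                       biolog_midpoint = 48,
                       biolog_baseline = 0.05,
                       biolog_noise_sd = 0.02,
                       biolog_times = seq(0, 120, by = 12),
                       seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(hub_cross_loading = hub_cross_loading,
             member_loading = member_loading, factor_cor = factor_cor,
             hub_noise = hub_noise, shared_core_fraction = shared_core_fraction,
             gut_diversity_deficit = gut_diversity_deficit)
  bad <- names(fracs)[fracs < 0 | fracs > 1]
  if (length(bad)) abort(sprintf("fraction(s) outside [0, 1]: %s",
                                 paste(bad, collapse = ", ")))
  if (n_per_group < 1 || n_taxa < 1) abort("counts must be positive")
  n_signal <- n_modules * (taxa_per_module + n_hubs)
  if (n_signal > n_taxa) {
    abort("taxa_per_module (plus hubs) x n_modules exceeds n_taxa")
  }
  if (length(env_coupling) && max(abs(env_coupling)) > 1) {
    abort("env_coupling entries must be in [-1, 1]")
  }
  cfg$n_signal <- n_signal
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_env_profile <- function() {
  tibble(
    covariate = c("pH", "OM", "TN", "TP", "TK", "MC"),
    HMs = c(5.6, 18, 1.6, 0.9, 12, 22),
    HMe = c(6.6, 28, 2.4, 1.2, 13, 30),
    HMLs = c(6.8, 17, 1.5, 0.9, 12, 23),
    HMLe = c(7.1, 26, 2.3, 1.1, 13, 31),
    sd = c(0.15, 2, 0.15, 0.08, 0.8, 2)
  )
}

# Orthonormalized factor scores within a sample block: centered columns,
# unit sample variance, exactly zero pairwise correlation. Falls back to
# plain standardized normals when the block is too small to orthogonalize.
ortho_block <- function(nb, k) {
  if (nb < k + 2) {
    z <- matrix(rnorm(nb * k), nb)
    return(apply(z, 2, function(v) (v - mean(v)) / sd(v)))
  }
  z <- matrix(rnorm(nb * (k + 1)), nb)
  z <- sweep(z, 2, colMeans(z))
  q <- qr.Q(qr(z))[, seq_len(k), drop = FALSE]
  for (i in 1:2) {
    q <- sweep(q, 2, colMeans(q))
    q <- qr.Q(qr(q))
  }
  q * sqrt(nb - 1)
}

# Residual vector orthogonal to the factor block (and the intercept),
# scaled to unit sample variance, computed per block.
ortho_resid <- function(blocks, fac) {
  n <- sum(lengths(blocks))
  e <- rnorm(n)
  for (blk in blocks) {
    fb <- cbind(1, fac[blk, , drop = FALSE])
    eb <- e[blk]
    eb <- eb - fb %*% solve(crossprod(fb), crossprod(fb, eb))
    e[blk] <- eb / sd(eb)
  }
  e
}

#' Generate a synthetic community with planted ground truth
#'
#' Draws the OTU table, sample metadata, and the truth record (planted
#' module assignment, hub ids, environmental effect sizes, per-group
#' metabolic levels) for the configured design. Counts are negative-binomial
#' around per-sample depths; gut samples draw their background taxa from a
#' richness-thinned pool; the planted taxa form the shared core present in
#' both habitats.
#'
#' @param config a [sim_config()].
#' @return list with elements `table` (OTU table tibble), `metadata`
#'   (metadata tibble), `truth` (list: `modules` tibble of `otu_id`,
#'   `module`; `hubs` tibble of `otu_id`, `module`; `core_ids`;
#'   `env_coupling`; `group_metabolism`).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(derive_seed(cfg$seed, "community"), {
    groups <- c("HMs", "HMe", "HMLs", "HMLe")
    habitats <- c(HMs = "soil", HMe = "gut", HMLs = "soil", HMLe = "gut")
    treatments <- c(HMs = "HM", HMe = "HM", HMLs = "HML", HMLe = "HML")
    meta <- purrr::map_dfr(groups, function(g) {
      tibble(
        sample_id = sprintf("%s_%d", g, seq_len(cfg$n_per_group)),
        habitat = habitats[[g]],
        treatment = treatments[[g]],
        group_label = g
      )
    })
    n <- nrow(meta)
    blocks <- list(soil = which(meta$habitat == "soil"),
                   gut = which(meta$habitat == "gut"))

    M <- cfg$n_modules
    nfac <- 1L + M
    fac <- matrix(0, n, nfac)
    for (blk in blocks) fac[blk, ] <- ortho_block(length(blk), nfac)
    G <- fac[, 1]
    b <- cfg$factor_cor
    f <- if (M > 0) {
      sqrt(b) * G + sqrt(1 - b) * fac[, -1, drop = FALSE]
    } else {
      matrix(0, n, 0)
    }

    per <- cfg$taxa_per_module
    n_members <- M * per
    n_hub <- M * cfg$n_hubs
    n_signal <- n_members + n_hub
    n_bg <- cfg$n_taxa - n_signal

    X <- matrix(0, n, n_signal)
    member_module <- rep(seq_len(max(M, 1L)), each = per)[seq_len(n_members)]
    a <- cfg$member_loading
    for (i in seq_len(n_members)) {
      X[, i] <- a * f[, member_module[i]] + sqrt(1 - a^2) * ortho_resid(blocks, fac)
    }
    hub_module <- integer(0)
    if (M > 0 && cfg$n_hubs > 0) {
      w <- cfg$hub_cross_loading
      for (m in seq_len(M)) for (h in seq_len(cfg$n_hubs)) {
        oth <- setdiff(seq_len(M), m)
        raw <- sqrt(1 - w) * f[, m]
        if (length(oth) && w > 0) {
          raw <- raw + sqrt(w / length(oth)) * rowSums(f[, oth, drop = FALSE])
        }
        for (blk in blocks) raw[blk] <- raw[blk] / sd(raw[blk])
        j <- n_members + (m - 1) * cfg$n_hubs + h
        X[, j] <- sqrt(1 - cfg$hub_noise^2) * raw +
          cfg$hub_noise * ortho_resid(blocks, fac)
        hub_module <- c(hub_module, m)
      }
    }

    otu_ids <- sprintf("OTU_%04d", seq_len(cfg$n_taxa))
    member_ids <- otu_ids[seq_len(n_members)]
    hub_ids <- otu_ids[n_members + seq_len(n_hub)]

    # weights: planted block + log-normal background
    w_signal <- cfg$signal_weight * exp(cfg$latent_scale * X)
    w_bg <- matrix(exp(rnorm(n * n_bg, 0, cfg$background_sd)), n)

    # shared core and gut richness thinning (background only)
    n_core <- ceiling(cfg$shared_core_fraction * cfg$n_taxa)
    n_core_bg <- max(0L, n_core - n_signal)
    noncore_bg <- setdiff(seq_len(n_bg), seq_len(n_core_bg))
    n_drop <- round((1 - cfg$gut_diversity_deficit) * length(noncore_bg))
    drop_bg <- if (n_drop > 0) sample(noncore_bg, n_drop) else integer(0)
    w_bg[blocks$gut, drop_bg] <- 0

    W <- cbind(w_signal, w_bg)
    P <- W / rowSums(W)
    depth <- cfg$depth_mean[meta$habitat]
    sdl <- sqrt(log(1 + cfg$depth_cv^2))
    depth <- rlnorm(n, meanlog = log(depth) - sdl^2 / 2, sdlog = sdl)
    counts <- matrix(rnbinom(length(P), mu = depth * P, size = cfg$nb_size), n)

    counts <- t(counts)
    rownames(counts) <- otu_ids
    colnames(counts) <- meta$sample_id
    table <- otu_table(counts, taxonomy = synth_taxonomy(cfg$n_taxa))

    # environmental covariates: group means plus noise, then mixed with the
    # community factor G so that the coupling is an effect size against the
    # covariate's *total* (between- plus within-group) variation -- group
    # mean differences would otherwise swamp a within-group coupling
    prof <- cfg$env_profile
    for (i in seq_len(nrow(prof))) {
      v <- prof$covariate[i]
      gamma <- unname(cfg$env_coupling[v])
      gamma <- if (is.null(gamma) || is.na(gamma)) 0 else gamma
      mu <- unlist(prof[i, meta$group_label])
      base <- unname(mu + prof$sd[i] * rnorm(n))
      if (gamma != 0) {
        dev <- base - mean(base)
        meta[[v]] <- mean(base) +
          sqrt(1 - gamma^2) * dev + gamma * sd(base) * G
      } else {
        meta[[v]] <- base
      }
    }

    truth <- list(
      modules = tibble(otu_id = member_ids, module = member_module),
      hubs = tibble(otu_id = hub_ids, module = hub_module),
      core_ids = otu_ids[seq_len(min(cfg$n_taxa, n_signal + n_core_bg))],
      env_coupling = cfg$env_coupling,
      group_metabolism = cfg$biolog_asymptote
    )
    list(table = table, metadata = meta, truth = truth)
  })
}

# Deterministic synthetic 7-rank lineages.
synth_taxonomy <- function(n_taxa) {
  i <- seq_len(n_taxa)
  sprintf("Bacteria;Phylum_%02d;Class_%02d;Order_%02d;Family_%03d;Genus_%03d;",
          i %% 12 + 1, i %% 27 + 1, i %% 53 + 1, i %% 101 + 1, i)
}

#' Generate synthetic Biolog plates
#'
#' One plate per sample: 71 substrate wells plus the water control. Well
#' trajectories follow a logistic curve toward the sample group's asymptote
#' mean, with a multiplicative per-well effect and additive Gaussian reading
#' noise (both scaled by `biolog_noise_sd`; zero noise gives exactly the
#' configured asymptote at large times), clamped at zero. The control well
#' carries baseline plus noise only.
#'
#' @param config a [sim_config()].
#' @param meta metadata tibble (needs `sample_id` and `group_label`).
#' @return a plate tibble (see [read_biolog()]) covering all samples.
#' @export
generate_biolog <- function(config, meta) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  catalog <- biolog_catalog()
  withr::with_seed(derive_seed(cfg$seed, "biolog"), {
    purrr::map_dfr(seq_len(nrow(meta)), function(si) {
      g <- meta$group_label[si]
      amp <- unname(cfg$biolog_asymptote[g])
      wells <- catalog %>%
        mutate(well_effect = ifelse(
          .data$is_control, 0,
          amp * exp(rnorm(dplyr::n(), 0, cfg$biolog_noise_sd))
        ))
      tidyr::crossing(wells, time_h = cfg$biolog_times) %>%
        mutate(
          sample_id = meta$sample_id[si],
          od590 = pmax(
            cfg$biolog_baseline +
              .data$well_effect /
                (1 + exp(-cfg$biolog_rate * (.data$time_h - cfg$biolog_midpoint))) +
              rnorm(dplyr::n(), 0, cfg$biolog_noise_sd),
            0
          )
        ) %>%
        select("sample_id", "well_id", "carbon_source", "category",
               "is_control", "time_h", "od590")
    })
  })
}

#' Write a synthetic bundle to disk
#'
#' Emits the same TSV/CSV formats the readers consume, plus the truth record
#' as JSON.
#'
#' @param bundle result of [generate_community()] (optionally with a
#'   `biolog` element).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(bundle$table, file.path(dir, "otu_table.tsv"))
  write_sample_metadata(bundle$metadata, file.path(dir, "metadata.tsv"))
  if (!is.null(bundle$biolog)) {
    write_biolog(bundle$biolog, file.path(dir, "biolog.csv"))
  }
  jsonlite::write_json(
    list(
      modules = bundle$truth$modules,
      hubs = bundle$truth$hubs,
      core_ids = bundle$truth$core_ids,
      env_coupling = as.list(bundle$truth$env_coupling),
      group_metabolism = as.list(bundle$truth$group_metabolism)
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
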