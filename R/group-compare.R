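#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Compares a per-sample quantity across groups: one-way ANOVA F test,
#' all pairwise Tukey honestly-significant-difference comparisons (with the
#' studentized-range statistic q), and a compact letter display at the given
#' alpha -- groups sharing a letter are not significantly different.
#'
#' @param data a data frame with one row per sample.
#' @param value column holding the numeric response (tidy-eval).
#' @param group column holding the group factor (tidy-eval).
#' @param alpha significance level for the letter display (default 0.05).
#' @return an object of class `group_comparison`; see [tidy.group_comparison()]
#'   and [glance.group_comparison()].
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 4), y = c(1:4, 11:14))
#' group_compare(d, y, g)
#' @export
group_compare <- function(data, value, group, alpha = 0.05) {
  df <- tibble(
    value = dplyr::pull(data, {{ value }}),
    group = as.character(dplyr::pull(data, {{ group }}))
  )
  if (anyNA(df$value)) abort("group_compare(): missing values in the response")
  sizes <- dplyr::count(df, .data$group)
  if (nrow(sizes) < 2) abort("group_compare() needs at least 2 groups")
  small <- sizes$group[sizes$n < 2]
  if (length(small)) {
    abort(sprintf("group(s) with fewer than 2 samples: %s",
                  paste(small, collapse = ", ")))
  }
  df$group <- factor(df$group)
  means <- df %>%
    group_by(.data$group) %>%
    summarise(n = dplyr::n(), mean = mean(.data$value), .groups = "drop") %>%
    mutate(group = as.character(.data$group))

  fit <- aov(value ~ group, data = df)
  an <- suppressWarnings(anova(fit))
  fstat <- an[["F value"]][1]
  pval <- an[["Pr(>F)"]][1]
  mse <- an[["Mean Sq"]][2]
  # a response with no variation at all has no F test worth reporting
  degenerate <- !is.finite(fstat) ||
    all(abs(df$value - df$value[1]) < 1e-12)

  glance_tbl <- tibble(
    statistic = if (degenerate) NA_real_ else fstat,
    df = an$Df[1], df.residual = an$Df[2],
    p.value = if (degenerate) NA_real_ else pval,
    mean.sq.error = mse
  )

  if (degenerate && all(abs(means$mean - means$mean[1]) < 1e-12)) {
    # identical values within and between groups: no differences at all
    tukey_tbl <- tidyr::crossing(group1 = means$group, group2 = means$group) %>%
      filter(.data$group1 < .data$group2) %>%
      mutate(estimate = 0, conf.low = 0, conf.high = 0,
             q = 0, adj.p.value = 1)
  } else {
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
    cmp <- stringr::str_split_fixed(rownames(tk), "-", 2)
    n_by <- setNames(means$n, means$group)
    tukey_tbl <- tibble(
      group1 = cmp[, 1], group2 = cmp[, 2],
      estimate = unname(tk[, "diff"]),
      conf.low = unname(tk[, "lwr"]), conf.high = unname(tk[, "upr"]),
      q = unname(abs(tk[, "diff"]) /
        sqrt(mse / 2 * (1 / n_by[cmp[, 1]] + 1 / n_by[cmp[, 2]]))),
      adj.p.value = unname(tk[, "p adj"])
    )
  }

  letters_tbl <- cld_letters(means, tukey_tbl, alpha)

  structure(
    list(glance = glance_tbl, tukey = tukey_tbl, letters = letters_tbl,
         alpha = alpha),
    class = "group_comparison"
  )
}

# Compact letter display: maximal cliques of the not-significantly-different
# graph, ordered by descending group mean, lettered a, b, c, ...
cld_letters <- function(means, tukey, alpha) {
  gs <- means$group[order(-means$mean)]
  g <- igraph::make_empty_graph(n = length(gs), directed = FALSE)
  igraph::V(g)$name <- gs
  ns <- tukey[tukey$adj.p.value >= alpha | !is.finite(tukey$adj.p.value), ]
  if (nrow(ns)) {
    g <- igraph::add_edges(g, rbind(match(ns$group1, gs), match(ns$group2, gs)))
  }
  cl <- igraph::max_cliques(g)
  # order cliques by the best (largest-mean) member so 'a' marks the top group
  best <- vapply(cl, function(cc) min(match(igraph::V(g)$name[cc], gs)), numeric(1))
  cl <- cl[order(best)]
  lab <- setNames(rep("", length(gs)), gs)
  for (i in seq_along(cl)) {
    members <- igraph::V(g)$name[cl[[i]]]
    lab[members] <- paste0(lab[members], letters[i])
  }
  means %>%
    mutate(letter = unname(lab[.data$group])) %>%
    arrange(dplyr::desc(.data$mean))
}

#' @rdname group_compare
#' @param x a `group_comparison` object.
#' @param ... unused.
#' @export
tidy.group_comparison <- function(x, ...) x$tukey

#' @rdname group_compare
#' @export
glance.group_comparison <- function(x, ...) x$glance

#' @export
print.group_comparison <- function(x, ...) {
  g <- x$glance
  cat(sprintf("One-way ANOVA: F(%d, %d) = %s, p = %s\n", g$df, g$df.residual,
              format(g$statistic, digits = 4), format(g$p.value, digits = 3)))
  print(x$letters)
  invisible(x)
}
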