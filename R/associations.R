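# Association screen: Spearman correlations between oculomotor
# parameters and clinical outcomes with Benjamini-Hochberg control, and
# the high/low-EDSS z-scored subgroup contrast.

spearman_one <- function(x, y, exact_below = 10) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) return(list(rho = NA_real_, p = NA_real_, n = n, flag = "too_few_pairs"))
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, flag = "constant_column"))
  }
  rho <- cor(rank(x), rank(y))
  if (n < exact_below) {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = TRUE, alternative = "two.sided"))
    p <- ct$p.value
  } else { # t-approximation
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = min(p, 1), n = n, flag = NA_character_)
}

#' Spearman correlation screen with false-discovery-rate control
#'
#' Correlates every oculomotor parameter with every clinical outcome
#' (pairwise-complete observations), computing Spearman's rho with
#' average ranks for ties, an exact permutation p-value for fewer than
#' ten pairs and the t-approximation otherwise, and Benjamini-Hochberg
#' adjusted p-values within each outcome's family of parameters (or
#' globally across all tests).
#'
#' @param profiles Tibble of per-participant parameters (`participant`
#'   plus parameter columns).
#' @param outcomes Tibble of per-participant outcomes (`participant`
#'   plus outcome columns, e.g. `edss`, `sdmt`, `bicams`, `msfc`).
#' @param alpha Significance level for the adjusted p-values.
#' @param family BH family scope: `"per_outcome"` (default) or
#'   `"global"`.
#' @return Tibble: `parameter`, `outcome`, `rho`, `n`, `p`, `p_adj`,
#'   `significant`, `flag`; the family scope is recorded in the
#'   `bh_family` attribute.
#' @export
spearman_with_fdr <- function(profiles, outcomes, alpha = 0.05,
                              family = c("per_outcome", "global")) {
  family <- match.arg(family)
  key <- intersect(names(profiles), names(outcomes))
  key <- key[key %in% c("participant", "id")]
  if (length(key) == 0) abort("`profiles` and `outcomes` must share a `participant` column.")
  merged <- dplyr::inner_join(profiles, outcomes, by = key[1],
                              suffix = c("", ".outcome"))
  params <- setdiff(names(profiles), key)
  outs <- setdiff(names(outcomes), key)
  grid <- tidyr::expand_grid(parameter = params, outcome = outs)
  res <- purrr::pmap(grid, function(parameter, outcome) {
    r <- spearman_one(merged[[parameter]],
                      merged[[if (outcome %in% names(merged)) outcome
                              else paste0(outcome, ".outcome")]])
    tibble(parameter = parameter, outcome = outcome, rho = r$rho,
           n = r$n, p = r$p, flag = r$flag)
  }) %>% bind_rows()
  if (family == "per_outcome") {
    res <- res %>%
      group_by(.data$outcome) %>%
      mutate(p_adj = p.adjust(.data$p, method = "BH")) %>%
      ungroup()
  } else {
    res$p_adj <- p.adjust(res$p, method = "BH")
  }
  res <- res %>%
    mutate(significant = !is.na(.data$p_adj) & .data$p_adj < alpha) %>%
    select("parameter", "outcome", "rho", "n", "p", "p_adj", "significant", "flag")
  attr(res, "bh_family") <- family
  attr(res, "alpha") <- alpha
  res
}

#' High- vs low-EDSS subgroup contrast
#'
#' z-scores each oculomotor parameter against the whole cohort, splits
#' participants into low (EDSS <= cutoff) and high (EDSS >= cutoff + 0.5)
#' disability subgroups, and compares each parameter between subgroups
#' with a two-sided Mann–Whitney U test (exact when the smaller group has
#' fewer than 20 observations and there are no ties; normal approximation
#' with tie correction otherwise). The subgroup mean z-scores are the
#' radar-plot table.
#'
#' @param profiles Per-participant parameter tibble.
#' @param outcomes Tibble with `participant` and `edss`.
#' @param cutoff Low-group upper bound on the 0.5-step EDSS grid.
#' @param alpha Significance level for BH-adjusted p-values.
#' @return Tibble: `parameter`, `mean_z_low`, `mean_z_high`, `n_low`,
#'   `n_high`, `statistic` (U of the low group), `p`, `p_adj`,
#'   `significant`.
#' @export
compare_edss_subgroups <- function(profiles, outcomes, cutoff = 4,
                                   alpha = 0.05) {
  key <- intersect(names(profiles), names(outcomes))
  key <- key[key %in% c("participant", "id")]
  if (length(key) == 0) abort("`profiles` and `outcomes` must share a `participant` column.")
  merged <- dplyr::inner_join(profiles, outcomes[, c(key[1], "edss")], by = key[1])
  low <- merged$edss <= cutoff
  high <- merged$edss >= cutoff + 0.5
  if (!any(low, na.rm = TRUE) || !any(high, na.rm = TRUE)) {
    abort(sprintf("A subgroup at EDSS cutoff %.1f/%.1f is empty.", cutoff, cutoff + 0.5))
  }
  params <- setdiff(names(profiles), key)
  res <- purrr::map(params, function(pm) {
    x <- merged[[pm]]
    z <- (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
    zl <- z[low & is.finite(z)]
    zh <- z[high & is.finite(z)]
    if (length(zl) < 1 || length(zh) < 1 || (sd(c(zl, zh)) == 0)) {
      return(tibble(parameter = pm, mean_z_low = mean(zl), mean_z_high = mean(zh),
                    n_low = length(zl), n_high = length(zh),
                    statistic = NA_real_, p = NA_real_))
    }
    ties <- anyDuplicated(c(zl, zh)) > 0
    wt <- suppressWarnings(
      wilcox.test(zl, zh, exact = min(length(zl), length(zh)) < 20 && !ties,
                  correct = TRUE)
    )
    tibble(parameter = pm, mean_z_low = mean(zl), mean_z_high = mean(zh),
           n_low = length(zl), n_high = length(zh),
           statistic = unname(wt$statistic), p = wt$p.value)
  }) %>% bind_rows()
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res
}
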