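#' Group comparisons for replicate-level rotation statistics
#'
#' Tidy wrappers around the standard tests used to compare per-replicate
#' angular-velocity and twisting summaries across chambers and genotypes:
#' Wilcoxon rank-sum (= Mann-Whitney U) with Bonferroni correction across
#' a set of prespecified comparisons, the equal-variance two-sample
#' t-test, and a one-way ANOVA convenience wrapper. Rank-sum and
#' Mann-Whitney are the same test family; p-values are exact for small
#' untied samples and use the normal approximation with continuity and
#' tie correction otherwise.
#'
#' @name stats_compare
NULL

#' Significance stars for a p-value
#'
#' `ns` (p >= 0.05), `*` (< 0.05), `**` (< 0.01), `***` (< 0.001),
#' `****` (< 0.0001) — the mapping used in the figure panels this package
#' reproduces the analysis style of.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Mann-Whitney U test (two-sided)
#'
#' @param a,b numeric samples.
#' @return list with `U` (the Mann-Whitney U of sample `a`), `p`
#'   (two-sided) and `method`.
#' @export
mannwhitney_u <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  vals <- c(a, b)
  if (length(unique(vals)) == 1L) {   # every observation tied
    return(list(U = length(a) * length(b) / 2, p = 1,
                method = "degenerate (all values tied)"))
  }
  exact <- length(a) <= 8L && length(b) <= 8L && !anyDuplicated(vals)
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                       alternative = "two.sided")
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact enumeration" else "normal approximation, tie/continuity corrected")
}

#' Equal-variance two-sample (or paired) t-test, two-sided
#'
#' Degenerate limits are defined rather than errors: with zero pooled
#' variance the test returns `p = 1` when the means agree and `p = 0`
#' (infinite t) when they differ.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param paired logical.
#' @return list with `t`, `df`, `p`.
#' @export
ttest_two_sample <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (paired) stopifnot(length(a) == length(b))
  pooled0 <- if (paired) stats::var(a - b) == 0 else
    (stats::var(a) == 0 && stats::var(b) == 0)
  if (pooled0) {
    d <- mean(a) - mean(b)
    df <- if (paired) length(a) - 1L else length(a) + length(b) - 2L
    if (d == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(d) * Inf, df = df, p = 0))
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = TRUE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' One-way ANOVA convenience wrapper
#'
#' @param values numeric vector.
#' @param groups factor or character vector of group labels.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2L)
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
       p = s[["Pr(>F)"]][1])
}

#' Rank-sum tests with Bonferroni correction over prespecified comparisons
#'
#' Runs the two-sided Wilcoxon rank-sum / Mann-Whitney U test for each
#' requested pair of groups and Bonferroni-adjusts across the `m`
#' comparisons actually made: `p_adj = min(1, m * p_raw)`. `m` is always
#' explicit — it is the number of comparisons you pass in.
#'
#' @param table data.frame with at least a group column and a value
#'   column (e.g. one row per replicate x chamber x window).
#' @param comparisons list of length-2 character vectors of group labels.
#' @param group_col,value_col column names in `table`.
#' @return tidy data.frame: `group_a`, `group_b`, `n_a`, `n_b`, `U`,
#'   `p_raw`, `p_adj`, `stars`. Comparisons with an empty group are
#'   skipped with a warning.
#' @export
ranksum_bonferroni <- function(table, comparisons, group_col = "group",
                               value_col = "value") {
  stopifnot(is.data.frame(table), length(comparisons) >= 1L)
  for (cc in c(group_col, value_col)) {
    if (!cc %in% names(table)) {
      stop("schema error: missing column ", sQuote(cc), call. = FALSE)
    }
  }
  if (!all(is.finite(table[[value_col]]))) {
    stop("values must be finite", call. = FALSE)
  }
  m <- length(comparisons)
  rows <- lapply(comparisons, function(pair) {
    stopifnot(length(pair) == 2L)
    a <- table[[value_col]][table[[group_col]] == pair[1]]
    b <- table[[value_col]][table[[group_col]] == pair[2]]
    if (!length(a) || !length(b)) {
      warning("comparison ", pair[1], " vs ", pair[2],
              " skipped: empty group", call. = FALSE)
      return(NULL)
    }
    mw <- mannwhitney_u(a, b)
    data.frame(group_a = pair[1], group_b = pair[2],
               n_a = length(a), n_b = length(b),
               U = mw$U, p_raw = mw$p,
               p_adj = min(1, m * mw$p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(group_a = character(0), group_b = character(0),
                      n_a = integer(0), n_b = integer(0), U = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      stars = character(0)))
  }
  out$stars <- p_stars(out$p_adj)
  out
}
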