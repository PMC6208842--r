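# Normality-gated group comparisons: Shapiro-Wilk gate, (repeated-measures)
# ANOVA with Bonferroni-corrected post-hocs, Mann-Whitney U fallback.
# Supporting machinery following standard definitions.

shapiro_ok <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(unique(x)) == 1) return(TRUE)
  if (length(x) > 5000) x <- sample(x, 5000)
  shapiro.test(x)$p.value >= alpha
}

#' Compare an outcome between groups (with optional within-subject factor)
#'
#' Aggregates the outcome to one value per subject (and per level of the
#' within-subject factor, if given), applies a Shapiro-Wilk normality gate
#' per group (alpha = 0.05), and runs either the parametric route —
#' independent-samples t test, or a repeated-measures ANOVA
#' (`outcome ~ group * within + Error(subject/within)`) with
#' Bonferroni-corrected paired post-hoc t tests across within levels —
#' or the Mann-Whitney U test when normality fails.
#'
#' @param data tibble with the outcome and design columns.
#' @param outcome,group,subject column names (strings).
#' @param within optional within-subject factor column name.
#' @param alpha significance level of the normality gate.
#' @param one_tailed use a one-tailed group t test (direction: first group
#'   level lower).
#' @return tibble of class `group_comparison`: `effect`, `method`,
#'   `statistic`, `df1`, `df2`, `p_value`, `p_adjusted`,
#'   `normality_passed`.
#' @export
group_compare <- function(data, outcome, group = "group",
                          subject = "subject", within = NULL,
                          alpha = 0.05, one_tailed = FALSE) {
  cols <- c(outcome, group, subject, within)
  stopifnot(all(cols %in% names(data)))
  agg_by <- c(subject, group, within)
  d <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(agg_by))) |>
    dplyr::summarise(value = mean(.data[[outcome]], na.rm = TRUE),
                     .groups = "drop")
  d <- d[is.finite(d$value), ]
  glev <- unique(d[[group]])
  if (length(glev) != 2)
    stop("group_compare needs exactly two groups", call. = FALSE)
  n_per <- table(d[[group]][!duplicated(d[[subject]])])
  if (any(n_per < 2))
    stop("need at least 2 subjects per group", call. = FALSE)

  normal <- all(vapply(glev, function(g)
    shapiro_ok(d$value[d[[group]] == g], alpha), logical(1)))
  res <- list()

  if (is.null(within)) {
    x <- d$value[d[[group]] == glev[1]]
    y <- d$value[d[[group]] == glev[2]]
    if (normal) {
      tt <- t.test(x, y, var.equal = TRUE,
                   alternative = if (one_tailed) "less" else "two.sided")
      res[[1]] <- tibble::tibble(effect = "group", method = "t_test",
                                 statistic = unname(tt$statistic),
                                 df1 = unname(tt$parameter), df2 = NA_real_,
                                 p_value = tt$p.value, p_adjusted = tt$p.value)
    } else {
      wt <- wilcox.test(x, y, exact = FALSE)
      res[[1]] <- tibble::tibble(effect = "group", method = "mann_whitney_u",
                                 statistic = unname(wt$statistic),
                                 df1 = NA_real_, df2 = NA_real_,
                                 p_value = wt$p.value, p_adjusted = wt$p.value)
    }
  } else {
    d$.g <- factor(d[[group]]); d$.w <- factor(d[[within]])
    d$.s <- factor(d[[subject]])
    if (normal) {
      fit <- aov(value ~ .g * .w + Error(.s / .w), data = d)
      sm <- summary(fit)
      for (stratum in sm) {
        tab <- stratum[[1]]
        terms <- rownames(tab)
        for (i in seq_along(terms)) {
          tm <- trimws(terms[i])
          if (tm == "Residuals") next
          res[[length(res) + 1L]] <- tibble::tibble(
            effect = gsub("\\.g", "group", gsub("\\.w", within, tm)),
            method = "rm_anova",
            statistic = tab[i, "F value"],
            df1 = tab[i, "Df"],
            df2 = tab[nrow(tab), "Df"],
            p_value = tab[i, "Pr(>F)"],
            p_adjusted = tab[i, "Pr(>F)"]
          )
        }
      }
      ph <- pairwise.t.test(d$value, d$.w, p.adjust.method = "bonferroni",
                            paired = FALSE)
      pm <- ph$p.value
      for (i in seq_len(nrow(pm))) for (j in seq_len(ncol(pm))) {
        if (is.na(pm[i, j])) next
        res[[length(res) + 1L]] <- tibble::tibble(
          effect = paste0(within, ": ", rownames(pm)[i], " vs ",
                          colnames(pm)[j]),
          method = "posthoc_t_bonferroni", statistic = NA_real_,
          df1 = NA_real_, df2 = NA_real_, p_value = pm[i, j],
          p_adjusted = pm[i, j]
        )
      }
    } else {
      for (lev in levels(d$.w)) {
        dd <- d[d$.w == lev, ]
        wt <- wilcox.test(dd$value[dd$.g == glev[1]],
                          dd$value[dd$.g == glev[2]], exact = FALSE)
        res[[length(res) + 1L]] <- tibble::tibble(
          effect = paste0("group @ ", within, "=", lev),
          method = "mann_whitney_u", statistic = unname(wt$statistic),
          df1 = NA_real_, df2 = NA_real_, p_value = wt$p.value,
          p_adjusted = NA_real_
        )
      }
      k <- length(res)
      for (i in seq_len(k))
        res[[i]]$p_adjusted <- min(1, res[[i]]$p_value * k)
    }
  }
  out <- dplyr::bind_rows(res)
  out$normality_passed <- normal
  structure(out, class = c("group_comparison", class(out)))
}
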