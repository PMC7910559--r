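#' Significance stars
#'
#' The conventional annotation: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `ns` otherwise.
#'
#' @param p p-value(s).
#' @return character vector of star labels.
#' @export
p_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) NA_character_
    else if (x < 0.001) "***"
    else if (x < 0.01) "**"
    else if (x < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Group summary (mean and SEM)
#'
#' @param values numeric measurements.
#' @param label group label.
#' @return data.frame with `label`, `n`, `mean`, `sem` (NA for n < 2).
#' @export
group_summary <- function(values, label = "group") {
  n <- length(values)
  if (n < 1) stop("empty group")
  data.frame(label = label, n = n, mean = mean(values),
             sem = if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and two-sided p-value, the comparison used for two-condition measurement
#' sets.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 observations.
#' @return list with `t`, `df`, `p`, group means, and `stars`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations")
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b),
       stars = p_stars(ht$p.value))
}

#' One-way ANOVA with Tukey's post hoc correction
#'
#' The comparison used for measurement sets with more than two conditions:
#' one-way analysis of variance followed by Tukey honest significant
#' differences, whose adjusted p-values come from the studentized range
#' distribution. With two groups the ANOVA degenerates to the pooled t-test
#' (F equals t squared).
#'
#' @param groups a named list of numeric vectors (>= 2 groups, each with
#'   >= 2 observations), or a data.frame with columns `value` and `group`.
#' @return list with `F`, `df`, `p`, and `pairwise`: a data.frame of all
#'   group pairs with mean difference, Tukey-adjusted p, and stars.
#' @export
anova_tukey <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    dat <- data.frame(value = groups$value, group = factor(groups$group))
  } else {
    if (is.null(names(groups)) || any(!nzchar(names(groups))))
      names(groups) <- paste0("g", seq_along(groups))
    dat <- data.frame(value = unlist(groups, use.names = FALSE),
                      group = factor(rep(names(groups), lengths(groups)),
                                     levels = names(groups)))
  }
  ns <- table(dat$group)
  if (length(ns) < 2) stop("need at least 2 groups")
  if (any(ns < 2)) stop("every group needs at least 2 observations")
  fit <- stats::aov(value ~ group, data = dat)
  s <- summary(fit)[[1]]
  Fv <- s[["F value"]][1]
  pv <- s[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  pw <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                   p_adj = tk[, "p adj"], stars = p_stars(tk[, "p adj"]),
                   row.names = NULL)
  list(F = Fv, df = c(s$Df[1], s$Df[2]), p = pv, pairwise = pw)
}
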