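#' Coefficient of variation
#'
#' Sample standard deviation (denominator `n - 1`) divided by the mean.
#'
#' @param values Numeric vector, `n >= 2`, non-zero mean.
#' @return Scalar CoV.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("need at least two values")
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  stats::sd(values) / m
}

#' Coefficient-of-variation matrix for a clustered heatmap
#'
#' Computes the CoV of every variable within every group, then z-scores
#' each variable across groups (the normalization applied along the
#' condition axis in clustered CoV heatmaps).  Hierarchical-clustering
#' row/column orders are attached as metadata only; plotting is left to
#' the caller.
#'
#' @param table Feature table (e.g. from [extract_cell_features()]).
#' @param variables Character vector of numeric columns.
#' @param group Name of the grouping column.
#' @return A list of class `omi_cov_matrix`: `cov` (variables x groups),
#'   `z` (row-wise z-scored; constant rows become 0 with a warning),
#'   `row_order`, `col_order` (hclust orders on the z matrix).
#' @export
cov_heatmap_matrix <- function(table, variables, group = "condition") {
  if (!group %in% names(table)) stop("grouping column not found")
  groups <- unique(as.character(table[[group]]))
  bad <- expand.grid(variable = variables, group = groups,
                     stringsAsFactors = FALSE)
  bad$n <- mapply(function(v, g) sum(table[[group]] == g & !is.na(table[[v]])),
                  bad$variable, bad$group)
  if (any(bad$n < 2))
    stop("fewer than 2 observations for: ",
         paste(sprintf("%s/%s", bad$variable[bad$n < 2],
                       bad$group[bad$n < 2]), collapse = ", "))
  cv <- sapply(groups, function(g) {
    sub <- table[table[[group]] == g, , drop = FALSE]
    vapply(variables, function(v)
      coefficient_of_variation(sub[[v]][!is.na(sub[[v]])]), numeric(1))
  })
  cv <- matrix(cv, nrow = length(variables), ncol = length(groups),
               dimnames = list(variables, groups))
  z <- t(apply(cv, 1, function(r) {
    s <- stats::sd(r)
    if (!is.finite(s) || s == 0) {
      warning("constant CoV row z-scored to 0")
      rep(0, length(r))
    } else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(cv)
  row_order <- if (nrow(z) > 2)
    stats::hclust(stats::dist(z))$order else seq_len(nrow(z))
  col_order <- if (ncol(z) > 2)
    stats::hclust(stats::dist(t(z)))$order else seq_len(ncol(z))
  structure(list(cov = cv, z = z, row_order = row_order,
                 col_order = col_order),
            class = "omi_cov_matrix")
}

#' Glass's delta effect size
#'
#' \eqn{\Delta = (\bar x_{treated} - \bar x_{control}) / s_{control}}
#' with the sample SD (`n - 1`) of the control group — the effect size
#' used when the treatment may change the variance.
#'
#' @param treated,control Numeric vectors.
#' @return A list of class `omi_effect_size`: `delta`, `mean_treated`,
#'   `mean_control`, `sd_control`, `n_treated`, `n_control`.
#' @export
glass_delta <- function(treated, control) {
  s <- stats::sd(control)
  if (!is.finite(s) || s == 0)
    stop("control SD is zero; Glass's delta undefined")
  structure(list(delta = (mean(treated) - mean(control)) / s,
                 mean_treated = mean(treated),
                 mean_control = mean(control), sd_control = s,
                 n_treated = length(treated),
                 n_control = length(control)),
            class = "omi_effect_size")
}

#' Log2 fold change of an abundance relative to control
#'
#' @param abundance,control_abundance Positive abundances; replicate
#'   vectors are averaged before the ratio is taken.
#' @return `log2(mean(abundance) / mean(control_abundance))`.
#' @export
log2_fold_change <- function(abundance, control_abundance) {
  if (any(abundance <= 0) || any(control_abundance <= 0))
    stop("abundances must be positive (no pseudo-count is applied)")
  log2(mean(abundance) / mean(control_abundance))
}

#' Redox ratio from LC-MS cofactor concentrations
#'
#' The mass-spectrometry analogue of the optical redox ratio, computed
#' from molar concentrations of the redox cofactors.  Two conventions are
#' supported because the literature uses both; the one used is recorded
#' in the result so outputs are self-describing.
#'
#' @param nadh,nadph,fad Molar concentrations (>= 0).
#' @param definition `"nadh_nadph"` (default):
#'   `(NADH + NADPH) / (NADH + NADPH + FAD)`; `"nadph_only"`:
#'   `NADPH / (NADPH + FAD)`.
#' @return A list of class `omi_lcms_redox`: `value`, `definition`.
#' @export
lcms_redox <- function(nadh, nadph, fad,
                       definition = c("nadh_nadph", "nadph_only")) {
  definition <- match.arg(definition)
  if (any(c(nadh, nadph, fad) < 0))
    stop("concentrations must be non-negative")
  num <- if (definition == "nadh_nadph") nadh + nadph else nadph
  den <- num + fad
  if (den == 0) stop("zero denominator; redox ratio undefined")
  structure(list(value = num / den, definition = definition),
            class = "omi_lcms_redox")
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Two-group t test or one-way ANOVA with Tukey's post hoc test
#'
#' Thin contract over the standard routines: Student's t test (pooled
#' variance) for two groups, one-way ANOVA with Tukey's HSD for three or
#' more.  Significance stars follow the 0.05 / 0.01 / 0.001 convention.
#'
#' @param table Data frame with the response and grouping columns.
#' @param variable Name of the numeric response column.
#' @param group Name of the grouping column.
#' @param method `"auto"` picks the t test for two groups and ANOVA
#'   otherwise; `"t"` and `"anova"` force the choice.
#' @return A list of class `omi_group_test`: `method`, `statistic`,
#'   `p_value`, `stars`, and for ANOVA a `posthoc` data.frame of Tukey
#'   pairwise comparisons (`comparison`, `diff`, `p_adj`, `stars`).
#' @export
compare_groups <- function(table, variable, group = "condition",
                           method = c("auto", "t", "anova")) {
  method <- match.arg(method)
  g <- factor(table[[group]])
  x <- table[[variable]]
  if (nlevels(g) < 2) stop("need at least two groups")
  if (method == "auto") method <- if (nlevels(g) == 2) "t" else "anova"
  if (method == "t") {
    if (nlevels(g) != 2) stop("t test requires exactly two groups")
    tt <- stats::t.test(x ~ g, var.equal = TRUE)
    out <- list(method = "student_t", statistic = unname(tt$statistic),
                p_value = tt$p.value, stars = significance_stars(tt$p.value),
                posthoc = NULL)
  } else {
    fit <- stats::aov(x ~ g)
    an <- summary(fit)[[1]]
    p <- an[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$g
    out <- list(method = "anova_tukey", statistic = an[["F value"]][1],
                p_value = p, stars = significance_stars(p),
                posthoc = data.frame(comparison = rownames(tk),
                                     diff = tk[, "diff"],
                                     p_adj = tk[, "p adj"],
                                     stars = significance_stars(
                                       tk[, "p adj"]),
                                     row.names = NULL))
  }
  structure(out, class = "omi_group_test")
}

#' @export
print.omi_group_test <- function(x, ...) {
  cat(sprintf("<omi_group_test> %s: statistic = %.4g, p = %.3g %s\n",
              x$method, x$statistic, x$p_value, x$stars))
  if (!is.null(x$posthoc)) print(x$posthoc)
  invisible(x)
}
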