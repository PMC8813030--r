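covariate_design <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) &&
                              ncol(covariates) == 0)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  if (!is.null(covariates$sex) && !is.numeric(covariates$sex)) {
    covariates$sex <- as.integer(factor(covariates$sex)) - 1L
  }
  model.matrix(~ ., data = covariates)
}

#' Residualize a response on nuisance covariates
#'
#' Least-squares residuals of `y` on an intercept plus the covariate
#' columns (sex coded 0/1 if given as a factor/character). With no
#' covariates this reduces to mean-centering.
#'
#' @param y numeric vector (or n x m matrix of responses).
#' @param covariates data.frame of nuisance covariates (e.g. age, sex,
#'   education, mean FD), or NULL.
#' @return residuals with the same shape as `y`.
#' @export
covariate_adjust <- function(y, covariates = NULL) {
  y <- as.matrix(y)
  X <- covariate_design(covariates, nrow(y))
  res <- lm.fit(X, y)$residuals
  if (ncol(y) == 1) drop(res) else res
}

#' Covariate-adjusted group F-test
#'
#' Linear model `y ~ group + covariates` versus the reduced model without
#' group: an exact F-test of the group effect with nuisance covariates
#' partialled out (the univariate follow-up used for edge-wise and
#' metric-wise group comparisons). When both models fit perfectly (zero
#' residual variance) the test is uninformative and reported as F = 0,
#' p = 1.
#'
#' @param y numeric response vector.
#' @param group factor with >= 2 levels.
#' @param covariates optional data.frame of nuisance covariates.
#' @param feature_id label carried through to the result.
#' @return list with `feature_id`, `statistic` (F), `df1`, `df2`, `p`,
#'   `group_means` (covariate-adjusted), `test_name`.
#' @export
group_glm_ftest <- function(y, group, covariates = NULL,
                            feature_id = "feature") {
  group <- droplevels(as.factor(group))
  n <- length(y)
  Xc <- covariate_design(covariates, n)
  Xg <- model.matrix(~ group)[, -1, drop = FALSE]
  Xf <- cbind(Xc, Xg)
  fit_full <- lm.fit(Xf, y)
  fit_red <- lm.fit(Xc, y)
  rss1 <- sum(fit_full$residuals^2)
  rss0 <- sum(fit_red$residuals^2)
  df1 <- ncol(Xg)
  df2 <- n - fit_full$rank
  if (rss1 <= .Machine$double.eps * max(1, rss0)) {
    f <- if (rss0 - rss1 <= .Machine$double.eps) 0 else Inf
    p <- if (f == 0) 1 else 0
  } else {
    f <- ((rss0 - rss1) / df1) / (rss1 / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  adj <- covariate_adjust(y, covariates) + mean(y)
  list(feature_id = feature_id, statistic = f, df1 = df1, df2 = df2, p = p,
       group_means = tapply(adj, group, mean), test_name = "ancova_f")
}

#' Edge-wise covariate-adjusted group F-tests
#'
#' Vectorized version of [group_glm_ftest()] for a matrix of features
#' (subjects x edges/metrics): one QR decomposition per design, residual
#' sums by column. Adds Benjamini-Hochberg adjusted p-values.
#'
#' @param y_matrix n x m numeric matrix, one column per feature.
#' @param group factor of group labels.
#' @param covariates optional data.frame of nuisance covariates.
#' @param q FDR level used for the `significant` flag.
#' @return data.frame: feature, F, p, q (BH-adjusted), significant.
#' @export
edge_group_ftests <- function(y_matrix, group, covariates = NULL,
                              q = 0.05) {
  y_matrix <- as.matrix(y_matrix)
  group <- droplevels(as.factor(group))
  n <- nrow(y_matrix)
  Xc <- covariate_design(covariates, n)
  Xg <- model.matrix(~ group)[, -1, drop = FALSE]
  Xf <- cbind(Xc, Xg)
  rss1 <- colSums(lm.fit(Xf, y_matrix)$residuals^2)
  rss0 <- colSums(lm.fit(Xc, y_matrix)$residuals^2)
  df1 <- ncol(Xg)
  df2 <- n - qr(Xf)$rank
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  f[rss1 <= .Machine$double.eps & (rss0 - rss1) <= .Machine$double.eps] <- 0
  p <- pf(f, df1, df2, lower.tail = FALSE)
  p[f == 0] <- 1
  adj <- fdr_bh(p, q)
  data.frame(feature = colnames(y_matrix) %||%
               paste0("f", seq_along(p)),
             statistic = f, p = p, q = adj$p_adjusted,
             significant = adj$reject, row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure with the standard monotone adjusted p-values.
#'
#' @param pvals vector of p-values.
#' @param q FDR level.
#' @return list with `reject` (logical mask) and `p_adjusted`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  adj <- p.adjust(pvals, method = "BH")
  list(reject = !is.na(adj) & adj <= q, p_adjusted = adj)
}

#' Kruskal-Wallis test
#'
#' Rank-based comparison of a response across groups (ties-corrected H,
#' chi-square p-value), used where responses are non-normal.
#'
#' @param y numeric response.
#' @param group factor of group labels.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(y, group) {
  kt <- kruskal.test(y, as.factor(group))
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Dunn post-hoc pairwise tests with Bonferroni correction
#'
#' Pairwise z-tests on mean ranks (ties-corrected pooled variance) after a
#' Kruskal-Wallis test; p-values multiplied by the number of pairs, capped
#' at 1.
#'
#' @param y numeric response.
#' @param group factor of group labels.
#' @return data.frame: group1, group2, z, p_raw, p_bonferroni.
#' @export
posthoc_dunn_bonferroni <- function(y, group) {
  group <- droplevels(as.factor(group))
  ok <- !is.na(y)
  y <- y[ok]
  group <- group[ok]
  n <- length(y)
  r <- rank(y)
  tie_tab <- table(y)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  lv <- levels(group)
  pairs <- utils::combn(lv, 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(pi) {
    a <- pairs[1, pi]; b <- pairs[2, pi]
    na <- sum(group == a); nb <- sum(group == b)
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / na + 1 / nb))
    z <- (mean(r[group == a]) - mean(r[group == b])) / se
    p <- 2 * pnorm(-abs(z))
    data.frame(group1 = a, group2 = b, z = z, p_raw = p,
               p_bonferroni = min(1, p * n_pairs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Partial correlation with nuisance covariates
#'
#' Pearson correlation between the covariate-adjusted residuals of `x` and
#' `y`; the t-test uses `df = n - 2 - k` where k is the number of covariate
#' columns in the design (after dummy coding). With no covariates this
#' reduces to the plain Pearson correlation test.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame of nuisance covariates.
#' @param x_name,y_name labels carried through to the result.
#' @return list with `r`, `p`, `df`, `x_name`, `y_name`,
#'   `covariate_names`.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                x_name = "x", y_name = "y") {
  n <- length(x)
  stopifnot(length(y) == n)
  X <- covariate_design(covariates, n)
  k <- ncol(X) - 1L
  rx <- lm.fit(X, x)$residuals
  ry <- lm.fit(X, y)$residuals
  r <- cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  list(x_name = x_name, y_name = y_name, r = r, p = p, df = df,
       covariate_names = if (is.null(covariates)) character()
                         else names(as.data.frame(covariates)))
}

#' Demographics and clinical comparison table
#'
#' Reproduces the structure of a cohort characteristics table: one-way
#' ANOVA across all groups for continuous demographics, chi-square for
#' categorical variables, and two-sample t-tests between the two patient
#' groups for clinical features.
#'
#' @param meta data.frame with a `group` column.
#' @param continuous columns compared by one-way ANOVA across all groups.
#' @param categorical columns compared by chi-square on counts.
#' @param clinical columns compared by two-sample t-test restricted to
#'   `clinical_groups`.
#' @param clinical_groups the two groups compared on clinical features.
#' @param chisq_correct apply Yates continuity correction (default FALSE).
#' @return data.frame: variable, test, statistic, p, and per-group
#'   `mean (sd)` summaries for continuous variables.
#' @export
demographics_table <- function(meta, continuous = c("age", "education"),
                               categorical = "sex",
                               clinical = character(),
                               clinical_groups = c("LTLE", "RTLE"),
                               chisq_correct = FALSE) {
  group <- droplevels(as.factor(meta$group))
  summ <- function(v) {
    vapply(levels(group), function(g) {
      sprintf("%.2f (%.2f)", mean(v[group == g], na.rm = TRUE),
              sd(v[group == g], na.rm = TRUE))
    }, "")
  }
  rows <- list()
  for (v in continuous) {
    a <- stats::anova(stats::lm(meta[[v]] ~ group))
    st <- a[["F value"]][1]
    p <- a[["Pr(>F)"]][1]
    if (is.nan(st) || is.na(p)) { st <- 0; p <- 1 }
    rows[[length(rows) + 1L]] <- c(variable = v, test = "anova_f",
                                   statistic = st, p = p, summ(meta[[v]]))
  }
  for (v in categorical) {
    tab <- table(group, meta[[v]])
    ct <- suppressWarnings(chisq.test(tab, correct = chisq_correct))
    rows[[length(rows) + 1L]] <- c(variable = v, test = "chisq",
                                   statistic = unname(ct$statistic),
                                   p = ct$p.value,
                                   setNames(rep(NA, nlevels(group)),
                                            levels(group)))
  }
  for (v in clinical) {
    sel <- group %in% clinical_groups
    tt <- t.test(meta[[v]][sel] ~ droplevels(group[sel]),
                 var.equal = TRUE)
    s <- setNames(rep(NA_character_, nlevels(group)), levels(group))
    s[clinical_groups] <- summ(meta[[v]])[clinical_groups]
    rows[[length(rows) + 1L]] <- c(variable = v, test = "t",
                                   statistic = unname(tt$statistic),
                                   p = tt$p.value, s)
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  out$statistic <- as.numeric(out$statistic)
  out$p <- as.numeric(out$p)
  rownames(out) <- NULL
  out
}
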