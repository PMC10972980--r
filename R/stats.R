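# Group- and state-level statistics: edgewise tests with FDR, a
# covariate-adjusted group model for network metrics, one-factor
# repeated-measures ANOVA with Tukey-Kramer post hoc, and the demographic
# comparisons (chi-square for sex, pooled two-sample t for age).

stat_result <- function(test_name, contrast, statistic, df1, df2 = NA_real_,
                        p_value, q_value = NA_real_, estimate = NA_real_,
                        direction = NA_real_) {
  tibble(test_name = test_name, contrast = contrast,
         statistic = statistic, df1 = df1, df2 = df2,
         p_value = p_value, q_value = q_value,
         estimate = estimate, direction = direction)
}

# Stack per-subject PLV matrices into a subjects x edges matrix.
edge_stack <- function(matrices) {
  vals <- lapply(matrices, function(m) if (inherits(m, "plv_matrix")) m$values else m)
  n <- nrow(vals[[1]])
  ut <- which(upper.tri(vals[[1]]), arr.ind = TRUE)
  labs <- rownames(vals[[1]]) %||% as.character(seq_len(n))
  X <- matrix(unlist(lapply(vals, function(v) v[upper.tri(v)])),
              nrow = length(vals), byrow = TRUE)
  list(X = X, ch1 = labs[ut[, 1]], ch2 = labs[ut[, 2]])
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values (via [stats::p.adjust()]) and the rejection
#' mask at level `alpha`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return List with `q_values` and logical `reject`.
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort_value("p-values must lie in [0, 1].")
  }
  q <- p.adjust(p_values, method = "BH")
  list(q_values = q, reject = q <= alpha)
}

#' Edgewise two-sample comparison of PLV networks
#'
#' Welch two-sample t per upper-triangle edge between two groups of
#' per-subject (epoch-mean) PLV matrices, with BH-FDR across the edges
#' (171 for the 19-channel montage).
#'
#' @param group_a,group_b Lists of [plv_matrix()] objects (or plain
#'   matrices), one per subject, >= 2 per group.
#' @param alpha FDR level.
#' @param var_equal Pooled-variance t instead of Welch.
#' @return Tibble with one row per edge: `ch1`, `ch2`, `statistic`, `df1`,
#'   `p_value`, `q_value`, `significant`, `direction` (+1 where group A
#'   exceeds group B).
#' @export
edgewise_two_sample_t <- function(group_a, group_b, alpha = 0.05,
                                  var_equal = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort_value("need at least 2 subjects per group.")
  }
  a <- edge_stack(group_a)
  b <- edge_stack(group_b)
  res <- lapply(seq_along(a$ch1), function(e) {
    x <- a$X[, e]
    y <- b$X[, e]
    if (stats::var(x) + stats::var(y) == 0) {
      # degenerate edge: zero variance in both groups
      df <- length(x) + length(y) - 2
      if (mean(x) == mean(y)) c(0, df, 1) else c(sign(mean(x) - mean(y)) * Inf, df, 0)
    } else {
      tt <- stats::t.test(x, y, var.equal = var_equal)
      unname(c(tt$statistic, tt$parameter, tt$p.value))
    }
  })
  res <- do.call(rbind, res)
  adj <- fdr_bh(res[, 3], alpha)
  tibble(ch1 = a$ch1, ch2 = a$ch2,
         statistic = res[, 1], df1 = res[, 2], p_value = res[, 3],
         q_value = adj$q_values, significant = adj$reject,
         direction = sign(colMeans(a$X) - colMeans(b$X)))
}

#' Edgewise four-state comparison within patients
#'
#' One-way ANOVA F per edge across the seizure states, with BH-FDR across
#' edges. `paired = TRUE` uses the within-subject repeated-measures F
#' instead (subjects must be in matching order across states).
#'
#' @param states Named list (one entry per state) of per-subject PLV
#'   matrix lists.
#' @param alpha FDR level.
#' @param paired Use the repeated-measures F per edge.
#' @return Tibble with one row per edge: `ch1`, `ch2`, `statistic`, `df1`,
#'   `df2`, `p_value`, `q_value`, `significant`.
#' @export
edgewise_state_anova <- function(states, alpha = 0.05, paired = FALSE) {
  if (length(states) < 2 || is.null(names(states))) {
    abort_value("`states` must be a named list with one entry per state.")
  }
  ns <- vapply(states, length, 1L)
  if (paired && length(unique(ns)) != 1) {
    abort_value("paired comparison requires every state for every subject.")
  }
  stacks <- lapply(states, edge_stack)
  n_edge <- length(stacks[[1]]$ch1)
  grp <- factor(rep(names(states), ns))
  res <- vapply(seq_len(n_edge), function(e) {
    y <- unlist(lapply(stacks, function(s) s$X[, e]), use.names = FALSE)
    if (paired) {
      wide <- do.call(cbind, lapply(stacks, function(s) s$X[, e]))
      fit <- rm_anova(wide)
      unname(c(fit$F, fit$df1, fit$df2, fit$p_value))
    } else {
      ft <- stats::oneway.test(y ~ grp, var.equal = TRUE)
      unname(c(ft$statistic, ft$parameter[1], ft$parameter[2], ft$p.value))
    }
  }, numeric(4))
  adj <- fdr_bh(res[4, ], alpha)
  tibble(ch1 = stacks[[1]]$ch1, ch2 = stacks[[1]]$ch2,
         statistic = res[1, ], df1 = res[2, ], df2 = res[3, ],
         p_value = res[4, ], q_value = adj$q_values,
         significant = adj$reject)
}

#' Covariate-adjusted group comparison of a network metric
#'
#' Ordinary least squares `metric ~ group + sex + age`; the reported test
#' is the two-sided t on the group coefficient with residual degrees of
#' freedom n - 4. Used for patient-vs-control comparisons of network
#' properties so that sex and age differences cannot masquerade as group
#' effects.
#'
#' @param data Optional data frame with columns `metric`, `group`, `sex`,
#'   `age`; alternatively supply the four vectors.
#' @param metric,group,sex,age Numeric metric, binary group/sex (factor,
#'   logical, or 2-level character), numeric age.
#' @return One-row StatResult tibble (`estimate` = adjusted group effect).
#' @export
glm_adjusted_group_test <- function(data = NULL, metric, group, sex, age) {
  if (!is.null(data)) {
    metric <- data$metric; group <- data$group
    sex <- data$sex; age <- data$age
  }
  df <- data.frame(metric = metric, group = factor(group),
                   sex = factor(sex), age = age)
  if (nrow(df) < 6) abort_value("need n >= number of coefficients + 2.")
  fit <- stats::lm(metric ~ group + sex + age, data = df)
  if (fit$rank < 4) abort_design("rank-deficient design (collinear covariates).")
  co <- summary(fit)$coefficients
  grow <- grep("^group", rownames(co))[1]
  stat_result("glm_group_adjusted",
              contrast = paste(levels(df$group)[2], "vs", levels(df$group)[1]),
              statistic = co[grow, "t value"], df1 = fit$df.residual,
              p_value = co[grow, "Pr(>|t|)"], estimate = co[grow, "Estimate"],
              direction = sign(co[grow, "Estimate"]))
}

#' One-factor repeated-measures ANOVA
#'
#' Within-subject F = MS_condition / MS_(condition x subject) with degrees
#' of freedom (k - 1, (k - 1)(n - 1)); no sphericity correction by default
#' (Greenhouse-Geisser available via `gg = TRUE`).
#'
#' @param values Subjects-by-conditions numeric matrix/data frame
#'   (complete), or a long tibble with columns `subject`, `condition`,
#'   `value`.
#' @param gg Apply the Greenhouse-Geisser epsilon correction to the
#'   degrees of freedom and p-value.
#' @return An `rm_anova_fit` object; see [tidy()] / [glance()] methods.
#' @export
rm_anova <- function(values, gg = FALSE) {
  X <- rm_wide(values)
  n <- nrow(X); k <- ncol(X)
  if (n < 3) abort_value("repeated-measures ANOVA needs >= 3 subjects.")
  if (anyNA(X)) abort_value("the subject x condition table must be complete.")
  grand <- mean(X)
  cond_means <- colMeans(X)
  subj_means <- rowMeans(X)
  ss_total <- sum((X - grand)^2)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_err <- ss_total - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  Fstat <- if (ms_err > 0) ms_cond / ms_err else ifelse(ms_cond > 0, Inf, 0)
  eps <- 1
  if (gg) {
    S <- stats::cov(X)
    Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
    eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  }
  p <- stats::pf(Fstat, df1 * eps, df2 * eps, lower.tail = FALSE)
  structure(
    list(F = Fstat, df1 = df1 * eps, df2 = df2 * eps, p_value = p,
         epsilon = eps, ms_error = ms_err, n = n, k = k,
         cond_means = cond_means, conditions = colnames(X) %||%
           paste0("cond", seq_len(k)), wide = X),
    class = "rm_anova_fit")
}

rm_wide <- function(values) {
  if (is.data.frame(values) && all(c("subject", "condition", "value") %in% names(values))) {
    w <- tidyr::pivot_wider(values, id_cols = "subject",
                            names_from = "condition", values_from = "value")
    X <- as.matrix(w[, -1, drop = FALSE])
    rownames(X) <- as.character(w$subject)
    return(X)
  }
  as.matrix(values)
}

#' @export
print.rm_anova_fit <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%g, %g) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F, x$p_value))
  invisible(x)
}

#' @rdname rm_anova
#' @param x,... An `rm_anova_fit` and unused arguments.
#' @method tidy rm_anova_fit
#' @export
tidy.rm_anova_fit <- function(x, ...) {
  stat_result("rm_anova", contrast = paste(x$conditions, collapse = " | "),
              statistic = x$F, df1 = x$df1, df2 = x$df2, p_value = x$p_value)
}

#' @rdname rm_anova
#' @method glance rm_anova_fit
#' @export
glance.rm_anova_fit <- function(x, ...) {
  tibble(statistic = x$F, df1 = x$df1, df2 = x$df2, p_value = x$p_value,
         epsilon = x$epsilon, ms_error = x$ms_error, n_subjects = x$n,
         n_conditions = x$k)
}

#' Tukey-Kramer all-pairs post hoc comparisons
#'
#' Studentized-range q for every pair of conditions using the
#' repeated-measures ANOVA error mean square, with p-values from the
#' studentized range distribution on the ANOVA's error degrees of freedom.
#'
#' @param values Subjects-by-conditions table (as in [rm_anova()]) or an
#'   `rm_anova_fit`.
#' @param rm_result Optional pre-computed [rm_anova()] fit on the same
#'   table.
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble with one StatResult row per pair; `direction` is the
#'   sign of (first condition - second condition).
#' @export
tukey_kramer <- function(values, rm_result = NULL, alpha = 0.05) {
  fit <- if (inherits(values, "rm_anova_fit")) values
         else rm_result %||% rm_anova(values)
  k <- fit$k
  se <- sqrt(fit$ms_error / fit$n)
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    diff <- unname(fit$cond_means[i1] - fit$cond_means[i2])
    q <- abs(diff) / se
    p <- stats::ptukey(q, nmeans = k, df = fit$df2, lower.tail = FALSE)
    stat_result("tukey_kramer",
                contrast = paste(fit$conditions[i1], "-", fit$conditions[i2]),
                statistic = q, df1 = k, df2 = fit$df2, p_value = p,
                estimate = diff, direction = sign(diff))
  })
  res <- dplyr::bind_rows(out)
  res$significant <- res$p_value <= alpha
  res
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction (the convention used for the
#' demographics table), df = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return One-row StatResult tibble.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort_value("`table` must be 2x2.")
  if (any(table < 0) || any(table != round(table))) {
    abort_value("counts must be non-negative integers.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort_degenerate("2x2 table has a zero margin.")
  }
  ct <- stats::chisq.test(table, correct = FALSE)
  stat_result("chi_square", contrast = "2x2 association",
              statistic = unname(ct$statistic), df1 = 1,
              p_value = ct$p.value)
}

#' Pooled two-sample t-test from summary statistics
#'
#' For published mean +/- SD summaries: pooled-variance t with
#' n1 + n2 - 2 degrees of freedom, two-sided p.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return One-row StatResult tibble.
#' @export
two_sample_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (!(s1 > 0 && s2 > 0) || n1 < 2 || n2 < 2) {
    abort_value("SDs must be positive and both groups need n >= 2.")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  stat_result("two_sample_t_pooled", contrast = "group 1 vs group 2",
              statistic = t, df1 = df,
              p_value = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
              estimate = m1 - m2, direction = sign(m1 - m2))
}

#' Demographics comparison table
#'
#' Sex ratio by Pearson chi-square and age by pooled two-sample t, for a
#' cohort manifest with `group`, `sex` and `age_years` columns.
#'
#' @param manifest Cohort covariate tibble (see [cohort_manifest()]).
#' @return Tibble with one row per comparison.
#' @export
demographics_table <- function(manifest) {
  groups <- sort(unique(manifest$group))
  if (length(groups) != 2) abort_value("manifest must contain exactly 2 groups.")
  tab <- table(manifest$group, manifest$sex)
  sex_res <- chi_square_2x2(tab)
  a1 <- manifest$age_years[manifest$group == groups[1]]
  a2 <- manifest$age_years[manifest$group == groups[2]]
  age_res <- two_sample_t_from_summary(mean(a1), sd(a1), length(a1),
                                       mean(a2), sd(a2), length(a2))
  dplyr::bind_rows(
    dplyr::mutate(sex_res, variable = "sex", .before = 1),
    dplyr::mutate(age_res, variable = "age_years", .before = 1))
}
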