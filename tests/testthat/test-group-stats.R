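test_that("BH step-up matches the hand computation and controls the FDR", {
  out <- fdr_bh(c(0.01, 0.04, 0.03, 0.005))
  expect_equal(out$q_values, c(0.02, 0.04, 0.04, 0.02))
  expect_true(all(out$reject))

  flat <- fdr_bh(rep(0.01, 171))
  expect_true(all(flat$q_values == 0.01))
  expect_true(all(flat$reject))

  expect_error(fdr_bh(c(0.5, 1.2)), class = "jaenet_error_value")

  # full-null simulation: share of replicates with any false rejection ~ alpha
  any_rej <- withr::with_seed(11, vapply(1:1000, function(i)
    any(fdr_bh(runif(171))$reject), logical(1)))
  expect_lt(mean(any_rej), 0.05 + 2.6 * sqrt(0.05 * 0.95 / 1000))
})

test_that("edgewise two-sample comparison flags only truly shifted edges", {
  mk_group <- function(n, shift_edge = FALSE) {
    lapply(1:n, function(i) {
      W <- random_weight_matrix(8)
      if (shift_edge) W[1, 2] <- W[2, 1] <- W[1, 2] + 2
      W
    })
  }
  withr::with_seed(21, {
    a <- mk_group(18, shift_edge = TRUE)
    b <- mk_group(18)
  })
  res <- edgewise_two_sample_t(a, b)
  expect_equal(nrow(res), 28)
  shifted <- res[res$ch1 == "1" & res$ch2 == "2", ]
  expect_true(shifted$significant)
  expect_equal(shifted$direction, 1)
  expect_lte(mean(res$significant[-1]), 0.05)

  ident <- replicate(5, random_weight_matrix(6, seed = 1), simplify = FALSE)
  res0 <- edgewise_two_sample_t(ident, ident)
  expect_true(all(res0$statistic == 0))
  expect_false(any(res0$significant))

  expect_error(edgewise_two_sample_t(ident[1], ident),
               class = "jaenet_error_value")

  # Welch statistic equals the textbook formula on a printed 4+4 sample
  x <- c(0.52, 0.48, 0.55, 0.50)
  y <- c(0.40, 0.44, 0.38, 0.43)
  tw <- (mean(x) - mean(y)) / sqrt(var(x) / 4 + var(y) / 4)
  mk <- function(v) matrix(c(0, v, v, 0), 2)
  res <- edgewise_two_sample_t(lapply(x, mk), lapply(y, mk))
  expect_equal(res$statistic, tw, tolerance = 1e-10)
})

test_that("edgewise state ANOVA reduces to partitioned sums of squares", {
  # brute-force one-way ANOVA on a 3-group toy table
  g <- list(c(1.1, 0.9, 1.0), c(1.4, 1.6, 1.5), c(0.8, 1.0, 0.9))
  all_v <- unlist(g)
  grand <- mean(all_v)
  ss_b <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 1))
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  f_ref <- (ss_b / 2) / (ss_w / 6)
  mk <- function(v) matrix(c(0, v, v, 0), 2)
  states <- lapply(g, function(v) lapply(v, mk))
  names(states) <- c("a", "b", "c")
  res <- edgewise_state_anova(states)
  expect_equal(res$statistic, f_ref, tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)

  same <- list(a = states$a, b = states$a, c = states$a)
  expect_true(all(edgewise_state_anova(same)$statistic == 0))

  # shifted edges concentrate the detections
  withr::with_seed(31, {
    base <- replicate(3, lapply(1:12, function(i) random_weight_matrix(6)),
                      simplify = FALSE)
    ict <- lapply(1:12, function(i) {
      W <- random_weight_matrix(6)
      W[1, 2] <- W[2, 1] <- W[1, 2] + 2
      W[3, 4] <- W[4, 3] <- W[3, 4] + 2
      W
    })
  })
  st <- c(base, list(ict))
  names(st) <- c("inter", "pre", "post", "ictal")
  res <- edgewise_state_anova(st)
  hits <- res[res$significant, ]
  expect_true(all(paste(hits$ch1, hits$ch2) %in% c("1 2", "3 4")))
})

test_that("covariate-adjusted group test recovers effects and respects nulls", {
  withr::with_seed(41, {
    n <- 72
    grp <- rep(c("JAE", "HC"), each = n / 2)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    age <- runif(n, 6, 20)
    metric <- 1 * (grp == "JAE") + 0.02 * age + rnorm(n, sd = 0.1)
  })
  res <- glm_adjusted_group_test(metric = metric, group = grp,
                                 sex = sex, age = age)
  expect_equal(res$df1, n - 4)
  expect_gt(abs(res$estimate), 0.9)
  expect_lt(abs(res$estimate), 1.1)

  # metric that is exactly a function of age: adjusted group effect ~ 0
  res0 <- glm_adjusted_group_test(metric = 2 * age, group = grp,
                                  sex = sex, age = age)
  expect_lt(abs(res0$statistic), 1e-8)

  # coefficients equal the normal-equations solution on a 6-row design
  d6 <- data.frame(metric = c(1.2, 0.8, 1.5, 0.9, 1.1, 1.4),
                   group = c("a", "b", "a", "b", "a", "b"),
                   sex = c("m", "m", "f", "f", "m", "f"),
                   age = c(10, 12, 9, 15, 11, 13))
  X <- cbind(1, d6$group == "b", d6$sex == "m", d6$age)
  beta <- solve(t(X) %*% X, t(X) %*% d6$metric)
  res6 <- glm_adjusted_group_test(d6)
  expect_equal(res6$estimate, beta[2], tolerance = 1e-10)

  collinear <- data.frame(metric = rnorm(8), group = rep(c("a", "b"), 4),
                          sex = rep(c("m", "f"), 4), age = rep(1, 8))
  collinear$sex <- collinear$group  # sex duplicates group
  expect_error(glm_adjusted_group_test(collinear),
               class = "jaenet_error_design")
})

test_that("repeated-measures ANOVA equals brute-force partitioning and aov", {
  X <- matrix(c(5.1, 5.9, 7.0, 6.1,
                4.2, 5.0, 6.4, 5.0,
                6.0, 6.8, 7.7, 7.1), 3, 4, byrow = TRUE)
  colnames(X) <- paste0("c", 1:4)
  fit <- rm_anova(X)

  grand <- mean(X)
  ss_cond <- 3 * sum((colMeans(X) - grand)^2)
  ss_subj <- 4 * sum((rowMeans(X) - grand)^2)
  ss_err <- sum((X - grand)^2) - ss_cond - ss_subj
  f_ref <- (ss_cond / 3) / (ss_err / 6)
  expect_equal(fit$F, f_ref, tolerance = 1e-10)
  expect_equal(c(fit$df1, fit$df2), c(3, 6))

  # base-R aov with an Error() stratum as the independent cross-check
  long <- data.frame(y = as.vector(X),
                     subj = factor(rep(1:3, 4)),
                     cond = factor(rep(1:4, each = 3)))
  av <- summary(aov(y ~ cond + Error(subj / cond), data = long))
  f_aov <- av[["Error: subj:cond"]][[1]]["cond", "F value"]
  expect_equal(fit$F, f_aov, tolerance = 1e-8)

  # additive subject offsets do not change F
  fit2 <- rm_anova(X + c(10, -5, 3))
  expect_equal(fit2$F, fit$F, tolerance = 1e-10)

  # identical condition means per subject: F = 0
  flat <- matrix(rep(c(1, 2, 3), 4), 3, 4)
  expect_equal(rm_anova(flat)$F, 0)

  expect_error(rm_anova(X[1:2, ]), class = "jaenet_error_value")
  Xna <- X; Xna[2, 3] <- NA
  expect_error(rm_anova(Xna), class = "jaenet_error_value")

  # long-format input is equivalent
  fit_long <- rm_anova(data.frame(subject = rep(1:3, 4),
                                  condition = rep(colnames(X), each = 3),
                                  value = as.vector(X)))
  expect_equal(fit_long$F, fit$F, tolerance = 1e-12)

  td <- tidy(fit)
  expect_equal(td$statistic, fit$F)
  expect_equal(glance(fit)$n_subjects, 3)
})

test_that("Tukey-Kramer contrasts follow the studentized range", {
  withr::with_seed(51, {
    n <- 12
    base <- rnorm(n)
    X <- cbind(a = base + rnorm(n, sd = 0.3),
               b = base + rnorm(n, sd = 0.3),
               c = base + rnorm(n, sd = 0.3),
               d = base + 3 + rnorm(n, sd = 0.3))
  })
  fit <- rm_anova(X)
  tk <- tukey_kramer(fit)
  expect_equal(nrow(tk), 6)
  sig <- tk[tk$significant, ]
  expect_equal(sort(sig$contrast), sort(c("a - d", "b - d", "c - d")))

  # q equals the hand formula |m_i - m_j| / sqrt(MSE / n)
  q_ref <- abs(mean(X[, "a"]) - mean(X[, "d"])) / sqrt(fit$ms_error / n)
  expect_equal(tk$statistic[tk$contrast == "a - d"], q_ref, tolerance = 1e-10)
  p_ref <- ptukey(q_ref, 4, fit$df2, lower.tail = FALSE)
  expect_equal(tk$p_value[tk$contrast == "a - d"], p_ref, tolerance = 1e-12)

  # exactly equal condition means (noise retained): all pairwise p = 1
  flat <- withr::with_seed(52, {
    E <- matrix(rnorm(24, sd = 1), 6, 4)
    sweep(E, 2, colMeans(E)) + rnorm(6)
  })
  tk0 <- tukey_kramer(rm_anova(flat))
  expect_true(all(tk0$p_value > 0.999))
})

test_that("demographic tests reproduce their reference formulas", {
  chi <- chi_square_2x2(matrix(c(21, 22, 15, 14), 2))
  # brute-force sum over cells of (O - E)^2 / E
  tab <- matrix(c(21, 22, 15, 14), 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(chi$df1, 1)

  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)),
               class = "jaenet_error_degenerate")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)),
               class = "jaenet_error_value")

  tt <- two_sample_t_from_summary(1.2, 0.4, 3, 1.2, 0.5, 3)
  expect_equal(tt$statistic, 0)
  # hand formula on a 3+3 toy summary
  tt2 <- two_sample_t_from_summary(2.0, 0.5, 3, 1.0, 0.3, 3)
  sp2 <- (2 * 0.25 + 2 * 0.09) / 4
  expect_equal(tt2$statistic, 1 / sqrt(sp2 * (2 / 3)), tolerance = 1e-12)
  expect_error(two_sample_t_from_summary(1, 0, 3, 1, 1, 3),
               class = "jaenet_error_value")
})

test_that("the demographics table runs on a cohort manifest", {
  cfg <- cohort_config(n_jae = 36, n_hc = 36, rate_hz = 250,
                       epoch_plan = reduced_epoch_plan(), seed = 2)
  man <- cohort_manifest(jaenet:::cohort_subjects(cfg))
  dem <- demographics_table(man)
  expect_equal(nrow(dem), 2)
  expect_equal(dem$variable, c("sex", "age_years"))
  expect_true(all(dem$p_value >= 0 & dem$p_value <= 1))
})
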