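# End-to-end orchestration: generate -> preprocess -> PLV -> graph metrics
# -> statistics, deterministic under one master seed.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort.
#' @param bands Band table ([frequency_bands()]); analysis bands may be a
#'   subset of the bands the generator synthesises.
#' @param null_model A [null_model_config()] for the small-world index.
#' @param alpha Significance / FDR level for every test.
#' @param reduction `"metric"` (default): graph metrics are computed per
#'   epoch and averaged at the metric level; `"matrix"`: metrics of the
#'   entry-wise epoch-mean PLV matrix.
#' @param subgroup_axes Subset of `sex`, `age_13_split`,
#'   `discharge_pattern` along which patient ictal metrics are contrasted.
#' @param trim_fraction Hilbert edge trim for PLV estimation.
#' @param output_dir Optional directory; when set, every table is written
#'   as CSV along with a run log.
#' @param seed Master seed for the whole run.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            bands = frequency_bands(),
                            null_model = null_model_config(),
                            alpha = 0.05,
                            reduction = c("metric", "matrix"),
                            subgroup_axes = c("sex", "age_13_split",
                                              "discharge_pattern"),
                            trim_fraction = 0.1,
                            output_dir = NULL,
                            seed = 1L) {
  reduction <- match.arg(reduction)
  bad <- setdiff(subgroup_axes, c("sex", "age_13_split", "discharge_pattern"))
  if (length(bad) > 0) abort_value(paste0("unknown subgroup axis: ", bad[1]))
  if (nrow(bands) == 0) abort_value("`bands` must be non-empty.")
  structure(
    list(cohort = cohort, bands = bands, null_model = null_model,
         alpha = alpha, reduction = reduction, subgroup_axes = subgroup_axes,
         trim_fraction = trim_fraction, output_dir = output_dir,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the arguments of [pipeline_config()]
#' and [cohort_config()] (`n_jae`, `n_hc`, `rate_hz`, `bands`, `alpha`,
#' `n_surrogates`, `subgroup_axes`, `output_dir`, `seed`, ...); omitted
#' keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  bands <- if (!is.null(y$bands)) frequency_bands(unlist(y$bands)) else frequency_bands()
  cohort_args <- y[intersect(names(y), c("n_jae", "n_hc", "rate_hz", "k_local",
                                         "sigma_phi", "swd_amplitude_uv",
                                         "noise_spectrum_exponent",
                                         "noise_scale_uv"))]
  cohort_args$seed <- y$seed %||% 1L
  cohort <- do.call(cohort_config, cohort_args)
  null <- null_model_config(n_surrogates = y$n_surrogates %||% 100,
                            seed = (y$seed %||% 1L) + 7L)
  pipeline_config(
    cohort = cohort, bands = bands, null_model = null,
    alpha = y$alpha %||% 0.05,
    reduction = y$reduction %||% "metric",
    subgroup_axes = unlist(y$subgroup_axes %||%
                             c("sex", "age_13_split", "discharge_pattern")),
    trim_fraction = y$trim_fraction %||% 0.1,
    output_dir = y$output_dir, seed = y$seed %||% 1L)
}

subject_states <- function(group) {
  if (group == "JAE") c("inter_ictal", "pre_ictal", "ictal", "post_ictal")
  else "rest"
}

# Analyse one subject: returns per-state-band epoch-mean PLV matrices and
# a metrics table. The recording is generated, filtered 1-45 Hz,
# re-referenced and epoched here so that pipelines stream one subject at a
# time.
analyse_subject <- function(subject, config) {
  plan <- config$cohort$epoch_plan
  rec <- generate_subject_recording(subject, config$cohort, subject$seed)
  rec <- common_average_reference(bandpass_fir(rec, 1, 45))
  states <- subject_states(subject$group)
  mean_mats <- list()
  metric_rows <- list()
  null_seed_base <- subject$seed %% 1000000L
  for (state in states) {
    eps <- extract_epochs(rec, state, n_epochs = plan$n_epochs,
                          dur_s = plan$dur_s[[state]],
                          guard_s = plan$inter_ictal_guard_s)
    for (b in seq_len(nrow(config$bands))) {
      band <- config$bands[b, ]
      mats <- lapply(eps, function(ep) {
        bp <- bandpass_fir(ep, band$low_hz, band$high_hz)
        bp$band <- band$band
        plv_matrix(bp, trim_fraction = config$trim_fraction)
      })
      mmat <- average_plv(mats)
      mean_mats[[paste(state, band$band, sep = ".")]] <- mmat
      null <- null_model_config(config$null_model$n_surrogates,
                                seed = null_seed_base + 131L * b +
                                  17L * match(state, states))
      if (config$reduction == "metric") {
        per_epoch <- dplyr::bind_rows(lapply(mats, metrics_bundle, null = null))
        row <- per_epoch |>
          dplyr::summarise(dplyr::across(dplyr::all_of(metric_columns()), mean)) |>
          dplyr::mutate(subject_id = subject$subject_id, state = state,
                        band = band$band, epoch = "mean", .before = 1)
      } else {
        row <- metrics_bundle(mmat, null = null)
      }
      metric_rows[[length(metric_rows) + 1L]] <- row
    }
  }
  list(mean_matrices = mean_mats, metrics = dplyr::bind_rows(metric_rows))
}

subgroup_labels <- function(manifest, axis) {
  switch(axis,
    sex = manifest$sex,
    age_13_split = ifelse(manifest$age_years <= 13, "age_le_13", "age_gt_13"),
    discharge_pattern = manifest$discharge_pattern,
    abort_value(paste0("unknown subgroup axis: ", axis)))
}

#' Run the full analysis pipeline
#'
#' Generates (or streams) the synthetic cohort, preprocesses and epochs
#' every recording, builds per-band PLV networks, computes the five graph
#' metrics per subject/state/band, and runs the complete statistics block:
#' patient-inter-ictal vs control-rest (edgewise Welch t with FDR and
#' covariate-adjusted metric comparisons), the four-state within-patient
#' comparison (edgewise one-way ANOVA; repeated-measures ANOVA with
#' Tukey-Kramer per metric), subgroup contrasts on ictal metrics, and the
#' demographics table. Deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @param progress Print per-subject progress messages.
#' @return A `jaenet_report` list: `manifest`, `edges`, `metrics`,
#'   `stats` (named list of tibbles) and `log`.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  subjects <- cohort_subjects(config$cohort)
  states_jae <- c("inter_ictal", "pre_ictal", "ictal", "post_ictal")

  metrics <- list()
  edges <- list()
  group_mats <- list()  # [[band]][[state]][[subject]] mean matrices
  for (i in seq_len(nrow(subjects))) {
    subj <- subjects[i, ]
    if (progress) message(sprintf("[%d/%d] %s", i, nrow(subjects), subj$subject_id))
    res <- analyse_subject(subj, config)
    metrics[[i]] <- res$metrics
    for (key in names(res$mean_matrices)) {
      m <- res$mean_matrices[[key]]
      edges[[length(edges) + 1L]] <- tidy(m)
      group_mats[[m$band]][[m$state]][[subj$subject_id]] <- m
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  edges <- dplyr::bind_rows(edges)
  manifest <- cohort_manifest(subjects)
  alpha <- config$alpha

  stats_out <- list()
  ## patients (inter-ictal) vs controls (rest)
  ge <- list(); gm <- list()
  jae_ids <- subjects$subject_id[subjects$group == "JAE"]
  hc_ids <- subjects$subject_id[subjects$group == "HC"]
  for (b in config$bands$band) {
    res <- edgewise_two_sample_t(group_mats[[b]][["inter_ictal"]][jae_ids],
                                 group_mats[[b]][["rest"]][hc_ids],
                                 alpha = alpha)
    ge[[b]] <- dplyr::mutate(res, band = b, .before = 1)

    glm_band <- lapply(metric_columns(), function(mc) {
      dat <- metrics |>
        dplyr::filter(.data$band == b,
                      .data$state %in% c("inter_ictal", "rest")) |>
        dplyr::left_join(manifest, by = "subject_id")
      out <- glm_adjusted_group_test(
        data.frame(metric = dat[[mc]], group = dat$group,
                   sex = dat$sex, age = dat$age_years))
      dplyr::mutate(out, band = b, metric = mc, .before = 1)
    })
    glm_band <- dplyr::bind_rows(glm_band)
    adj <- fdr_bh(glm_band$p_value, alpha)
    glm_band$q_value <- adj$q_values
    glm_band$significant <- adj$reject
    gm[[b]] <- glm_band
  }
  stats_out$group_edgewise <- dplyr::bind_rows(ge)
  stats_out$group_metrics_glm <- dplyr::bind_rows(gm)

  ## four-state comparison within patients
  se <- list(); rm_rows <- list(); tukey_rows <- list()
  for (b in config$bands$band) {
    st_list <- lapply(states_jae, function(s) group_mats[[b]][[s]][jae_ids])
    names(st_list) <- states_jae
    se[[b]] <- dplyr::mutate(edgewise_state_anova(st_list, alpha = alpha),
                             band = b, .before = 1)
    for (mc in metric_columns()) {
      wide <- metrics |>
        dplyr::filter(.data$band == b, .data$state %in% states_jae) |>
        dplyr::select(dplyr::all_of(c("subject_id", "state", mc))) |>
        tidyr::pivot_wider(names_from = "state", values_from = dplyr::all_of(mc))
      X <- as.matrix(wide[, states_jae])
      fit <- rm_anova(X)
      rm_rows[[length(rm_rows) + 1L]] <-
        dplyr::mutate(tidy(fit), band = b, metric = mc, .before = 1)
      tukey_rows[[length(tukey_rows) + 1L]] <-
        dplyr::mutate(tukey_kramer(fit, alpha = alpha), band = b, metric = mc,
                      .before = 1)
    }
  }
  stats_out$state_edgewise <- dplyr::bind_rows(se)
  stats_out$state_rm_anova <- dplyr::bind_rows(rm_rows)
  stats_out$state_tukey <- dplyr::bind_rows(tukey_rows)

  ## subgroup contrasts on ictal metrics (patients only)
  sub_rows <- list()
  jae_manifest <- manifest[manifest$group == "JAE", ]
  ictal_metrics <- metrics |>
    dplyr::filter(.data$state == "ictal") |>
    dplyr::left_join(jae_manifest, by = "subject_id")
  for (axis in config$subgroup_axes) {
    lab <- subgroup_labels(ictal_metrics, axis)
    lv <- sort(unique(lab))
    if (length(lv) != 2) next
    n_per <- table(lab[ictal_metrics$band == config$bands$band[1]])
    if (min(n_per) < 2) {
      warn(sprintf("subgroup axis '%s' skipped: fewer than 2 patients on one side.",
                   axis))
      next
    }
    rows <- list()
    for (b in config$bands$band) {
      for (mc in metric_columns()) {
        sel <- ictal_metrics$band == b
        x1 <- ictal_metrics[[mc]][sel & lab == lv[1]]
        x2 <- ictal_metrics[[mc]][sel & lab == lv[2]]
        tt <- stats::t.test(x1, x2)
        rows[[length(rows) + 1L]] <- stat_result(
          "welch_t", contrast = paste(lv[1], "vs", lv[2]),
          statistic = unname(tt$statistic), df1 = unname(tt$parameter),
          p_value = tt$p.value, estimate = mean(x1) - mean(x2),
          direction = sign(mean(x1) - mean(x2))) |>
          dplyr::mutate(axis = axis, band = b, metric = mc, .before = 1)
      }
    }
    rows <- dplyr::bind_rows(rows)
    adj <- fdr_bh(rows$p_value, alpha)
    rows$q_value <- adj$q_values
    rows$significant <- adj$reject
    sub_rows[[axis]] <- rows
  }
  stats_out$subgroups <- dplyr::bind_rows(sub_rows)
  stats_out$demographics <- demographics_table(manifest)

  log <- tibble(
    config_hash = rlang::hash(config),
    seed = config$seed,
    n_subjects = nrow(subjects),
    n_bands = nrow(config$bands),
    reduction = config$reduction,
    timestamp = format(Sys.time(), tz = "UTC"))

  report <- structure(
    list(manifest = manifest, edges = edges, metrics = metrics,
         stats = stats_out, log = log, config = config),
    class = "jaenet_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.jaenet_report <- function(x, ...) {
  cat(sprintf("<jaenet_report> %d subjects, %d band(s); %d metric rows, %d edge rows\n",
              nrow(x$manifest), x$log$n_bands, nrow(x$metrics), nrow(x$edges)))
  cat("stats tables:", paste(names(x$stats), collapse = ", "), "\n")
  invisible(x)
}

# Write every table of a report as CSV plus a YAML run log.
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  }
  wr(report$manifest, "manifest")
  wr(report$edges, "plv_edges")
  wr(report$metrics, "graph_metrics")
  for (nm in names(report$stats)) wr(report$stats[[nm]], paste0("stats_", nm))
  log <- as.list(report$log)
  yaml::write_yaml(log, file.path(dir, "run_log.yaml"))
  invisible(dir)
}
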