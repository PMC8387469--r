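#' Load a pipeline configuration
#'
#' Configurations are YAML files with a top-level `seed`, an `out_dir`, a
#' `stages` block of toggles (`simulate`, `bouts`, `calcium`, `fos`,
#' `stats`), per-stage parameter blocks, and an `alpha`.  See
#' `system.file("extdata", "demo_config.yaml", package = "striatlearn")` for
#' a complete, commented example.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$alpha <- cfg$alpha %||% 0.05
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("`alpha` must be in (0,1)", call. = FALSE)
  cfg$stages <- utils::modifyList(
    list(simulate = FALSE, bouts = FALSE, calcium = FALSE,
         fos = FALSE, stats = FALSE),
    cfg$stages %||% list())
  if (cfg$stages$bouts && !cfg$stages$simulate && is.null(cfg$bouts$event_logs))
    stop("bouts stage enabled without simulate stage or bouts$event_logs paths",
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in order — simulate (behavioral sessions for
#' two groups), bouts (per-animal microstructure summaries and
#' magazine-entry correlations), calcium (trace simulation, dF/F, event
#' detection and a two-condition rate comparison), fos (cell-cloud
#' simulation, subregion binning, densities, z-scores, group contrast and
#' mutual-KNN clustering), stats (group comparison of the bout metrics) —
#' writing each stage's tables under `out_dir` together with a run log that
#' echoes the seed and parameters.  Two runs with an identical config
#' produce bit-identical outputs.
#'
#' @param config a [pipeline_config()] or a path to one.
#' @return (invisibly) a list of per-stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  out_dir <- cfg$out_dir %||% "results/pipeline"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("striatlearn pipeline run")
  logf("seed: %d", cfg$seed)
  logf("stages: %s", paste(names(Filter(isTRUE, cfg$stages)), collapse = ", "))
  bundle <- list(config = cfg)

  run_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  streams <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    bundle$simulate <- run_stage("simulate", {
      sc <- cfg$simulate %||% list()
      n <- sc$n_per_group %||% 6L
      groups <- sc$groups %||% list(
        trained = list(schedule = "FR1", criterion_rewards = 30,
                       session_cap = 7200, bout_rate = 1.2,
                       presses_per_bout_mean = 4, within_bout_iri_mean = 1.2,
                       solitary_rate = 0.4),
        yoked = list(schedule = "VT", criterion_rewards = 30,
                     session_cap = 7200, bout_rate = 0.15,
                     presses_per_bout_mean = 2.5, within_bout_iri_mean = 1.5,
                     solitary_rate = 0.3))
      streams <- list()
      for (g in names(groups)) {
        gp <- groups[[g]]
        sched <- schedule_config(gp$schedule, gp$criterion_rewards %||% 30,
                                 gp$session_cap %||% 7200)
        for (i in seq_len(n)) {
          id <- sprintf("%s_%02d", g, i)
          bp <- bout_process_params(
            bout_rate = gp$bout_rate, presses_per_bout_mean =
              gp$presses_per_bout_mean %||% 4,
            within_bout_iri_mean = gp$within_bout_iri_mean %||% 1,
            solitary_rate = gp$solitary_rate %||% 0,
            duration = sched$session_cap,
            seed = child_seed(cfg$seed, paste0("press-", id)))
          streams[[id]] <- simulate_operant_session(
            sched, bp, subject_id = id, group = g,
            seed = child_seed(cfg$seed, paste0("sched-", id)))
          write_event_log(streams[[id]],
                          file.path(out_dir, paste0("events_", id, ".tsv")))
        }
      }
      logf("simulate: %d sessions written", length(streams))
      names(streams)
    })
  }

  if (isTRUE(cfg$stages$bouts)) {
    bundle$bouts <- run_stage("bouts", {
      bc <- cfg$bouts %||% list()
      cfg_b <- bout_config(epoch_width = bc$epoch_width %||% 5,
                           gap_threshold = bc$gap_threshold %||% 5)
      if (is.null(streams)) {
        streams <- lapply(bc$event_logs, read_event_log)
        names(streams) <- vapply(streams, function(s)
          s$events$subject_id[1], "")
      }
      sums <- lapply(streams, summarize_session, cfg = cfg_b)
      tab <- data.frame(
        subject_id = names(sums),
        group = vapply(streams, function(s) s$events$group[1], ""),
        n_presses = vapply(sums, `[[`, 1, "n_presses"),
        bout_frequency = vapply(sums, `[[`, 1, "bout_frequency"),
        bout_density = vapply(sums, `[[`, 1, "bout_density"),
        n_solitary = vapply(sums, `[[`, 1, "n_solitary"),
        n_magazine = vapply(sums, `[[`, 1, "n_magazine"),
        row.names = NULL)
      utils::write.table(tab, file.path(out_dir, "bout_summaries.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      corr <- if (length(sums) >= 3) correlate_bout_magazine(sums) else NULL
      if (!is.null(corr))
        utils::write.table(corr, file.path(out_dir, "bout_magazine_correlation.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      logf("bouts: %d sessions summarized", nrow(tab))
      list(summaries = sums, table = tab, correlation = corr)
    })
  }

  if (isTRUE(cfg$stages$calcium)) {
    bundle$calcium <- run_stage("calcium", {
      cc <- cfg$calcium %||% list()
      conds <- cc$conditions %||% list(post_magazine = 1.5, post_acquisition = 3.5)
      n_rois <- cc$n_rois %||% 25L
      dur <- cc$duration %||% 300
      det <- event_detect_config(k_sigma = cc$k_sigma %||% 3)
      rates <- list()
      for (cond in names(conds)) {
        sim <- simulate_calcium_traces(calcium_sim_params(
          duration = dur, event_rate = conds[[cond]], n_rois = n_rois,
          seed = child_seed(cfg$seed, paste0("ca-", cond))))
        dff <- delta_f_over_f(sim$traces)
        rates[[cond]] <- vapply(seq_len(n_rois), function(r) {
          ev <- detect_events(dff[, r], sim$sampling_rate, det)
          events_per_minute(ev, dur)$events_per_minute
        }, 1)
      }
      tab <- do.call(rbind, lapply(names(rates), function(cond)
        data.frame(condition = cond, roi = seq_along(rates[[cond]]),
                   events_per_minute = rates[[cond]])))
      utils::write.table(tab, file.path(out_dir, "calcium_event_rates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tt <- compare_event_rates(rates[[1]], rates[[2]])
      logf("calcium: %d ROIs x %d conditions; t=%.3f p=%.4g",
           n_rois, length(rates), unname(tt$statistic), tt$p.value)
      list(rates = rates, table = tab, test = tt)
    })
  }

  if (isTRUE(cfg$stages$fos)) {
    bundle$fos <- run_stage("fos", {
      fc <- cfg$fos %||% list()
      # single-hemisphere synthetic striatal frame: x = |ML|, y = AP, z = DV (um)
      bounds <- matrix(c(1000, 3000, 0, 2000, 0, 2000), 3, 2, byrow = TRUE)
      scheme <- subregion_scheme(ap_boundary = 1000, ml_boundary = 2000,
                                 striatal_bounds = bounds)
      part <- list(
        pDMS = matrix(c(1000, 2000, 0, 1000, 0, 2000), 3, 2, byrow = TRUE),
        pDLS = matrix(c(2000, 3000, 0, 1000, 0, 2000), 3, 2, byrow = TRUE),
        aDMS = matrix(c(1000, 2000, 1000, 2000, 0, 2000), 3, 2, byrow = TRUE),
        aDLS = matrix(c(2000, 3000, 1000, 2000, 0, 2000), 3, 2, byrow = TRUE))
      vols <- vapply(part, function(b) prod(b[, 2] - b[, 1]) / 1e9, 1)
      default_rates <- list(aDLS = list(trained = 9000, yoked = 5000),
                            aDMS = list(trained = 5000, yoked = 5000),
                            pDMS = list(trained = 8000, yoked = 5000),
                            pDLS = list(trained = 5000, yoked = 5000))
      rates <- fc$rates %||% default_rates
      rate_mat <- do.call(rbind, lapply(rates, unlist))
      rownames(rate_mat) <- names(rates)
      sim <- simulate_cell_cloud(cloud_sim_params(
        bounding_box = bounds, region_partition = part[rownames(rate_mat)],
        per_region_rate = rate_mat,
        n_animals_per_group = fc$n_animals_per_group %||% 5L,
        seed = child_seed(cfg$seed, "fos")))
      labeled <- lapply(sim$clouds, assign_subregions, scheme = scheme)
      groups <- colnames(rate_mat)
      dm <- density_matrix(labeled, volumes = vols[scheme$region_labels])
      write_density_matrix(dm, file.path(out_dir, "fos_densities.tsv"))
      z <- zscore_densities(dm)
      write_density_matrix(z, file.path(out_dir, "fos_densities_zscored.tsv"))
      gl <- attr(dm, "groups")
      sub_mat <- function(g) {
        m <- unclass(dm)[, gl == g, drop = FALSE]
        structure(m, groups = gl[gl == g], zscored = FALSE,
                  class = class(dm))
      }
      contrast <- group_density_difference(sub_mat(groups[1]), sub_mat(groups[2]),
                                           alpha = cfg$alpha)
      utils::write.table(contrast$anova, file.path(out_dir, "fos_anova.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(contrast$contrasts))
        utils::write.table(contrast$contrasts,
                           file.path(out_dir, "fos_contrasts.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      k <- fc$k %||% 2L
      clust <- region_knn_clusters(dm, k = min(k, nrow(dm) - 1L),
                                   seed = child_seed(cfg$seed, "tsne"))
      clust_tab <- data.frame(region = names(clust$clusters),
                              cluster = as.integer(clust$clusters),
                              dim1 = clust$embedding[, 1],
                              dim2 = clust$embedding[, 2], row.names = NULL)
      utils::write.table(clust_tab, file.path(out_dir, "fos_clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      logf("fos: %d animals, interaction p=%.4g, gated=%s",
           length(labeled), contrast$anova$p[3], contrast$gated)
      list(densities = dm, zscored = z, contrast = contrast, clusters = clust)
    })
  }

  if (isTRUE(cfg$stages$stats)) {
    bundle$stats <- run_stage("stats", {
      if (is.null(bundle$bouts)) {
        logf("stats: no bout table available; nothing to compare")
        NULL
      } else {
        tab <- bundle$bouts$table
        cmp <- group_compare(
          data.frame(value = tab$bout_frequency, group = tab$group),
          design = if (length(unique(tab$group)) == 2L) "t" else "one_way",
          alpha = cfg$alpha)
        out <- data.frame(outcome = "bout_frequency", design = cmp$design,
                          statistic = cmp$statistic, p = cmp$p)
        utils::write.table(out, file.path(out_dir, "stats_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        logf("stats: bout_frequency %s-test p=%.4g", cmp$design, cmp$p)
        cmp
      }
    })
  }

  logf("done")
  invisible(bundle)
}
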