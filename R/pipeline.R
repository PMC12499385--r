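# End-to-end analyses tying the stages together: real-time remodeling
# of homogeneous GUVs, domain stabilization by actin, domain-number
# versus network structure, and the plain simulator run.

#' Pipeline run configuration
#'
#' Gathers every tunable the analyses use, so each output artifact can
#' echo the exact settings (and seed) that produced it.
#'
#' @param output_dir Directory for result files (created if needed).
#' @param seed Integer seed controlling every random stage.
#' @param pixel_size_um Pixel size for synthetic rendering.
#' @param ld_threshold Ld-domain calling threshold (default 0.2).
#' @param edge_k Actin outer-edge threshold multiplier (default 3).
#' @param a_sym,r_comet Structure classification thresholds.
#' @param params [physical_params()] for simulation-driven analyses.
#' @param n_guvs Cohort size for the homogeneous analysis.
#' @param n_reps Replicates per condition for the stabilization
#'   analysis.
#' @param lapse_paths Optional character vector of TIFF paths to analyze
#'   instead of synthesizing data.
#' @return Object of class `run_config`.
#' @export
run_config <- function(output_dir = tempfile("guvactin_run_"),
                       seed = 1,
                       pixel_size_um = 0.3,
                       ld_threshold = 0.2,
                       edge_k = 3,
                       a_sym = 0.3,
                       r_comet = 1.5,
                       params = physical_params(),
                       n_guvs = 3,
                       n_reps = 3,
                       lapse_paths = NULL) {
  if (ld_threshold <= 0 || ld_threshold >= 1) {
    stop_validation("ld_threshold must be in (0, 1)")
  }
  if (edge_k <= 0 || a_sym <= 0 || a_sym >= 1 || r_comet <= 1) {
    stop_validation("invalid threshold configuration")
  }
  structure(
    list(output_dir = output_dir, seed = seed,
         pixel_size_um = pixel_size_um, ld_threshold = ld_threshold,
         edge_k = edge_k, a_sym = a_sym, r_comet = r_comet,
         params = params, n_guvs = n_guvs, n_reps = n_reps,
         lapse_paths = lapse_paths),
    class = "run_config"
  )
}

#' @noRd
.config_header <- function(config) {
  c(sprintf("# guvactin %s", as.character(utils::packageVersion("guvactin"))),
    sprintf("# seed=%s ld_threshold=%g edge_k=%g a_sym=%g r_comet=%g pixel_size_um=%g",
            config$seed, config$ld_threshold, config$edge_k, config$a_sym,
            config$r_comet, config$pixel_size_um))
}

#' @noRd
.write_csv_with_header <- function(df, path, config) {
  con <- file(path, "w")
  writeLines(.config_header(config), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Read a pipeline CSV, skipping the configuration header
#'
#' @param path CSV written by [run_pipeline()].
#' @return data.frame.
#' @export
read_pipeline_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' @noRd
.save_plot <- function(p, path) {
  tryCatch(
    suppressMessages(ggplot2::ggsave(path, p, width = 6, height = 4,
                                     dpi = 120)),
    error = function(e) {
      warning("could not save plot ", path, ": ", conditionMessage(e),
              call. = FALSE)
    })
  invisible(NULL)
}

#' Run a full analysis pipeline
#'
#' Deterministic given the config seed.  Analyses:
#'
#' * `"homogeneous"`: a cohort of homogeneous GUVs with growing actin
#'   shells (13 frames over 60 min); per-GUV morphometry and fitted
#'   growth rates.
#' * `"stabilization"`: diffusion-coalescence simulations for the
#'   bare / spvca / actin conditions, rendered to synthetic lapses,
#'   re-measured by radial profiling, and summarized as domain-count
#'   trajectories with N10/N0 and N60/N0 ratios and Mann-Whitney
#'   condition contrasts.
#' * `"nd_structure"`: phase-separated GUVs spanning the three initial
#'   domain-number categories; actin-on-Ld scores per category with
#'   Welch's t-test contrasts.
#' * `"simulate"`: one simulation per mode; count time series and merge
#'   event logs.
#'
#' Failures on individual GUVs are logged and skipped; the pipeline
#' continues over the remaining GUVs.
#'
#' @param config A [run_config()].
#' @param analysis One of `"homogeneous"`, `"stabilization"`,
#'   `"nd_structure"`, `"simulate"`.
#' @return Invisibly, a list of result data.frames (also written as
#'   CSV/JSON under `config$output_dir`).
#' @export
run_pipeline <- function(config = run_config(),
                         analysis = c("homogeneous", "stabilization",
                                      "nd_structure", "simulate")) {
  analysis <- match.arg(analysis)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run_log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    writeLines(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                       sprintf(...)), log_con)
  }
  logmsg("analysis=%s seed=%s R=%s guvactin=%s", analysis, config$seed,
         as.character(getRversion()),
         as.character(utils::packageVersion("guvactin")))
  set.seed(as.integer(config$seed))
  res <- switch(analysis,
    homogeneous = .run_homogeneous(config, logmsg),
    stabilization = .run_stabilization(config, logmsg),
    nd_structure = .run_nd_structure(config, logmsg),
    simulate = .run_simulate(config, logmsg)
  )
  logmsg("done")
  invisible(res)
}

#' @noRd
.run_homogeneous <- function(config, logmsg) {
  n <- config$n_guvs
  set.seed(as.integer(config$seed))
  diam <- stats::runif(n, 15, 30)
  rates <- stats::runif(n, 0.1, 0.3)
  times <- seq(0, 60, length.out = 13)
  records <- list()
  fits <- list()
  for (g in seq_len(n)) {
    spec <- synth_spec(
      guv_diameter_um = diam[g], pixel_size_um = config$pixel_size_um,
      actin_structure = "symmetric_shell", actin_thickness_um = 0.5,
      shot_noise = TRUE, gaussian_noise_sigma = 1,
      seed = config$seed * 1000 + g)
    lp <- suppressMessages(
      render_time_lapse(spec, times, growth_rate_um_per_min = rates[g]))
    th <- rep(NA_real_, length(times))
    rec0 <- NULL
    for (k in seq_along(times)) {
      ok <- tryCatch({
        rec <- morphometry_record(lp$frames[[k]],
                                  pixel_size_um = lp$pixel_size_um,
                                  a_sym = config$a_sym,
                                  r_comet = config$r_comet,
                                  k = config$edge_k)
        th[k] <- rec$actin_thickness_um
        if (k == length(times)) rec0 <- rec
        TRUE
      }, error = function(e) {
        logmsg("GUV %d frame %d failed: %s", g, k, conditionMessage(e))
        FALSE
      })
    }
    if (is.null(rec0)) next
    rec0$guv <- g
    rec0$true_diameter_um <- diam[g]
    records[[length(records) + 1L]] <- rec0
    usable <- !is.na(th)
    if (sum(usable) >= 3) {
      fits[[length(fits) + 1L]] <- data.frame(
        guv = g, programmed_rate_um_per_min = rates[g],
        fitted_rate_um_per_min = fit_growth_rate(times[usable], th[usable]))
    }
  }
  morph <- do.call(rbind, records)
  growth <- do.call(rbind, fits)
  .write_csv_with_header(morph,
    file.path(config$output_dir, "morphometry.csv"), config)
  .write_csv_with_header(growth,
    file.path(config$output_dir, "growth_rates.csv"), config)
  p <- ggplot2::ggplot(growth,
         ggplot2::aes(x = programmed_rate_um_per_min,
                      y = fitted_rate_um_per_min)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "programmed rate (um/min)", y = "fitted rate (um/min)")
  .save_plot(p, file.path(config$output_dir, "growth_rates.png"))
  list(morphometry = morph, growth_rates = growth)
}

# Count Ld domains on every frame of a lapse via the profiling chain.
#' @noRd
.count_domains_lapse <- function(lapse, config, logmsg = function(...) NULL) {
  counts <- rep(NA_real_, length(lapse$frames))
  for (k in seq_along(lapse$frames)) {
    counts[k] <- tryCatch({
      fr <- lapse$frames[[k]]
      contour <- segment_guv_contour(fr, pixel_size_um = lapse$pixel_size_um)
      prof <- radial_profiles(fr, contour = contour)
      prof <- normalize_profiles(prof)
      dom <- segment_ld_domains(prof, threshold = config$ld_threshold,
                                pixel_size_um = lapse$pixel_size_um)
      dom$n_d
    }, error = function(e) {
      logmsg("frame %d domain counting failed: %s", k, conditionMessage(e))
      NA_real_
    })
  }
  counts
}

#' @noRd
.run_stabilization <- function(config, logmsg) {
  times_min <- c(0, 5, 10, 20, 30, 45, 60)
  r_guv <- 12e-6
  template <- synth_spec(guv_diameter_um = 2 * r_guv * 1e6,
                         pixel_size_um = config$pixel_size_um,
                         n_domains = 2)   # arcs replaced per frame
  trajs <- list()
  for (mode in c("bare", "spvca", "actin")) {
    for (rep in seq_len(config$n_reps)) {
      seed <- config$seed * 100 + rep +
        match(mode, c("bare", "spvca", "actin")) * 10
      set.seed(seed)
      n0 <- sample(c(8:12, 32:36), 1)
      tr <- simulate_domains(n0, r_guv, config$params, mode = mode,
                             t_end = max(times_min) * 60, dt = 0.25,
                             seed = seed, record_arcs = TRUE,
                             sample_times = times_min * 60)
      lp <- suppressMessages(lapse_from_simulation(tr, template, times_min))
      counts <- .count_domains_lapse(lp, config, logmsg)
      ok <- !is.na(counts)
      if (sum(ok) < 2) {
        logmsg("%s rep %d: too few measurable frames, skipped", mode, rep)
        next
      }
      trajs[[length(trajs) + 1L]] <- suppressWarnings(
        build_trajectory(counts[ok], times_min[ok], condition = mode))
    }
  }
  tab <- trajectory_table(trajs)
  .write_csv_with_header(tab,
    file.path(config$output_dir, "trajectories.csv"), config)
  # condition contrasts on ratio_60 (Mann-Whitney, independent samples)
  tests <- list()
  conds <- split(tab$ratio_60, tab$condition)
  pairs <- utils::combn(names(conds), 2, simplify = FALSE)
  for (pr in pairs) {
    a <- conds[[pr[1]]]; b <- conds[[pr[2]]]
    if (length(a) >= 3 && length(b) >= 3) {
      cmp <- compare_groups(a, b, design = "independent", labels = pr)
      tests[[paste(pr, collapse = "_vs_")]] <- list(
        test = cmp$test, statistic = cmp$statistic, p_value = cmp$p_value,
        tier = cmp$tier)
    }
  }
  jsonlite::write_json(tests,
    file.path(config$output_dir, "stabilization_tests.json"),
    auto_unbox = TRUE, digits = NA)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = condition, y = ratio_60)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = "domain number ratio N60/N0")
  .save_plot(p, file.path(config$output_dir, "domain_ratio.png"))
  list(trajectories = tab, tests = tests)
}

#' @noRd
.run_nd_structure <- function(config, logmsg) {
  # three categories of initial domain number; actin denser (brighter,
  # more confined) for few-domain GUVs, dimmer and more uniform for many
  set.seed(as.integer(config$seed) + 17L)
  nd_values <- c(2, 2, 2, 4, 6, 8, 12, 16, 24)
  rows <- list()
  for (i in seq_along(nd_values)) {
    nd <- nd_values[i]
    actin_int <- if (nd <= 10) 80 else 40
    spec <- synth_spec(
      guv_diameter_um = 30, pixel_size_um = config$pixel_size_um,
      n_domains = nd,
      actin_structure = "symmetric_shell", actin_thickness_um = 2,
      actin_intensity = actin_int, actin_on_ld_only = nd <= 10,
      shot_noise = TRUE, seed = config$seed * 50 + i)
    lp <- render_guv_frame(spec)
    row <- tryCatch({
      fr <- lp$frames[[1]]
      contour <- segment_guv_contour(fr, pixel_size_um = lp$pixel_size_um)
      prof <- normalize_profiles(radial_profiles(fr, contour = contour))
      dom <- segment_ld_domains(prof, threshold = config$ld_threshold,
                                pixel_size_um = lp$pixel_size_um)
      data.frame(guv = i, nd_true = nd, nd_measured = dom$n_d,
                 actin_on_ld = actin_on_ld(prof, dom))
    }, error = function(e) {
      logmsg("GUV %d (nd=%d) failed: %s", i, nd, conditionMessage(e))
      NULL
    })
    rows[[length(rows) + 1L]] <- row
  }
  tab <- do.call(rbind, rows)
  tab$category <- ifelse(tab$nd_true <= 2, "nd_eq_2",
                         ifelse(tab$nd_true <= 10, "nd_3_10", "nd_gt_10"))
  .write_csv_with_header(tab,
    file.path(config$output_dir, "actin_on_ld.csv"), config)
  tests <- list()
  grp <- split(tab$actin_on_ld, tab$category)
  for (pr in utils::combn(names(grp), 2, simplify = FALSE)) {
    if (length(grp[[pr[1]]]) >= 3 && length(grp[[pr[2]]]) >= 3) {
      cmp <- compare_groups(grp[[pr[1]]], grp[[pr[2]]],
                            design = "independent",
                            normality_assumed = TRUE, labels = pr)
      tests[[paste(pr, collapse = "_vs_")]] <- list(
        test = cmp$test, statistic = cmp$statistic, p_value = cmp$p_value,
        tier = cmp$tier)
    }
  }
  jsonlite::write_json(tests,
    file.path(config$output_dir, "nd_structure_tests.json"),
    auto_unbox = TRUE, digits = NA)
  list(actin_on_ld = tab, tests = tests)
}

#' @noRd
.run_simulate <- function(config, logmsg) {
  out <- list()
  for (mode in c("bare", "spvca", "actin")) {
    tr <- simulate_domains(20, 12e-6, config$params, mode = mode,
                           t_end = 600, dt = 0.25,
                           seed = config$seed + match(mode,
                             c("bare", "spvca", "actin")))
    df <- data.frame(mode = mode, time_s = tr$times_s,
                     n_total = tr$n_total, n_equatorial = tr$n_equatorial)
    out[[mode]] <- df
    jsonlite::write_json(tr$events,
      file.path(config$output_dir, paste0("events_", mode, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  counts <- do.call(rbind, out)
  .write_csv_with_header(counts,
    file.path(config$output_dir, "sim_counts.csv"), config)
  p <- ggplot2::ggplot(counts,
         ggplot2::aes(x = time_s / 60, y = n_total, color = mode)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (min)", y = "domain count")
  .save_plot(p, file.path(config$output_dir, "sim_counts.png"))
  list(sim_counts = counts)
}
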