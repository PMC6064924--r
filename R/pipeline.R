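# End-to-end orchestration: two-group statistics on subject-level regional
# metric summaries, config-driven runs, and run manifests.

#' Welch two-sample comparison of subject-level metric values
#'
#' Welch's unequal-variance t test on two groups of subject-level values
#' (one value per subject, e.g. a regional TAWSS mean). Reports the test
#' statistic, Welch degrees of freedom, two-sided p-value and group means
#' with standard errors. With fewer than 2 subjects in either group the
#' comparison is flagged not-available (`available = FALSE`, statistics
#' `NA`).
#'
#' @param values_a,values_b Numeric vectors of subject-level values.
#' @param metric,region Labels carried into the output row.
#' @param group_names Length-2 character vector of group names.
#' @return One-row data frame with columns `metric`, `region`, group means,
#'   SEMs and ns, `t`, `df`, `p_value`, `available`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_groups <- function(values_a, values_b, metric = "value", region = "all",
                           group_names = c("A", "B")) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  na <- length(values_a); nb <- length(values_b)
  sem <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))
  row <- data.frame(metric = metric, region = region,
                    mean_a = if (na) mean(values_a) else NA_real_,
                    sem_a = sem(values_a), n_a = na,
                    mean_b = if (nb) mean(values_b) else NA_real_,
                    sem_b = sem(values_b), n_b = nb,
                    t = NA_real_, df = NA_real_, p_value = NA_real_,
                    available = FALSE, stringsAsFactors = FALSE)
  names(row)[c(3:5, 6:8)] <- c(paste0(c("mean_", "sem_", "n_"), group_names[1L]),
                               paste0(c("mean_", "sem_", "n_"), group_names[2L]))
  if (na < 2L || nb < 2L) return(row)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    # degenerate zero-variance groups: no test possible
    if (isTRUE(all.equal(mean(values_a), mean(values_b)))) {
      row$t <- 0; row$df <- na + nb - 2; row$p_value <- 1; row$available <- TRUE
    }
    return(row)
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  row$t <- unname(tt$statistic)
  row$df <- unname(tt$parameter)
  row$p_value <- tt$p.value
  row$available <- TRUE
  row
}

#' Group comparison of cohort summaries across metrics and regions
#'
#' Applies [compare_groups()] to every metric x region cell of a
#' [cohort_summaries()] table, with Holm correction of the p-values across
#' regions within each metric.
#'
#' @param summaries Data frame from [cohort_summaries()].
#' @param metric_cols Metric columns to test.
#' @param adjust Multiplicity adjustment method across regions
#'   (see [stats::p.adjust()]; default `"holm"`).
#' @return Data frame with one row per metric x region, including
#'   `p_adjusted`.
#' @export
compare_cohort <- function(summaries,
                           metric_cols = c("tawss_pa", "osi", "transwss_pa"),
                           adjust = "holm") {
  stopifnot(all(c("group", "region") %in% names(summaries)))
  groups <- unique(summaries$group)
  if (length(groups) != 2L)
    stop("cohort summaries must contain exactly 2 groups", call. = FALSE)
  out <- list()
  for (mc in intersect(metric_cols, names(summaries))) {
    rows <- lapply(unique(summaries$region), function(r) {
      a <- summaries[summaries$group == groups[1L] & summaries$region == r, mc]
      b <- summaries[summaries$group == groups[2L] & summaries$region == r, mc]
      compare_groups(a, b, metric = mc, region = r, group_names = groups)
    })
    tab <- do.call(rbind, rows)
    tab$p_adjusted <- NA_real_
    ok <- tab$available
    tab$p_adjusted[ok] <- stats::p.adjust(tab$p_value[ok], method = adjust)
    out[[mc]] <- tab
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# --- run configuration ------------------------------------------------------

config_schema <- list(
  top = c("mode", "seed", "output", "waveform", "cohort", "solver", "metrics"),
  output = c("dir"),
  waveform = c("period_s", "peak_m_s", "n_segments"),
  cohort = c("n_subjects", "n_points", "n_times", "subject_sdlog",
             "oscillatory_frac", "transverse_frac", "noise_sd", "point_sdlog",
             "region_means", "groups"),
  solver = c("length_m", "height_m", "grid_nx", "grid_ny", "n_ostia",
             "ostium_width_m", "n_cycles", "steps_per_cycle", "main_split_raw",
             "ostium_split_raw"),
  metrics = c("region_halfwidth"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown config key(s) in %s: %s", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
}

#' Validate and normalize a run configuration
#'
#' Accepts a config list or a YAML file path; rejects unknown keys and
#' fills defaults. `mode` is `"synthetic"` (generate a cohort and compare
#' groups) or `"solver"` (run the channel solver and summarize wall
#' metrics).
#'
#' @param config A named list or path to a YAML file.
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  check_keys(config, config_schema$top, "top level")
  if (is.null(config$mode) || !config$mode %in% c("synthetic", "solver"))
    stop("config `mode` must be 'synthetic' or 'solver'", call. = FALSE)
  for (sec in c("output", "waveform", "cohort", "solver", "metrics"))
    if (!is.null(config[[sec]]))
      check_keys(config[[sec]], config_schema[[sec]], sec)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$output$dir))
    stop("config must give `output: dir:`", call. = FALSE)
  structure(config, class = "run_config")
}

write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  path
}

#' Execute a configured pipeline run
#'
#' Runs the configured mode end to end and writes its outputs under the
#' configured directory: per-point metric tables, per-region summaries,
#' group comparisons (synthetic mode), the wall shear series (solver mode),
#' and a `manifest.json` recording the full config, seed and package
#' version so the run can be reproduced exactly. Rerunning the same config
#' and seed yields byte-identical tables.
#'
#' @param config A [run_config()], config list, or YAML path.
#' @return Invisibly, a list with the output file paths and the in-memory
#'   result tables.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()

  if (cfg$mode == "synthetic") {
    co <- cfg$cohort
    fs_args <- co[intersect(names(co), c("n_points", "n_times", "oscillatory_frac",
                                         "transverse_frac", "noise_sd",
                                         "point_sdlog", "region_means"))]
    if (!is.null(fs_args$region_means)) fs_args$region_means <- unlist(fs_args$region_means)
    field <- do.call(synthetic_field_spec, c(fs_args, list(seed = cfg$seed)))
    cs_args <- list(field = field, base_seed = cfg$seed)
    if (!is.null(co$n_subjects)) cs_args$n_subjects <- co$n_subjects
    if (!is.null(co$subject_sdlog)) cs_args$subject_sdlog <- co$subject_sdlog
    if (!is.null(co$groups)) cs_args$groups <- co$groups
    cspec <- do.call(cohort_spec, cs_args)
    cohort <- generate_cohort(cspec)
    summ <- cohort_summaries(cohort)
    per_point <- do.call(rbind, lapply(cohort, function(s)
      data.frame(subject = s$subject, group = s$group,
                 compute_metrics(s$records), stringsAsFactors = FALSE)))
    comp <- if (all(table(summ$group) >= 2L)) compare_cohort(summ) else {
      warning("fewer than 2 subjects per group: comparison not available")
      NULL
    }
    outputs$per_point <- write_table(per_point, cfg$output$dir, "metrics_points.csv")
    outputs$summaries <- write_table(summ, cfg$output$dir, "summaries_subjects.csv")
    if (!is.null(comp))
      outputs$comparisons <- write_table(comp, cfg$output$dir, "comparisons.csv")
    result <- list(summaries = summ, comparisons = comp, per_point = per_point)
  } else {
    sv <- cfg$solver
    getd <- function(x, d) if (is.null(x)) d else x
    L <- getd(sv$length_m, 0.019); h <- getd(sv$height_m, 0.00158)
    n_ost <- getd(sv$n_ostia, 12L)
    geo <- build_channel(L, h, getd(sv$grid_nx, 60L), getd(sv$grid_ny, 40L),
                         if (n_ost > 0L) default_ostia(L, getd(sv$ostium_width_m, L / 60)))
    props <- fluid_properties()
    wf <- cfg$waveform
    sw <- default_mouse_waveform(getd(wf$period_s, 0.1), getd(wf$peak_m_s, 1.0))
    inlet <- fit_bezier_waveform(sw, getd(wf$n_segments, 10L))
    splits <- default_outlet_split(geo, getd(sv$main_split_raw, 0.698),
                                   getd(sv$ostium_split_raw, 0.0014))
    rec <- run_cycles(geo, props, inlet, splits,
                      n_cycles = getd(sv$n_cycles, 3L),
                      steps_per_cycle = getd(sv$steps_per_cycle, 1000L),
                      region_halfwidth = getd(cfg$metrics$region_halfwidth, 1.5))
    met <- compute_metrics(rec)
    summ <- summarize_regions(met)
    outputs$wss <- write_wss_csv(rec, file.path(cfg$output$dir, "wss_wall.csv"))
    outputs$per_point <- write_table(met, cfg$output$dir, "metrics_points.csv")
    outputs$summaries <- write_table(summ, cfg$output$dir, "summaries_regions.csv")
    result <- list(metrics = met, summaries = summ,
                   diagnostics = attr(rec, "diagnostics"))
  }

  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   package = "aortashear",
                   version = as.character(utils::packageVersion("aortashear")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(cfg$output$dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  outputs$manifest <- file.path(cfg$output$dir, "manifest.json")
  invisible(c(list(outputs = outputs), result))
}
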