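#' Pipeline configuration
#'
#' Assembles the configuration of a full end-to-end run: input source
#' (a cohort CSV or the synthetic generator), adjustment and EFA options,
#' battery resampling counts and directions, and the global seed from
#' which every stage seed is derived.
#'
#' @param input path to a cohort CSV, or `NULL` to simulate.
#' @param generator a [default_config()] list used when simulating.
#' @param n_total subjects to simulate when `generator` is `NULL`.
#' @param max_factors factors extracted before retention.
#' @param score_method factor score estimator.
#' @param boot_replicates,ba_permutations,hn_permutations battery
#'   resampling counts.
#' @param directions named vector of JT/HN trend directions per indicator
#'   (`"auto"` entries resolved from the data).
#' @param alpha,ba_alpha nominal levels (density tests Bonferroni 0.05/3).
#' @param out_dir optional output directory for CSV artifacts.
#' @param seed global seed.
#' @return A list of class `carproc_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, generator = NULL, n_total = 756,
                            max_factors = 4,
                            score_method = "regression",
                            boot_replicates = 5000, ba_permutations = 500,
                            hn_permutations = 2000, directions = "auto",
                            alpha = 0.05, ba_alpha = 0.05 / 3,
                            out_dir = NULL, seed = 1L) {
  if (is.null(input) && is.null(generator))
    generator <- default_config(n_total = n_total, seed = seed)
  structure(list(input = input, generator = generator,
                 max_factors = max_factors, score_method = score_method,
                 boot_replicates = boot_replicates,
                 ba_permutations = ba_permutations,
                 hn_permutations = hn_permutations,
                 directions = directions, alpha = alpha,
                 ba_alpha = ba_alpha, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "carproc_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in analysis order: ingest or simulate the cohort;
#' screen the raw proxies (correlations, ANOVA/KW); adjust for age and
#' gender; extract and label the latent domains; build the seven indicator
#' columns; correlate the indicators; run the 9-test battery per indicator;
#' grade the evidence and assemble the synoptic table.  The run is
#' deterministic given the configuration seed.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `carproc_report`: `cohort`, `proxy_screen`,
#'   `proxy_correlations`, `adjustment`, `efa`, `labels`, `indicators`,
#'   `indicator_correlations`, `batteries`, `grades`, `synoptic`, and a
#'   `provenance` block (seed, config echo, package version).
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(n_total = 400, seed = 1,
#'                                     boot_replicates = 500,
#'                                     ba_permutations = 100,
#'                                     hn_permutations = 500))
#' rep$synoptic
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "carproc_pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("input", {
    if (!is.null(config$input)) read_cohort(config$input)
    else generate_cohort(config$generator)$cohort
  })
  screen <- stage("proxy_screen", proxy_group_screen(cohort))
  pc <- stage("proxy_correlations",
              correlation_screen(cbind(bmi = cohort$bmi,
                                       as.matrix(cohort[, proxy_names()]))))
  built <- stage("indicators", build_indicators(cohort,
                                                max_factors = config$max_factors))
  ind <- built$indicators
  icorr <- stage("indicator_correlations", indicator_correlations(ind))
  dirs <- config$directions
  batteries <- list()
  # BMI_aPRT is correlated with the indicators (step-a analysis) but not
  # battery-tested against its own grouping variable
  battery_cols <- setdiff(names(ind), "BMI_aPRT")
  for (i in seq_along(battery_cols)) {
    nm <- battery_cols[i]
    dirn <- if (identical(dirs, "auto")) "auto"
    else if (nm %in% names(dirs)) dirs[[nm]] else "auto"
    batteries[[nm]] <- stage(paste0("battery_", nm),
      run_battery(ind[[nm]], cohort$group, direction = dirn,
                  alpha = config$alpha, ba_alpha = config$ba_alpha,
                  boot_replicates = config$boot_replicates,
                  ba_permutations = config$ba_permutations,
                  hn_permutations = config$hn_permutations,
                  seed = config$seed + 100 * i))
  }
  grades <- lapply(batteries, grade_evidence)
  syn <- stage("synoptic", synoptic_table(batteries))
  report <- structure(list(
    cohort = cohort, proxy_screen = screen, proxy_correlations = pc,
    adjustment = built$model, efa = built$efa, labels = built$labels,
    indicators = ind, indicator_correlations = icorr,
    batteries = batteries, grades = grades, synoptic = syn,
    provenance = list(seed = config$seed,
                      n = nrow(cohort),
                      package_version =
                        as.character(utils::packageVersion("carproc")),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "carproc_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Pearson correlations among the indicator columns
#'
#' @param indicators data.frame of the seven indicator columns.
#' @return A [correlation_screen()] list (`r`, `p`, `codes`).
#' @export
indicator_correlations <- function(indicators) {
  correlation_screen(as.matrix(indicators))
}

#' Write the report artifacts as CSV files
#'
#' @param report a `carproc_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$synoptic,
                   file.path(out_dir, "synoptic.csv"), row.names = FALSE)
  utils::write.csv(report$proxy_screen,
                   file.path(out_dir, "proxy_screen.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$indicator_correlations$r),
                   file.path(out_dir, "indicator_correlations.csv"))
  utils::write.csv(cbind(report$cohort[, c("id", "group")],
                         report$indicators),
                   file.path(out_dir, "indicators.csv"), row.names = FALSE)
  tidy <- do.call(rbind, lapply(names(report$batteries), function(nm) {
    b <- report$batteries[[nm]]
    do.call(rbind, lapply(b$tests, function(t)
      data.frame(indicator = nm, test = t$test_name,
                 pair = t$groups_compared, statistic = t$statistic,
                 p = t$p_value, alpha = t$alpha,
                 significant = t$significant,
                 stringsAsFactors = FALSE)))
  }))
  utils::write.csv(tidy, file.path(out_dir, "battery.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.carproc_report <- function(x, ...) {
  cat("carproc pipeline report -", x$provenance$n, "subjects, seed",
      x$provenance$seed, "\n\n")
  print(x$synoptic, row.names = FALSE)
  invisible(x)
}
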