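# End-to-end pipeline: simulate (or load) both study phases, run the
# compliance engine, compute the three metrics, run the pre/post tests, and
# emit a JSON report plus CSV outputs.

#' Default run configuration
#'
#' Assembles the full configuration for [run_pipeline()]: engine settings,
#' one simulation configuration per phase, metric and test options. The
#' default phase regimes are the package's study conditions: 75 baseline and
#' 63 post-intervention patients, with caregiver-turn miss probabilities
#' calibrated (via [make_phase_regimes()]) so pooled compliance approximates
#' 64% at baseline and 98% post-intervention, and Braden/age/sex
#' distributions following the two cohorts.
#'
#' @param seed Global integer seed.
#' @param n_baseline,n_post Patients per phase.
#' @param baseline_miss,post_miss Caregiver-turn miss probabilities for the
#'   two regimes.
#' @param block_h Block size for adherence, in patient-hours.
#' @param exempt Exemption handling for metrics (see [patient_compliance()]).
#' @param t_variant,t_tails Conventions for the primary t test.
#' @param out_dir Optional output directory for report and CSVs.
#' @return A \code{run_config} list.
#' @export
run_config <- function(seed = 20130501,
                       n_baseline = 75, n_post = 63,
                       baseline_miss = 0.75, post_miss = 0,
                       block_h = 100,
                       exempt = "include",
                       t_variant = "student", t_tails = "two",
                       out_dir = NULL) {
  baseline <- simulation_config(n_patients = n_baseline,
                                miss_probability = baseline_miss,
                                phase = "baseline", seed = seed)
  post <- simulation_config(n_patients = n_post,
                            miss_probability = post_miss,
                            phase = "post",
                            demographics = list(
                              age_mean = 63, age_sd = 18,
                              female_prob = 0.56,
                              braden_mean = 19.9, braden_sd = 2.2,
                              isolation_prob = 5 / 63),
                            seed = seed + 1L)
  cfg <- list(seed = as.integer(seed),
              engine = engine_config(),
              baseline = baseline, post = post,
              metrics = list(block_h = block_h, exempt = exempt),
              stats = list(variant = t_variant, tails = t_tails),
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Any field omitted in the file keeps its [run_config()] default. Engine
#' fields go under \code{engine:}, per-phase simulation overrides under
#' \code{baseline:} / \code{post:}.
#'
#' @param path YAML file path.
#' @return A \code{run_config} list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
  if (!is.null(y$engine))
    cfg$engine <- do.call(engine_config,
                          y$engine[intersect(names(y$engine),
                                             names(formals(engine_config)))])
  for (ph in c("baseline", "post")) {
    if (!is.null(y[[ph]])) {
      args <- unclass(cfg[[ph]])
      over <- y[[ph]][intersect(names(y[[ph]]), names(formals(simulation_config)))]
      args[names(over)] <- over
      cfg[[ph]] <- do.call(simulation_config,
                           args[intersect(names(args),
                                          names(formals(simulation_config)))])
    }
  }
  cfg
}

#' Run the full monitoring analysis pipeline
#'
#' Simulates both phase cohorts (or uses cohorts supplied by the caller),
#' scores every trace with the compliance engine, computes pooled
#' compliance, block adherence and hourly compliance per phase, and runs the
#' inferential comparisons: the primary t test on per-patient compliance
#' fractions, the isolation-subgroup t test (flagged as underpowered when
#' either subgroup has fewer than 10 patients), the Braden t test and the
#' sex chi-square. Fully deterministic given \code{config$seed}.
#'
#' @param config A [run_config()].
#' @param cohorts Optional list with elements \code{baseline} and \code{post},
#'   each as returned by [simulate_cohort()]; when supplied, simulation is
#'   skipped.
#' @return A report list (also written as JSON/CSVs when
#'   \code{config$out_dir} is set).
#' @export
run_pipeline <- function(config = run_config(), cohorts = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  if (is.null(cohorts)) {
    message("simulate: baseline n=", config$baseline$n_patients,
            ", post n=", config$post$n_patients)
    cohorts <- stage("simulate", list(
      baseline = simulate_cohort(config$baseline),
      post = simulate_cohort(config$post)))
  }

  timelines <- stage("engine", lapply(cohorts, score_cohort,
                                      engine = config$engine))
  summaries <- stage("metrics", lapply(names(timelines), function(ph)
    phase_summary(timelines[[ph]], cohorts[[ph]]$records, phase = ph,
                  block_h = config$metrics$block_h,
                  exempt = config$metrics$exempt)))
  names(summaries) <- names(timelines)

  tests <- stage("stats", {
    sb <- summaries$baseline; sp <- summaries$post
    if (sb$n_patients < 2 || sp$n_patients < 2)
      stop("t test needs n >= 2 per phase")
    rb <- cohorts$baseline$records; rp <- cohorts$post$records
    iso_b <- sb$per_patient_compliance[rb$isolation]
    iso_p <- sp$per_patient_compliance[rp$isolation]
    iso <- if (length(iso_b) >= 2 && length(iso_p) >= 2)
      two_sample_t(iso_b, iso_p, config$stats$variant, config$stats$tails)
    else NULL
    if (!is.null(iso))
      iso$underpowered <- length(iso_b) < 10 || length(iso_p) < 10
    list(
      primary_compliance = two_sample_t(sb$per_patient_compliance,
                                        sp$per_patient_compliance,
                                        config$stats$variant,
                                        config$stats$tails),
      isolation_compliance = iso,
      braden = two_sample_t(rb$braden, rp$braden, "student", "two"),
      # a tiny cohort can produce an all-F or all-M table; report NULL then
      sex = tryCatch(chi_square_2x2(rbind(
        table(factor(rb$sex, c("F", "M"))),
        table(factor(rp$sex, c("F", "M"))))),
        error = function(e) NULL),
      sample_size_target = sample_size(1.96, 0.5, 0.123))
  })

  report <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    config = list(
      engine = unclass(config$engine),
      baseline = unclass(config$baseline),
      post = unclass(config$post),
      metrics = config$metrics,
      stats = config$stats),
    phases = lapply(summaries, function(s)
      s[c("phase", "n_patients", "monitored_h", "pooled_compliance",
          "per_patient_compliance", "block_adherence", "hourly_compliance")]),
    tests = lapply(tests, function(t)
      if (is.list(t)) unclass(t) else t))
  class(report) <- "turnwatch_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    h <- report$config_hash
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    for (ph in names(timelines)) {
      write_trace_csv(cohorts[[ph]]$traces,
                      file.path(config$out_dir, paste0(ph, "_traces.csv")),
                      config)
      write_exemption_csv(cohorts[[ph]]$exemptions,
                          file.path(config$out_dir, paste0(ph, "_exemptions.csv")),
                          config)
      write_record_csv(cohorts[[ph]]$records,
                       file.path(config$out_dir, paste0(ph, "_records.csv")),
                       config)
      write_timeline_csv(timelines[[ph]],
                         file.path(config$out_dir, paste0(ph, "_timeline.csv")),
                         config)
      s <- summaries[[ph]]
      write_with_header(
        data.frame(block = seq_along(s$block_adherence),
                   adherence = s$block_adherence),
        file.path(config$out_dir, paste0(ph, "_block_adherence.csv")), h)
      write_with_header(
        data.frame(hour = 0:23, compliance = unname(s$hourly_compliance)),
        file.path(config$out_dir, paste0(ph, "_hourly_compliance.csv")), h)
    }
  }
  report
}

#' @export
print.turnwatch_report <- function(x, ...) {
  cat("<turnwatch_report>\n")
  for (ph in names(x$phases)) {
    p <- x$phases[[ph]]
    cat(sprintf("  %-9s n=%3d  %7.0f h  pooled compliance %.1f%%\n",
                p$phase, p$n_patients, p$monitored_h,
                100 * p$pooled_compliance))
  }
  t <- x$tests$primary_compliance
  cat(sprintf("  primary t test: t = %.3f, df = %.1f, p = %.3g\n",
              t$statistic, t$df, t$p_value))
  invisible(x)
}
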