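#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer master seed; every stochastic stage derives its seed
#'   from it.
#' @param inputs_path optional national-inputs YAML/JSON (default: packaged
#'   2022 Romanian inputs).
#' @param value_set_path optional EQ-5D value-set CSV (default: packaged
#'   synthetic tariff).
#' @param fx_override optional RON/EUR rate overriding the config value.
#' @param mnar logical; inject and re-impute adult treatment-cost
#'   missingness (the study's situation) rather than costing the complete
#'   synthetic data directly.
#' @param m,iterations imputation settings (see [impute_treatment()]).
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("adcoi-run-"), seed = 1L,
                       inputs_path = NULL, value_set_path = NULL,
                       fx_override = NULL, mnar = TRUE,
                       m = 5L, iterations = 10L) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 inputs_path = inputs_path, value_set_path = value_set_path,
                 fx_override = fx_override, mnar = mnar,
                 m = m, iterations = iterations),
            class = "run_config")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full cost-of-illness pipeline
#'
#' Executes synth (seeded study-calibrated cohorts) -> process (MNAR
#' injection, missingness diagnosis, PMM imputation, severity averages) ->
#' extrapolate (case / hospitalization / worker counts per segment and
#' basis) -> cost (all four scenarios for both segments) -> eq5d (utilities,
#' dichotomized frequencies, EQ-VAS). Writes tidy CSVs, rendered
#' paper-shaped tables and a manifest (inputs, seed, versions, checksums)
#' under `config$out_dir`. Any stage failure aborts with a stage-labelled
#' message and removes partial outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with cohorts, averages, stratifications, the 8
#'   scenario results, EQ-5D summaries, rendered tables and the manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  inputs <- pipeline_stage("config", national_inputs(config$inputs_path))
  if (!is.null(config$fx_override)) inputs$unit_costs$fx <- config$fx_override
  seed <- config$seed

  cohorts <- pipeline_stage("synth", {
    list(adult = generate_cohort(adult_study_spec(), seed = seed),
         pediatric = generate_cohort(pediatric_study_spec(), seed = seed + 1L))
  })

  processed <- pipeline_stage("process", {
    adult <- cohorts$adult
    report <- NULL
    if (config$mnar) {
      sp <- adult_study_spec()
      adult <- inject_mnar(adult, sp$mnar_rate, sp$mnar_strength, seed = seed + 2L)
      report <- missingness_report(adult)
      adult <- impute_treatment(adult, m = config$m,
                                iterations = config$iterations, seed = seed + 3L)
    }
    list(adult = adult, pediatric = cohorts$pediatric,
         missingness = report,
         averages = list(adult = severity_averages(adult),
                         pediatric = severity_averages(cohorts$pediatric)))
  })

  strats <- pipeline_stage("extrapolate", {
    out <- list()
    for (seg in c("adult", "pediatric"))
      for (b in c("prevalence", "incidence"))
        out[[paste(seg, b, sep = "_")]] <- build_stratification(
          seg, b, inputs$epi, inputs$survey, processed$averages[[seg]])
    out
  })

  results <- pipeline_stage("cost", {
    out <- list()
    for (seg in c("adult", "pediatric"))
      for (b in c("prevalence", "incidence"))
        for (src in c("survey", "prescription"))
          out[[paste(seg, b, src, sep = "_")]] <- run_scenario(
            scenario_spec(b, src), processed$averages[[seg]],
            strats[[paste(seg, b, sep = "_")]], inputs$unit_costs)
    out
  })

  eq <- pipeline_stage("eq5d", {
    vs <- read_value_set(config$value_set_path)
    list(value_set = vs,
         utilities = lapply(processed[c("adult", "pediatric")], function(r)
           utility_ranges(r, vs, grouping = "severity")),
         frequencies = lapply(processed[c("adult", "pediatric")],
                              dimension_frequencies),
         vas = lapply(processed[c("adult", "pediatric")], vas_summary))
  })

  tables <- pipeline_stage("render", render_tables(results, processed$averages, strats, eq))

  written <- character(0)
  manifest <- pipeline_stage("write", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      p <- file.path(config$out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      written <<- c(written, p)
      p
    }
    tryCatch({
      wr(do.call(rbind, lapply(results, scenario_table)), "scenario_results.csv")
      wr(do.call(rbind, lapply(strats, stratification_table)), "stratifications.csv")
      for (nm in names(tables)) wr(tables[[nm]], paste0(nm, ".csv"))
      manifest <- list(
        package_version = as.character(utils::packageVersion("adcoi")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = seed,
        inputs_path = config$inputs_path %||% "packaged national_inputs.yaml",
        value_set = eq$value_set$name,
        files = stats::setNames(as.character(tools::md5sum(written)),
                                basename(written)))
      mp <- file.path(config$out_dir, "manifest.json")
      jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
      manifest
    }, error = function(e) {
      unlink(written)
      stop(e)
    })
  })

  invisible(list(inputs = inputs, cohorts = cohorts, processed = processed,
                 stratifications = strats, results = results, eq5d = eq,
                 tables = tables, manifest = manifest))
}

fmt_eur <- function(x) round(x, 1)

scenario_order <- function(seg) {
  paste(seg, c("prevalence_survey", "incidence_survey",
               "prevalence_prescription", "incidence_prescription"), sep = "_")
}

average_table <- function(results, seg) {
  cols <- scenario_order(seg)
  out <- data.frame(row = c("average_all", paste0("average_", SEVERITIES)),
                    stringsAsFactors = FALSE)
  for (nm in cols) {
    r <- results[[nm]]
    out[[paste(r$basis, r$treatment_source, sep = "_")]] <-
      fmt_eur(c(r$average_overall, r$average_by_severity))
  }
  out
}

direct_cost_table <- function(results, seg) {
  rows <- list()
  for (b in c("prevalence", "incidence")) {
    sv <- results[[paste(seg, b, "survey", sep = "_")]]
    px <- results[[paste(seg, b, "prescription", sep = "_")]]
    rows[[b]] <- data.frame(
      basis = b,
      component = c("treatment", "treatment_prescription",
                    "medical_services", "associated"),
      rbind(fmt_eur(sv$cells["treatment", ]),
            fmt_eur(px$cells["treatment", ]),
            fmt_eur(sv$cells["medical_services", ]),
            fmt_eur(sv$cells["associated", ])),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[3:5] <- SEVERITIES
  rownames(out) <- NULL
  out
}

#' Render paper-shaped tables
#'
#' Formats the scenario results, input averages, stratifications and EQ-5D
#' summaries into the eleven published table shapes (average costs by
#' severity for each segment; total direct costs; productivity costs;
#' hospitalization costs; input cost averages; EQ-5D dimension frequencies
#' and EQ-VAS summaries for each segment). EUR cells are rounded to one
#' decimal and counts to integers; no value is recomputed here - every cell
#' is a rounded view of its tidy source.
#'
#' @param results named list of the 8 `scenario_result`s.
#' @param averages named list of `severity_averages` (adult, pediatric).
#' @param strats named list of `severity_stratification`s.
#' @param eq EQ-5D summary list (as built by [run_pipeline()]).
#' @return named list of data.frames `table01` .. `table11`.
#' @export
render_tables <- function(results, averages, strats, eq) {
  t5 <- do.call(rbind, lapply(c("adult", "pediatric"), function(seg)
    do.call(rbind, lapply(c("prevalence", "incidence"), function(b) {
      r <- results[[paste(seg, b, "survey", sep = "_")]]
      data.frame(segment = seg, basis = b, severity = SEVERITIES,
                 full_time = fmt_eur(r$cells["productivity_ft", ]),
                 part_time = fmt_eur(r$cells["productivity_pt", ]),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))))
  t6 <- data.frame(severity = SEVERITIES, stringsAsFactors = FALSE)
  for (seg in c("adult", "pediatric"))
    for (b in c("prevalence", "incidence"))
      t6[[paste(seg, b, sep = "_")]] <-
        fmt_eur(results[[paste(seg, b, "survey", sep = "_")]]$cells["hospitalization", ])
  t7 <- do.call(rbind, lapply(c("adult", "pediatric"), function(seg) {
    m <- averages[[seg]]$cost_means
    data.frame(segment = seg, severity = rownames(m),
               treatment = fmt_eur(m[, "treatment"]),
               medical_services = fmt_eur(m[, "medical_services"]),
               associated = fmt_eur(m[, "associated"]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  pct <- function(df) { df$problems_pct <- round(df$problems_pct, 2)
                        df$no_problems_pct <- round(df$no_problems_pct, 2); df }
  vas_round <- function(df) { for (cl in c("mean", "sd", "median", "p25", "p75"))
                                df[[cl]] <- round(df[[cl]], 2); df }
  list(table01 = average_table(results, "adult"),
       table02 = average_table(results, "pediatric"),
       table03 = direct_cost_table(results, "adult"),
       table04 = direct_cost_table(results, "pediatric"),
       table05 = t5, table06 = t6, table07 = t7,
       table08 = pct(eq$frequencies$adult),
       table09 = vas_round(eq$vas$adult),
       table10 = pct(eq$frequencies$pediatric),
       table11 = vas_round(eq$vas$pediatric))
}
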