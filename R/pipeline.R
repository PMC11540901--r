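# end-to-end pipeline: cohort -> scores -> levels -> plans -> summary

#' Pipeline configuration
#'
#' Bundles the stage configurations. Every component defaults to the
#' shipped tool definition; paths may be given instead of objects.
#'
#' @param weights A `weight_table` or YAML path.
#' @param cutoffs A `cutoff_set` or YAML path.
#' @param catalog An `intervention_catalog` or YAML path.
#' @param frequencies Frequency map (named vector) or YAML path.
#' @param policy A [derivation_policy()].
#' @param calibrate Recalibrate cutoffs from this cohort's scores with the
#'   Kaiser-pyramid fractions instead of using `cutoffs`?
#' @param fractions Pyramid fractions `(f1, f2)` used when `calibrate`.
#' @param exclude_overrides_from_calibration Drop override patients' scores
#'   from the percentile computation? Default `FALSE` (they are included).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(weights = default_weight_table(),
                            cutoffs = default_cutoffs(),
                            catalog = default_intervention_catalog(),
                            frequencies = default_frequency_map(),
                            policy = derivation_policy(),
                            calibrate = FALSE,
                            fractions = c(0.10, 0.30),
                            exclude_overrides_from_calibration = FALSE) {
  if (is.character(weights)) weights <- load_weight_table(weights)
  if (is.character(cutoffs)) cutoffs <- load_cutoffs(cutoffs)
  if (is.character(catalog)) catalog <- load_intervention_catalog(catalog)
  if (is.character(frequencies) && is.null(names(frequencies))) {
    frequencies <- unlist(yaml::read_yaml(frequencies))
  }
  structure(list(weights = validate_weight_table(weights),
                 cutoffs = cutoffs,
                 catalog = validate_intervention_catalog(catalog),
                 frequencies = frequencies, policy = policy,
                 calibrate = isTRUE(calibrate),
                 fractions = as.numeric(fractions),
                 exclude_overrides_from_calibration =
                   isTRUE(exclude_overrides_from_calibration)),
            class = "pipeline_config")
}

#' Run the full stratification pipeline
#'
#' Validates the cohort, routes and scores it, classifies against the
#' (optionally recalibrated) cutoffs, builds per-patient care plans and a
#' pyramid summary. Input files are never mutated. With `output_dir` set,
#' writes `scores.csv`, `levels.csv`, `plans.csv`, `summary.txt` and a
#' `manifest.json` recording counts and a hash of the configuration.
#'
#' @param cohort Cohort data frame or CSV path.
#' @param config A [pipeline_config()].
#' @param output_dir Optional output directory (created if needed).
#' @param verbose Log one line per stage?
#' @return A list: `cohort`, `scores`, `levels`, `plans`, `summary`,
#'   `cutoffs`, `manifest`.
#' @export
#' @examples
#' res <- run_pipeline(pilot_cohort())
#' res$summary
run_pipeline <- function(cohort, config = pipeline_config(),
                         output_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  cohort <- validate_cohort(cohort)
  say("stage=read records=%d", nrow(cohort))

  scores <- score_cohort(cohort, config$weights, config$policy)
  n_excluded <- sum(scores$routing == "pediatric_model_excluded")
  say("stage=score read=%d excluded=%d scored=%d", nrow(scores),
      n_excluded, nrow(scores) - n_excluded)

  cutoffs <- config$cutoffs
  if (config$calibrate) {
    s <- scores[scores$routing == "adult_scored", , drop = FALSE]
    if (config$exclude_overrides_from_calibration) {
      s <- s[s$override == "none", , drop = FALSE]
    }
    cutoffs <- calibrate_cutoffs(s$total_score, config$fractions[1],
                                 config$fractions[2])
    say("stage=calibrate c1=%d c2=%d", cutoffs$c1, cutoffs$c2)
  }

  levels <- classify(scores, cutoffs)
  say("stage=classify overridden=%d",
      sum(levels$override != "none" & levels$routing == "adult_scored"))
  plans <- build_plans(levels, cohort, config$catalog, config$frequencies)
  summary <- summarize_cohort(levels, cutoffs)
  say("stage=summarize level1=%d level2=%d level3=%d",
      summary$level_counts[[1]], summary$level_counts[[2]],
      summary$level_counts[[3]])

  manifest <- list(
    n_read = nrow(cohort),
    n_excluded_pediatric = summary$n_excluded_pediatric,
    n_scored = summary$n_scored,
    n_override_level1 = summary$n_override_level1,
    level_counts = as.list(summary$level_counts),
    cutoffs = list(c1 = cutoffs$c1, c2 = cutoffs$c2,
                   provenance = cutoffs$provenance),
    weight_table_version = attr(config$weights, "version"),
    config_hash = .config_hash(config)
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_scores_csv(scores, file.path(output_dir, "scores.csv"))
    lv <- levels[c("patient_id", "routing", "total_score", "override")]
    lv$priority_level <- levels$priority_level
    for (cc in names(lv)) lv[[cc]] <- fmt_val(lv[[cc]])
    utils::write.csv(lv, file.path(output_dir, "levels.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    pl <- plans
    for (cc in names(pl)) pl[[cc]] <- fmt_val(pl[[cc]])
    utils::write.csv(pl, file.path(output_dir, "plans.csv"),
                     row.names = FALSE, quote = TRUE, na = "")
    sink(file.path(output_dir, "summary.txt")); print(summary); sink()
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(cohort = cohort, scores = scores, levels = levels, plans = plans,
       summary = summary, cutoffs = cutoffs, manifest = manifest)
}

# stable fingerprint of the effective configuration (no digest dependency:
# serialize deterministically and sum a simple rolling hash)
.config_hash <- function(config) {
  payload <- jsonlite::toJSON(list(
    weights = unclass(config$weights)[c("variable_id", "trigger", "points",
                                        "exclusion_set", "override")],
    cutoffs = config$cutoffs[c("c1", "c2", "fractions")],
    catalog = unclass(config$catalog),
    frequencies = as.list(config$frequencies),
    policy = unclass(config$policy),
    calibrate = config$calibrate,
    fractions = config$fractions
  ), auto_unbox = TRUE, digits = 10)
  bytes <- utf8ToInt(as.character(payload))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
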