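# percentile cutoff calibration (Kaiser pyramid) and classification

#' Construct a cutoff set
#'
#' @param c1 Minimum total score for priority level 1 (highest complexity).
#' @param c2 Minimum total score for priority level 2; `c2 <= c1`.
#' @param fractions Pyramid target fractions `(f1, f2)` for levels 1 and 2.
#' @param provenance `"default"` for the shipped values or `"calibrated"`.
#' @return A list of class `cutoff_set`.
#' @export
cutoff_set <- function(c1, c2, fractions = c(0.10, 0.30),
                       provenance = c("calibrated", "default")) {
  provenance <- match.arg(provenance)
  if (!is_scalar_int(c1) || !is_scalar_int(c2) || c2 < 0 || c1 < c2) {
    stop_input("cutoffs must satisfy c1 >= c2 >= 0 (c1 == c2 only in the ",
               "degenerate all-tied case, which empties level 2)")
  }
  stopifnot(length(fractions) == 2, all(fractions > 0),
            sum(fractions) < 1)
  structure(list(c1 = as.integer(c1), c2 = as.integer(c2),
                 fractions = as.numeric(fractions), provenance = provenance),
            class = "cutoff_set")
}

#' Default priority cutoffs
#'
#' The shipped thresholds from the tool's final multicenter calibration:
#' level 1 from 32 points, level 2 from 21 points (Kaiser pyramid targets
#' 10%/30%).
#'
#' @return A `cutoff_set` with `c1 = 32`, `c2 = 21`.
#' @export
default_cutoffs <- function() {
  cutoff_set(32L, 21L, provenance = "default")
}

#' Calibrate priority cutoffs from a score distribution
#'
#' Kaiser-pyramid percentile rule: the top `f1` of patients by total score
#' form level 1 and the next `f2` level 2. On a discrete score scale ties
#' never split — a whole tie group is demoted when including it would
#' overshoot the target — so realized proportions can undershoot `f1` and
#' `f1 + f2`. Formally, `c1` is the smallest integer `t` with
#' `mean(scores >= t) <= f1`, and `c2` the smallest with
#' `mean(scores >= t) <= f1 + f2`.
#'
#' @param scores Non-empty integer vector of total scores.
#' @param f1,f2 Target fractions for levels 1 and 2 (defaults 0.10, 0.30).
#' @return A calibrated `cutoff_set`.
#' @export
#' @examples
#' calibrate_cutoffs(1:100)  # c1 = 91, c2 = 61
calibrate_cutoffs <- function(scores, f1 = 0.10, f2 = 0.30) {
  if (length(scores) == 0) stop_input("cannot calibrate on an empty cohort")
  if (anyNA(scores)) stop_input("scores contain NA; score the cohort first")
  if (any(scores < 0) || any(scores != floor(scores))) {
    stop_input("scores must be non-negative integers")
  }
  if (!(f1 > 0 && f2 > 0 && f1 + f2 < 1)) {
    stop_input("fractions must satisfy 0 < f1 < f1 + f2 < 1")
  }
  smallest_t <- function(target) {
    for (t in 0:(max(scores) + 1L)) {
      if (mean(scores >= t) <= target) return(as.integer(t))
    }
  }
  cutoff_set(smallest_t(f1), smallest_t(f1 + f2), fractions = c(f1, f2),
             provenance = "calibrated")
}

#' Classify scored patients into priority levels
#'
#' Level 1 if an override is present or `total_score >= c1`; level 2 if
#' `c2 <= total_score < c1`; otherwise level 3 (inclusive-minimum cutoff
#' semantics). Pediatric-excluded records are refused: they keep the
#' routing signal and an `NA` level.
#'
#' @param scores A `score_result` data frame from [score_cohort()], or a
#'   bare integer vector of totals (no overrides).
#' @param cutoffs A `cutoff_set`.
#' @return For a data frame input, the input with a `priority_level`
#'   column; for a vector, an integer vector of levels.
#' @export
#' @examples
#' classify(c(35, 21, 20), default_cutoffs())
classify <- function(scores, cutoffs = default_cutoffs()) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  level_of <- function(s) {
    ifelse(s >= cutoffs$c1, 1L, ifelse(s >= cutoffs$c2, 2L, 3L))
  }
  if (is.numeric(scores)) return(level_of(as.integer(scores)))
  if (!is.data.frame(scores) || is.null(scores$total_score)) {
    stop_input("scores must be a score_result data frame or integer vector")
  }
  excluded <- if (is.null(scores$routing)) rep(FALSE, nrow(scores)) else
    scores$routing == "pediatric_model_excluded"
  lv <- rep(NA_integer_, nrow(scores))
  lv[!excluded] <- level_of(scores$total_score[!excluded])
  if (!is.null(scores$override)) {
    lv[!excluded & scores$override != "none"] <- 1L
  }
  scores$priority_level <- lv
  scores
}

#' Summarize a classified cohort
#'
#' Pyramid accounting: totals in/excluded/scored, per-level counts and
#' proportions (over scored patients) and the number of override-assigned
#' level-1 patients.
#'
#' @param classified Output of [classify()] on a [score_cohort()] result.
#' @param cutoffs The `cutoff_set` used (recorded in the summary).
#' @return A list of class `cohort_summary`.
#' @export
summarize_cohort <- function(classified, cutoffs = default_cutoffs()) {
  if (!is.data.frame(classified) || is.null(classified$priority_level)) {
    stop_input("summarize_cohort expects a classified score_result")
  }
  excluded <- if (is.null(classified$routing)) {
    rep(FALSE, nrow(classified))
  } else {
    classified$routing == "pediatric_model_excluded"
  }
  scored <- classified[!excluded, , drop = FALSE]
  counts <- vapply(1:3, function(l) sum(scored$priority_level == l),
                   integer(1))
  names(counts) <- paste0("level", 1:3)
  n_scored <- nrow(scored)
  props <- if (n_scored > 0) counts / n_scored else counts * 0
  structure(list(
    n_total = nrow(classified),
    n_excluded_pediatric = sum(excluded),
    n_scored = n_scored,
    level_counts = counts,
    level_proportions = props,
    n_override_level1 = sum(scored$override != "none"),
    cutoffs = cutoffs
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort stratification summary\n")
  cat(sprintf("  records: %d (pediatric-model excluded: %d, scored: %d)\n",
              x$n_total, x$n_excluded_pediatric, x$n_scored))
  cat(sprintf("  cutoffs: level 1 >= %d, level 2 >= %d (%s)\n",
              x$cutoffs$c1, x$cutoffs$c2, x$cutoffs$provenance))
  for (l in 1:3) {
    cat(sprintf("  level %d: %4d (%5.1f%%)\n", l, x$level_counts[[l]],
                100 * x$level_proportions[[l]]))
  }
  cat(sprintf("  override-assigned level 1: %d\n", x$n_override_level1))
  invisible(x)
}

#' Load cutoffs from a YAML config
#' @param path YAML file with `c1`, `c2`, `fractions`, `provenance`.
#' @return A `cutoff_set`.
#' @export
load_cutoffs <- function(path) {
  cfg <- yaml::read_yaml(path)
  cutoff_set(cfg$c1, cfg$c2,
             fractions = as.numeric(cfg$fractions %||% c(0.10, 0.30)),
             provenance = cfg$provenance %||% "calibrated")
}

#' Write cutoffs to a YAML config
#' @param cutoffs A `cutoff_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cutoffs <- function(cutoffs, path) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  yaml::write_yaml(list(c1 = cutoffs$c1, c2 = cutoffs$c2,
                        fractions = cutoffs$fractions,
                        provenance = cutoffs$provenance), path)
  invisible(path)
}
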