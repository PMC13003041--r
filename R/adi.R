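#' Axonal Degeneration Index (ADI)
#'
#' The ADI stages each A53T animal by combining two complementary
#' striatal measures — TH optical density (fibre integrity) and axonal
#' swelling count (ongoing degeneration). Because swelling counts follow
#' an inverted-U over time (low early, peaking during active damage,
#' falling as fibres fragment), neither measure alone identifies the
#' stage; both are z-scored per time point and combined by a threshold
#' rule into stages 1 (early), 2 (intermediate) and 3 (advanced).
#'
#' @name adi
NULL

#' ADI staging rule
#'
#' Stage 1 (early): high TH (`z > th_high`) and low swelling
#' (`z < sw_low`). Stage 2 (intermediate): moderate TH
#' (`th_low <= z <= th_high`), any swelling. Stage 3 (advanced): low TH
#' (`z < th_low`) with either high (`z > sw_high`, active degeneration)
#' or low (`z < sw_low`, completed fibre loss) swelling. The quoted
#' inequalities are strict; combinations not covered by the three rules
#' (e.g. high TH with unremarkable swelling) fall back to
#' `fallback_score`, intermediate being the natural catch-all.
#'
#' @param th_high,th_low TH z-score thresholds (defaults 0.3 / -0.3).
#' @param sw_low,sw_high swelling z-score thresholds (defaults -0.5 / 0.5).
#' @param fallback_score stage assigned when no rule matches (default 2).
#' @return A `staging_rule` list.
#' @export
staging_rule <- function(th_high = 0.3, th_low = -0.3,
                         sw_low = -0.5, sw_high = 0.5,
                         fallback_score = 2L) {
  stopifnot(th_low < th_high, sw_low < sw_high,
            fallback_score %in% 1:3)
  structure(list(th_high = th_high, th_low = th_low, sw_low = sw_low,
                 sw_high = sw_high, fallback_score = as.integer(fallback_score)),
            class = "staging_rule")
}

#' Per-time-point z-scoring of cohort measurements
#'
#' Within each time point, z-scores the given variables across A53T
#' animals only (empty-vector animals have no swelling data: none are
#' imaged because they present no axonal swellings), using the sample SD.
#' Each per-time-point z-column has mean 0 and SD 1.
#'
#' @param cohort cohort data frame (columns `group`, `timepoint_days` and
#'   the measurement variables).
#' @param variables character vector of columns to z-score.
#' @param group_filter treatment group over which z-scores are defined
#'   (default `"a53t"`); use `NULL` to z-score across all animals.
#' @return The filtered cohort with one `<variable>_z` column added per
#'   variable.
#' @export
zscore_by_timepoint <- function(cohort,
                                variables = c("th_od", "swelling_count"),
                                group_filter = "a53t") {
  if (!is.null(group_filter)) cohort <- cohort[cohort$group %in% group_filter, ]
  if (!nrow(cohort)) stop("no animals after group filtering")
  for (v in variables) {
    if (!v %in% names(cohort)) stop("missing variable: ", v)
    z <- rep(NA_real_, nrow(cohort))
    for (tp in unique(cohort$timepoint_days)) {
      i <- cohort$timepoint_days == tp
      x <- cohort[[v]][i]
      if (sum(i) < 2)
        stop(sprintf("cannot z-score '%s' at time point %s: fewer than 2 animals",
                     v, tp))
      s <- sd(x)
      if (s == 0)
        stop(sprintf("zero SD for '%s' at time point %s", v, tp))
      z[i] <- (x - mean(x)) / s
    }
    cohort[[paste0(v, "_z")]] <- z
  }
  cohort
}

#' Classify degeneration stage from z-scores
#'
#' Vectorised, total classification under a [staging_rule()]; rules are
#' evaluated in the order 1, 3, 2, fallback, so every finite pair maps to
#' exactly one stage. The number of fallback assignments is attached as
#' `attr(, "n_fallback")`.
#'
#' @param th_z,sw_z finite z-scores (recycled to common length).
#' @param rule a [staging_rule()].
#' @return Integer stages in `{1, 2, 3}`.
#' @export
stage_classify <- function(th_z, sw_z, rule = staging_rule()) {
  n <- max(length(th_z), length(sw_z))
  th_z <- rep_len(th_z, n); sw_z <- rep_len(sw_z, n)
  if (any(!is.finite(th_z)) || any(!is.finite(sw_z)))
    stop("z-scores must be finite")
  out <- rep(NA_integer_, n)
  s1 <- th_z > rule$th_high & sw_z < rule$sw_low
  s3 <- th_z < rule$th_low & (sw_z > rule$sw_high | sw_z < rule$sw_low)
  s2 <- th_z >= rule$th_low & th_z <= rule$th_high
  out[s1] <- 1L
  out[!s1 & s3] <- 3L
  out[!s1 & !s3 & s2] <- 2L
  fb <- is.na(out)
  out[fb] <- rule$fallback_score
  attr(out, "n_fallback") <- sum(fb)
  out
}

#' Compute per-animal ADI records for a cohort
#'
#' z-scores TH OD and swelling count per time point across A53T animals
#' and applies the staging rule.
#'
#' @param cohort cohort data frame (see [generate_cohort()] for columns).
#' @param rule a [staging_rule()].
#' @return Data frame of ADI records: `animal_id`, `sex`,
#'   `timepoint_days`, `th_z`, `sw_z`, `stage`.
#' @export
compute_adi <- function(cohort, rule = staging_rule()) {
  z <- zscore_by_timepoint(cohort)
  stage <- stage_classify(z$th_od_z, z$swelling_count_z, rule)
  data.frame(animal_id = z$animal_id, sex = z$sex,
             timepoint_days = z$timepoint_days,
             th_z = z$th_od_z, sw_z = z$swelling_count_z,
             stage = as.integer(stage))
}

#' Compare ADI between sexes
#'
#' Mann-Whitney U test (midranks for ties, tie-corrected
#' continuity-corrected normal approximation), male sample first, as
#' appropriate for an ordinal stage score with only two groups.
#'
#' @param scores_m,scores_f stage scores of male and female animals.
#' @return A `test_result` from [mann_whitney()].
#' @export
adi_compare_sexes <- function(scores_m, scores_f) {
  mann_whitney(scores_m, scores_f)
}

#' Group summaries of ADI records
#'
#' @param records ADI record data frame from [compute_adi()].
#' @return Data frame with one row per sex x time point: `n`, `mean`,
#'   `sd` of the stage scores.
#' @export
adi_summarise <- function(records) {
  if (!nrow(records)) stop("no ADI records")
  agg <- aggregate(stage ~ sex + timepoint_days, data = records,
                   FUN = function(x) c(n = length(x), mean = mean(x),
                                       sd = if (length(x) > 1) sd(x) else NA))
  out <- data.frame(sex = agg$sex, timepoint_days = agg$timepoint_days,
                    n = agg$stage[, "n"], mean = agg$stage[, "mean"],
                    sd = agg$stage[, "sd"])
  out[order(out$timepoint_days, out$sex), , drop = FALSE]
}
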