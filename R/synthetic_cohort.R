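#' Configuration for synthetic cohort simulation
#'
#' Describes an animal-level cohort with the structure the downstream
#' analysis assumes: a 2 (sex) x 2 (AAV-A53T alpha-synuclein vs empty
#' vector) x time-point design in which striatal TH optical density
#' declines with time in A53T animals and axonal-swelling counts follow a
#' sex-specific inverted-U time profile (rising as axons swell, falling as
#' fibres fragment), with the male trajectory peaking earlier. Empty-vector
#' animals keep baseline TH and have structurally zero swelling counts
#' (they present no axonal swellings, so none are imaged).
#'
#' Defaults emulate the study design this pipeline targets: 5 A53T animals
#' per sex per time point, time points at 60 and 120 days post-surgery, a
#' male swelling peak at 60 days and a female peak at 120 days.
#'
#' @param n_per_cell animals per sex x group x time point (>= 2).
#' @param timepoints time points in days post-surgery.
#' @param th_baseline baseline TH optical density (arbitrary OD units).
#' @param th_decline_male,th_decline_female mean OD decline of A53T
#'   animals at each time point (same length as `timepoints`).
#' @param swelling_peak_time_male,swelling_peak_time_female day of the
#'   swelling-count peak per sex; the male peak must not be later than the
#'   female one (faster initial male progression).
#' @param swelling_peak_mean mean swelling count at the peak.
#' @param swelling_width temporal width (days) of the inverted-U profile.
#' @param dispersion negative-binomial size parameter of the count noise.
#' @param od_noise_sd between-animal OD noise SD.
#' @param weight_params list with per-sex body-weight mean/sd in grams.
#' @param seed integer RNG seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_per_cell = 5,
                              timepoints = c(60, 120),
                              th_baseline = 100,
                              th_decline_male = c(30, 45),
                              th_decline_female = c(10, 40),
                              swelling_peak_time_male = 60,
                              swelling_peak_time_female = 120,
                              swelling_peak_mean = 150,
                              swelling_width = 60,
                              dispersion = 10,
                              od_noise_sd = 5,
                              weight_params = list(
                                M = c(mean = 23, sd = 1.0),
                                F = c(mean = 19, sd = 1.5)),
                              seed = 1L) {
  stopifnot(n_per_cell >= 2, length(timepoints) >= 1,
            length(th_decline_male) == length(timepoints),
            length(th_decline_female) == length(timepoints),
            swelling_peak_mean >= 0, dispersion > 0, od_noise_sd >= 0,
            swelling_width > 0)
  if (swelling_peak_time_male > swelling_peak_time_female)
    stop("male swelling peak must not be later than the female peak")
  structure(as.list(environment()), class = "cohort_sim_config")
}

# inverted-U mean swelling-count profile
swelling_profile <- function(t, peak_time, peak_mean, width) {
  peak_mean * exp(-((t - peak_time) / width)^2)
}

#' Simulate an animal-level cohort table
#'
#' One row per animal with sex, treatment group, time point, TH optical
#' density (normal noise around the sex- and time-dependent mean),
#' swelling count (negative-binomial around the sex-specific inverted-U
#' profile; structurally zero for empty-vector animals), median swelling
#' volume and body weight.
#'
#' @param config a [cohort_sim_config()].
#' @return A data frame with columns `animal_id`, `sex`, `group`,
#'   `timepoint_days`, `th_od`, `swelling_count`,
#'   `swelling_median_volume_um3`, `weight_g`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  cells <- expand.grid(sex = c("M", "F"), group = c("a53t", "empty"),
                       timepoint_days = cfg$timepoints,
                       stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  id <- 0L
  for (i in seq_len(nrow(cells))) {
    sex <- cells$sex[i]; grp <- cells$group[i]; tp <- cells$timepoint_days[i]
    ti <- match(tp, cfg$timepoints)
    decline <- if (sex == "M") cfg$th_decline_male[ti] else
      cfg$th_decline_female[ti]
    th_mean <- if (grp == "a53t") cfg$th_baseline - decline else
      cfg$th_baseline
    peak_t <- if (sex == "M") cfg$swelling_peak_time_male else
      cfg$swelling_peak_time_female
    mu_sw <- if (grp == "a53t")
      swelling_profile(tp, peak_t, cfg$swelling_peak_mean,
                       cfg$swelling_width) else 0
    n <- cfg$n_per_cell
    wp <- cfg$weight_params[[sex]]
    sw <- if (mu_sw > 0) rnbinom(n, size = cfg$dispersion, mu = mu_sw)
          else integer(n)
    rows[[i]] <- data.frame(
      animal_id = sprintf("%s_%s_%03d_%02d", grp, sex, tp, id + seq_len(n)),
      sex = sex, group = grp, timepoint_days = tp,
      th_od = rnorm(n, th_mean, cfg$od_noise_sd),
      swelling_count = sw,
      swelling_median_volume_um3 =
        ifelse(sw > 0, exp(rnorm(n, log(2), 0.2)), NA_real_),
      weight_g = rnorm(n, wp["mean"], wp["sd"])
    )
    id <- id + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a cohort table as CSV
#'
#' @param cohort cohort data frame as from [generate_cohort()].
#' @param path CSV path.
#' @return `path` (write) or the cohort data frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
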