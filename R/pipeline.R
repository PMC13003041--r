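#' Write a synthetic demonstration data set
#'
#' Generates the fixture set used by the documentation and the end-to-end
#' pipeline: a handful of synthetic swelling stacks (multi-page TIFF with
#' JSON ground-truth sidecars) for the first A53T animals, a cohort CSV,
#' and a pipeline configuration JSON.
#'
#' @param out_dir writable output directory (created if needed).
#' @param seed integer seed driving both generators.
#' @param n_stacks number of image stacks to write.
#' @param stack_config optional [image_sim_config()] template; its seed is
#'   re-derived per stack from `seed`.
#' @param cohort_config optional [cohort_sim_config()]; its seed is set
#'   from `seed`.
#' @return Data frame inventory of the written files (relative path,
#'   size in bytes), invisibly also written as `manifest.json`.
#' @export
make_demo_data <- function(out_dir, seed = 1L, n_stacks = 4,
                           stack_config = NULL, cohort_config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(stack_config)) stack_config <- image_sim_config()
  if (is.null(cohort_config)) cohort_config <- cohort_sim_config()
  cohort_config$seed <- seed
  cohort <- generate_cohort(cohort_config)
  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
  imaged <- cohort$animal_id[cohort$group == "a53t"]
  stacks_dir <- file.path(out_dir, "stacks")
  dir.create(stacks_dir, showWarnings = FALSE)
  for (i in seq_len(n_stacks)) {
    cfg <- stack_config
    cfg$seed <- seed * 1000L + i
    sim <- generate_image_stack(cfg)
    aid <- imaged[(i - 1) %% length(imaged) + 1]
    write_stack_tiff(sim$stack,
                     file.path(stacks_dir, sprintf("%s_stack%02d.tif", aid, i)),
                     extra = list(truth = sim$truth))
  }
  config <- list(
    stacks_dir = "stacks", cohort_csv = "cohort.csv",
    animal_id_pattern = "^(.*)_stack[0-9]+\\.tif$",
    seed = seed,
    swelling = unclass(swelling_params()),
    adi_rule = unclass(staging_rule()),
    stats = list(response = "th_od", factor_a = "group", factor_b = "sex")
  )
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  inv <- data.frame(path = files,
                    bytes = file.size(file.path(out_dir, files)))
  jsonlite::write_json(inv, file.path(out_dir, "manifest.json"),
                       digits = NA)
  inv
}

pipeline_stage <- function(report, name, n_rows, outputs = character(0)) {
  report$stages[[name]] <- list(rows = n_rows, outputs = outputs)
  report
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: load stacks, quantify
#' swellings per stack, summarise per animal, load the cohort table,
#' compute per-animal ADI records, and run the group statistics
#' (Mann-Whitney ADI sex comparison per time point; two-way ANOVA on TH
#' OD). Every intermediate table is written as CSV and a manifest JSON
#' records the parameters, seed, per-stage row counts and content hashes
#' of the outputs. Deterministic for fixed inputs.
#'
#' @param config_path path to a pipeline `config.json` (as written by
#'   [make_demo_data()]); relative paths are resolved against its
#'   directory.
#' @param out_dir output directory (created if needed).
#' @return The run report (stage summaries and output manifest),
#'   invisibly; written as `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config_path, out_dir) {
  if (!file.exists(config_path)) stop("config not found: ", config_path)
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  root <- dirname(config_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(root, p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed, config = cfg, stages = list())

  stacks_dir <- resolve(cfg$stacks_dir)
  if (!dir.exists(stacks_dir)) stop("stage load_stacks: missing stacks dir: ",
                                    stacks_dir)
  tifs <- list.files(stacks_dir, pattern = "\\.tiff?$", full.names = TRUE)
  report <- pipeline_stage(report, "load_stacks", length(tifs))

  sp <- do.call(swelling_params, cfg$swelling[
    setdiff(names(cfg$swelling), character(0))])
  per_stack <- lapply(tifs, function(f) {
    res <- tryCatch(quantify_stack(read_stack_tiff(f), sp,
                                   stack_id = basename(f)),
                    error = function(e)
                      stop("stage swellings failed on ", basename(f), ": ",
                           conditionMessage(e)))
    data.frame(stack = basename(f), n_swellings = res$n_swellings,
               median_volume_um3 = res$median_volume,
               threshold = res$threshold)
  })
  stack_tab <- do.call(rbind, per_stack)
  swell_csv <- file.path(out_dir, "swellings_per_stack.csv")
  write.csv(stack_tab, swell_csv, row.names = FALSE)
  report <- pipeline_stage(report, "swellings", nrow(stack_tab),
                           basename(swell_csv))

  ids <- sub(cfg$animal_id_pattern, "\\1", stack_tab$stack)
  animal_tab <- do.call(rbind, lapply(unique(ids), function(a) {
    rows <- stack_tab[ids == a, ]
    data.frame(animal_id = a, n_stacks = nrow(rows),
               total_swellings = sum(rows$n_swellings))
  }))
  animal_csv <- file.path(out_dir, "swellings_per_animal.csv")
  write.csv(animal_tab, animal_csv, row.names = FALSE)
  report <- pipeline_stage(report, "summarize_animals", nrow(animal_tab),
                           basename(animal_csv))

  cohort <- read_cohort_csv(resolve(cfg$cohort_csv))
  report <- pipeline_stage(report, "cohort", nrow(cohort))

  rule <- do.call(staging_rule, cfg$adi_rule)
  adi <- compute_adi(cohort, rule)
  adi_csv <- file.path(out_dir, "adi.csv")
  write.csv(adi, adi_csv, row.names = FALSE)
  report <- pipeline_stage(report, "adi", nrow(adi), basename(adi_csv))

  stats_out <- list()
  for (tp in sort(unique(adi$timepoint_days))) {
    sub <- adi[adi$timepoint_days == tp, ]
    mw <- adi_compare_sexes(sub$stage[sub$sex == "M"],
                            sub$stage[sub$sex == "F"])
    stats_out[[paste0("adi_mw_day", tp)]] <-
      list(method = mw$method, U = mw$statistic, p = mw$p_value)
    an <- two_way_anova(cohort[cohort$timepoint_days == tp, ],
                        cfg$stats$response, cfg$stats$factor_a,
                        cfg$stats$factor_b)
    stats_out[[paste0("th_anova_day", tp)]] <- lapply(an, function(r)
      list(F = r$statistic, df = r$df, p = r$p_value))
  }
  stats_json <- file.path(out_dir, "stats.json")
  jsonlite::write_json(stats_out, stats_json, auto_unbox = TRUE, digits = NA)
  report <- pipeline_stage(report, "stats", length(stats_out),
                           basename(stats_json))

  outs <- list.files(out_dir, recursive = TRUE)
  outs <- setdiff(outs, "manifest.json")
  report$outputs <- data.frame(
    path = outs,
    md5 = unname(tools::md5sum(file.path(out_dir, outs))))
  jsonlite::write_json(report, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
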