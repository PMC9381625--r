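#' Write a cohort to NIfTI volumes plus a JSON manifest
#'
#' Per case: `<id>_T2.nii.gz`, `<id>_ADC.nii.gz`, `<id>_DWI.nii.gz`,
#' `<id>_prostate.nii.gz`; one `manifest.json` holding file paths, center
#' ids, lesion records (center voxel, radius, class), clicks and labels.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cases <- lapply(cohort$cases, function(case) {
    files <- list()
    for (sq in names(case$volumes)) {
      f <- file.path(dir, sprintf("%s_%s.nii.gz", case$case_id, sq))
      write_volume(case$volumes[[sq]], f)
      files[[sq]] <- basename(f)
    }
    fm <- file.path(dir, sprintf("%s_prostate.nii.gz", case$case_id))
    write_volume(case$prostate_mask, fm, spacing = case$spacing)
    list(case_id = case$case_id, center_id = case$center_id,
         volumes = files, prostate_mask = basename(fm),
         spacing = case$spacing,
         lesions = lapply(case$lesions, function(l)
           list(lesion_id = l$lesion_id, center_voxel = l$center_voxel,
                radius_mm = l$radius_mm, is_cs = l$is_cs)))
  })
  man <- list(cases = cases, lesion_table = cohort$manifest,
              seed = cohort$config$seed)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Load a cohort from a JSON manifest
#'
#' Reads back volumes and masks referenced by a manifest written with
#' [write_cohort()].
#'
#' @param path path to `manifest.json`.
#' @return A `synthetic_cohort`-shaped list usable by [extract_cohort()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  man <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dir <- dirname(path)
  cases <- lapply(man$cases, function(c_i) {
    vols <- lapply(c_i$volumes, function(f) read_volume(file.path(dir, f)))
    pm <- read_volume(file.path(dir, c_i$prostate_mask))
    lesions <- lapply(c_i$lesions, function(l)
      structure(list(lesion_id = l$lesion_id,
                     center_voxel = as.integer(unlist(l$center_voxel)),
                     radius_mm = l$radius_mm, is_cs = l$is_cs),
                class = "lesion_truth"))
    structure(list(case_id = c_i$case_id, center_id = c_i$center_id,
                   volumes = vols, prostate_mask = pm$values != 0,
                   spacing = pm$spacing, lesions = lesions),
              class = "synthetic_case")
  })
  manifest <- do.call(rbind, lapply(man$lesion_table, function(r)
    data.frame(case_id = r$case_id, center_id = r$center_id,
               lesion_id = r$lesion_id, click_i = r$click_i,
               click_j = r$click_j, click_k = r$click_k,
               radius_mm = r$radius_mm, is_cs = r$is_cs)))
  structure(list(cases = cases, manifest = manifest,
                 config = list(seed = man$seed)),
            class = "synthetic_cohort")
}

#' Pipeline configuration
#'
#' Defaults reproduce the reference settings: bin width 30, distance 1,
#' 4:1 train/test split, and the 6-30 mm diameter grid for sweeps.
#'
#' @param diameter_mm single VOI diameter for a plain run.
#' @param sweep run the full diameter sweep instead of one diameter.
#' @param budget optimizer trials.
#' @param seed integer seed for split, nested CV and optimizer.
#' @param extraction an [extraction_params()].
#' @param bins MI discretization bins.
#' @param out_dir optional directory for artifacts (features CSV, results
#'   JSON, provenance log).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(diameter_mm = 18, sweep = FALSE, budget = 30,
                            seed = 1, extraction = extraction_params(),
                            bins = 10, out_dir = NULL) {
  stopifnot(inherits(extraction, "extraction_params"))
  structure(list(diameter_mm = diameter_mm, sweep = sweep,
                 budget = as.integer(budget), seed = as.integer(seed),
                 extraction = extraction, bins = as.integer(bins),
                 out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full pipeline on a cohort
#'
#' Orchestrates VOI construction, feature extraction, the 4:1 split,
#' optimization on the training rows, and test-set evaluation — either at
#' one diameter or as the full diameter sweep. When `config$out_dir` is
#' set, writes the feature table (CSV), results (JSON) and a provenance
#' block (config hash, seeds, package version, timings).
#'
#' @param cohort a `synthetic_cohort`, or the path to a cohort manifest.
#' @param config a [pipeline_config()].
#' @return For a single-diameter run: list with `features`, `split`,
#'   `model`, `evaluation`. For a sweep: a `sweep_report`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  t0 <- Sys.time()
  if (config$sweep) {
    out <- diameter_sweep_report(cohort, budget = config$budget,
                                 seed = config$seed,
                                 params = config$extraction,
                                 bins = config$bins)
    results_json <- lapply(out$results, function(r)
      jsonlite::fromJSON(eval_result_to_json(r)))
  } else {
    tab <- tryCatch(
      extract_cohort(cohort, config$diameter_mm, config$extraction),
      error = function(e) stop(sprintf("stage [extract]: %s",
                                       conditionMessage(e))))
    split <- split_cohort(nrow(tab), seed = config$seed)
    train <- tab[split$train, , drop = FALSE]
    test <- tab[split$test, , drop = FALSE]
    opt <- tryCatch(
      optimize_model(train, train$label, budget = config$budget,
                     seed = config$seed, bins = config$bins),
      error = function(e) stop(sprintf("stage [optimize]: %s",
                                       conditionMessage(e))))
    ev <- eval_result(predict(opt$model, test), test$label,
                      model_id = sprintf("dlm_d%02d", config$diameter_mm),
                      diameter_mm = config$diameter_mm)
    out <- list(features = tab, split = split, model = opt$model,
                trace = opt$trace, evaluation = ev)
    results_json <- jsonlite::fromJSON(eval_result_to_json(ev))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!config$sweep)
      utils::write.csv(out$features,
                       file.path(config$out_dir, "features.csv"),
                       row.names = FALSE)
    prov <- list(config = unclass(config), config_hash = config_hash(config),
                 seed = config$seed,
                 package_version = as.character(utils::packageVersion("dlmvoi")),
                 elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    jsonlite::write_json(list(provenance = prov, results = results_json),
                         file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}
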