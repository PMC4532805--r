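# Pipeline orchestration: ties the stages (simulate -> reference -> quantify
# -> classify -> regress) into one reproducible run directory with
# provenance, plus a subcommand command line interface.

#' Default pipeline configuration
#'
#' Defaults reproduce the analysis' stated settings: z threshold 2, lesion
#' size filter > 10 voxels, 26-connectivity, Bonferroni family m = 7,
#' AIC-based backward selection.
#'
#' @param seed Global seed.
#' @param phantom Named list of [phantom_config()] overrides for synthetic
#'   runs.
#' @return Nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 42L, phantom = list()) {
  structure(
    list(seed = as.integer(seed), threshold = 2, min_voxels = 10L,
         connectivity = 26L, compartment = "voxel", pooling = "voxel",
         criterion = "AIC", alpha = 0.05, bonferroni_m = 7L,
         write_volumes = FALSE, phantom = phantom),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration (JSON)
#'
#' @param path JSON file.
#' @param config A `pipeline_config`.
#' @return `read_pipeline_config`: the config; `write_pipeline_config`:
#'   `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_pipeline_config()
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

phantom_from_config <- function(config) {
  args <- config$phantom %||% list()
  args$seed <- args$seed %||% config$seed
  if (!is.null(args$grid_shape)) args$grid_shape <- as.integer(args$grid_shape)
  do.call(phantom_config, args)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> reference -> quantify -> classify -> score
#' generation -> regress and writes every stage output (delimited tables,
#' atlas NIfTI, provenance log) into `out_dir`. Deterministic given the
#' config: rerunning with the same config reproduces every table.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`atlas`,
#'   `reference`, `lesions`, `combinations`, `predictors`, `covariates`,
#'   `scores`, `regression`) and `paths` of the written files.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (missing(out_dir) || is.null(out_dir)) {
    config_error("out_dir is required")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  paths$config <- write_pipeline_config(config, file.path(out_dir, "config.json"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      qmri_stop("qmri_stage_error",
                sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  pc <- phantom_from_config(config)
  cohort <- stage("simulate", generate_cohort(pc))
  atlas <- cohort$atlas
  paths$atlas <- file.path(out_dir, "atlas")
  write_atlas(atlas, paths$atlas)
  if (isTRUE(config$write_volumes)) {
    vol_dir <- file.path(out_dir, "volumes")
    dir.create(vol_dir, showWarnings = FALSE)
    side <- atlas$voxel_volume^(1 / 3)
    for (i in seq_along(cohort$hc)) {
      for (ct in qmri_contrasts()) {
        write_nifti(cohort$hc[[i]][[ct]],
                    file.path(vol_dir, sprintf("hc%02d_%s.nii", i, ct)),
                    pixdim = rep(side, 3L))
      }
    }
    for (i in seq_along(cohort$patients)) {
      p <- cohort$patients[[i]]
      for (ct in qmri_contrasts()) {
        write_nifti(p$maps[[ct]],
                    file.path(vol_dir, sprintf("pat%02d_%s.nii", i, ct)),
                    pixdim = rep(side, 3L))
      }
      for (mk in names(p$masks)) {
        write_nifti(p$masks[[mk]] + 0L,
                    file.path(vol_dir, sprintf("pat%02d_mask_%s.nii", i, mk)),
                    pixdim = rep(side, 3L), datatype = "int32")
      }
    }
  }
  truth <- do.call(rbind, lapply(seq_along(cohort$patients), function(i) {
    cbind(subject = sprintf("pat%02d", i), cohort$patients[[i]]$truth)
  }))
  paths$truth <- write_tsv(truth, file.path(out_dir, "ground_truth.tsv"))

  ref <- stage("reference",
               compute_reference_stats(cohort$hc, atlas,
                                       pooling = config$pooling))
  paths$reference <- write_reference_stats(
    ref, file.path(out_dir, "reference_stats.tsv"))

  lesions <- stage("quantify", {
    do.call(rbind, lapply(seq_along(cohort$patients), function(i) {
      p <- cohort$patients[[i]]
      q <- quantify_lesions(p$maps, p$masks, atlas, ref,
                            min_voxels = config$min_voxels,
                            connectivity = config$connectivity,
                            compartment = config$compartment)
      if (!nrow(q)) return(NULL)
      cbind(subject = sprintf("pat%02d", i), q)
    }))
  })
  if (is.null(lesions) || !nrow(lesions)) {
    qmri_stop("qmri_stage_error", "stage 'quantify' produced no lesions")
  }
  lesions$signature <- stage("classify", zscore_signature(
    lesions[c("z_T1", "z_T2", "z_T2star", "z_MTR")],
    threshold = config$threshold))
  lesions$group <- assign_group(lesions$signature)
  paths$lesions <- write_tsv(lesions, file.path(out_dir, "lesions.tsv"))

  comb <- stage("classify", enumerate_combinations(lesions))
  paths$combinations <- write_tsv(comb,
                                  file.path(out_dir, "combinations_pooled.tsv"))
  predictors <- stage("classify", mlv_predictor_matrix(lesions))
  paths$predictors <- write_tsv(predictors,
                                file.path(out_dir, "mlv_predictors.tsv"))

  covariates <- generate_covariates(nrow(predictors),
                                    seed = subject_seed(config$seed, 1L,
                                                        offset = 900000L))
  covariates <- cbind(subject = predictors$subject, covariates)
  paths$covariates <- write_tsv(covariates, file.path(out_dir, "covariates.tsv"))

  score_model <- pc$score_model %||%
    default_score_model(setdiff(names(predictors), "subject"))
  scores <- stage("simulate", generate_clinical_scores(
    cbind(predictors, covariates[setdiff(names(covariates), "subject")]),
    score_model, seed = subject_seed(config$seed, 2L, offset = 900000L)))
  paths$scores <- write_tsv(scores, file.path(out_dir, "scores.tsv"))

  reg <- stage("regress", regress_clinical(
    predictors, covariates, scores, m = config$bonferroni_m,
    criterion = config$criterion, alpha = config$alpha))
  paths$models <- write_tsv(reg$models,
                            file.path(out_dir, "regression_models.tsv"))
  paths$model_predictors <- write_tsv(
    predictor_pvalue_table(reg),
    file.path(out_dir, "regression_predictors.tsv"))

  prov <- c(
    sprintf("qmrilesion %s", as.character(utils::packageVersion("qmrilesion"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("config md5 %s", unname(tools::md5sum(paths$config))),
    sprintf("seed %d", config$seed),
    sprintf("generated %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  writeLines(prov, file.path(out_dir, "provenance.txt"))
  paths$provenance <- file.path(out_dir, "provenance.txt")

  invisible(list(atlas = atlas, reference = ref, lesions = lesions,
                 combinations = comb, predictors = predictors,
                 covariates = covariates, scores = scores, regression = reg,
                 truth = truth, paths = paths))
}
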