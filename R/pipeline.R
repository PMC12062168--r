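#' Default pipeline configuration
#'
#' One nested configuration holding every stage's parameters with their
#' standard defaults: phantom study conditions, LDM and BED constants,
#' preprocessing caps and bin widths, and the modeling harness settings.
#' Serializable to YAML for reproducible runs.
#'
#' @param n_cases,responder_fraction Cohort composition.
#' @param seed Master seed; every stage derives its own seed from it.
#' @return A `sirt_run_config` list.
#' @export
run_config <- function(n_cases = 17, responder_fraction = 5 / 17,
                       seed = 7L) {
  structure(list(
    n_cases = n_cases, responder_fraction = responder_fraction,
    seed = as.integer(seed),
    phantom = unclass(phantom_config(seed = seed)),
    ldm = unclass(ldm_config()),
    bed = list(tumor = unclass(bed_params_tumor()),
               normal = unclass(bed_params_normal())),
    preprocess = unclass(preprocess_config()),
    model = unclass(model_config(seed = seed))),
    class = "sirt_run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [run_config()].
#' @return `read_run_config()` returns the config; `write_run_config()`
#'   the path, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(raw$n_cases, raw$responder_fraction, raw$seed)
  for (nm in intersect(names(raw), names(cfg))) cfg[[nm]] <- raw[[nm]]
  class(cfg$phantom) <- "phantom_config"
  class(cfg$ldm) <- "ldm_config"
  class(cfg$preprocess) <- "preprocess_config"
  class(cfg$model) <- "model_config"
  cfg
}

restore_classes <- function(cfg) {
  ph <- cfg$phantom; class(ph) <- "phantom_config"
  lc <- cfg$ldm; class(lc) <- "ldm_config"
  pc <- cfg$preprocess; class(pc) <- "preprocess_config"
  mc <- cfg$model; class(mc) <- "model_config"
  list(phantom = ph, ldm = lc, preprocess = pc, model = mc)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Phantom generation, dosimetry, DVC extraction, feature tables, and the
#' modeling experiment, all derived from one master seed. Writes every
#' tabular artifact to `out_dir` and records a manifest with file
#' checksums, so a rerun with the same config reproduces byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param fs_methods,classifiers Subsets for the modeling stage; defaults
#'   are a light two-by-two smoke grid — pass
#'   [fs_method_names()] / [classifier_names()] for the full 1440-model
#'   enumeration.
#' @param channels Image channels to extract features for.
#' @param train Train the models (`TRUE`) or only enumerate the grid.
#' @param write_volumes Also write the NIfTI volumes per case.
#' @return List `results` (experiment tibble), `dvc`, `tables`,
#'   `manifest` (tibble of artifacts and MD5 checksums).
#' @export
run_all <- function(config = run_config(), out_dir = tempfile("sirt_run_"),
                    fs_methods = c("anova", "kruskal"),
                    classifiers = c("LR", "NB"),
                    channels = c("CT", "SPECT_MAA", "SPECT_Y90",
                                 "DOSE_MAA", "DOSE_Y90", "BED_MAA",
                                 "BED_Y90"),
                    train = TRUE, write_volumes = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sub <- restore_classes(config)
  cohort <- generate_cohort(config$n_cases, config$responder_fraction,
                            base_config = sub$phantom, seed = config$seed)
  if (write_volumes) write_cohort(cohort, file.path(out_dir, "cohort"))
  dvc <- cohort_dvc_table(cohort, cfg = sub$ldm)
  tables <- cohort_feature_tables(cohort, cfg = sub$preprocess,
                                  ldm = sub$ldm, channels = channels)
  tables$DVC <- dvc
  tables$CLINICAL <- attr(cohort, "clinical")
  results <- run_experiment(tables, cfg = sub$model,
                            fs_methods = fs_methods,
                            classifiers = classifiers, train = train)
  utils::write.csv(dvc, file.path(out_dir, "dvc.csv"), row.names = FALSE)
  utils::write.csv(dplyr::select(results, -dplyr::any_of("inputs")),
                   file.path(out_dir, "model_results.csv"),
                   row.names = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- tibble::tibble(
    file = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  list(results = results, dvc = dvc, tables = tables, manifest = manifest,
       out_dir = out_dir)
}
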