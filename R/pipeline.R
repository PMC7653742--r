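# End-to-end orchestration: simulate (optional) -> coverage -> calibrate ->
# call -> partition -> growth, with every artifact written under one output
# directory and a JSON manifest recording parameters, seeds and checksums.

#' Demo pipeline configuration
#'
#' A self-contained configuration that simulates a small diploid
#' population and runs the complete PAV pipeline on it.
#'
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return A named list accepted by [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("pavpan_demo_"), seed = 1L) {
  list(
    out_dir = out_dir,
    seed = seed,
    simulate = list(n_core = 300L, n_dispensable = 100L, n_individuals = 8L),
    coverage = list(lambda = 40, dispersion = 0.05, epsilon = 0.5, window = 100L),
    thresholds = list(t_p = 0.25, t_h = 1.5),
    calibration = list(cv_max = 0.2, min_relative_depth = 0.5, target_count = 4000L),
    growth = list(n_permutations = 50L)
  )
}

#' Run the PAV pipeline
#'
#' Executes the pipeline stages in order. With a `simulate` entry in the
#' configuration, a synthetic dataset is generated and written first; the
#' coverage stage then reads the emitted GFF3 and bedGraph files, so the
#' run exercises the same file formats a real analysis would. Stage
#' results and TSV/JSON artifacts are written under `out_dir`, together
#' with `manifest.json` (parameters, seeds, file checksums).
#'
#' @param config a configuration list; see [demo_config()] for the shape.
#'   Alternatively a path to a YAML file with the same structure.
#' @return Invisibly, a list with the in-memory stage results (`matrix`,
#'   `calibrations`, `zygosity`, `partition`, `growth`, `fit`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_config("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$out_dir)) {
    abort_config("config must be a list with at least `out_dir`")
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    abort_io(sprintf("cannot create output directory: %s", out_dir))
  }
  seed <- as.integer(config$seed %||% 1L)
  thr <- config$thresholds %||% list()
  t_p <- thr$t_p %||% 0.25
  t_h <- thr$t_h %||% 1.5

  # --- simulate ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    model <- build_pangenome_model(sim$n_core %||% 300L,
                                   sim$n_dispensable %||% 100L,
                                   seed = seed)
    pop <- sample_population(model, sim$n_individuals %||% 8L, seed = seed + 1L)
    cov <- config$coverage %||% list()
    cfg <- coverage_config(lambda = cov$lambda %||% 40,
                           dispersion = cov$dispersion %||% 0.05,
                           epsilon = cov$epsilon %||% 0.5,
                           window = cov$window %||% 100L)
    emit_dataset(pop, cfg, out_dir, seed = seed + 2L)
    annotation_path <- file.path(out_dir, "annotation.gff3")
    track_paths <- file.path(out_dir, paste0(pop$individual_ids, ".bedgraph"))
  } else {
    annotation_path <- config$annotation %||%
      abort_config("config needs `annotation` when no simulate stage is given")
    track_paths <- config$tracks %||%
      abort_config("config needs `tracks` when no simulate stage is given")
    if (!all(file.exists(track_paths))) abort_io("missing depth track files")
  }

  # --- coverage ---------------------------------------------------------
  annotation <- read_annotation(annotation_path)
  tracks <- lapply(track_paths, read_depth_track)
  mat <- build_matrix(tracks, annotation)
  write_coverage_matrix(mat, file.path(out_dir, "coverage_raw.tsv"), "raw")

  # --- calibrate --------------------------------------------------------
  cal_cfg <- config$calibration %||% list()
  calibrations <- calibrate_individuals(
    mat,
    cv_max = cal_cfg$cv_max %||% 0.2,
    min_relative_depth = cal_cfg$min_relative_depth %||% 0.5,
    target_count = cal_cfg$target_count %||% 4000L
  )
  jsonlite::write_json(
    lapply(calibrations, function(c) {
      list(individual_id = c$individual_id, lambda1 = c$lambda1,
           lambda2 = c$lambda2, method = c$method,
           n_stable_genes = length(c$stable_gene_ids))
    }),
    file.path(out_dir, "calibration.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  mat <- normalize_matrix(mat, calibrations)
  write_coverage_matrix(mat, file.path(out_dir, "coverage_normalized.tsv"),
                        "normalized")

  # --- call + partition -------------------------------------------------
  z <- call_matrix(mat, t_p = t_p, t_h = t_h)
  write_zygosity(z, file.path(out_dir, "zygosity.tsv"))
  part <- suppressWarnings(partition_core_dispensable(z))
  write_partition(part, file.path(out_dir, "partition.tsv"))
  write.table(part$per_individual, file.path(out_dir, "per_individual.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- growth -----------------------------------------------------------
  gcfg <- config$growth %||% list()
  sets <- presence_sets(z)
  curve <- growth_curve(sets, reference_set = character(0),
                        n_permutations = gcfg$n_permutations %||% 100L,
                        seed = seed + 3L)
  write.table(curve$summary, file.path(out_dir, "growth_curve.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  fit <- tryCatch(fit_openness(curve), pavpan_error = function(e) NULL)
  if (!is.null(fit)) {
    jsonlite::write_json(unclass(fit), file.path(out_dir, "openness_fit.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  # --- manifest ---------------------------------------------------------
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    seed = seed,
    thresholds = list(t_p = t_p, t_h = t_h),
    config = config[setdiff(names(config), "out_dir")],
    outputs = setNames(as.list(unname(tools::md5sum(files))), basename(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(matrix = mat, calibrations = calibrations, zygosity = z,
                 partition = part, growth = curve, fit = fit,
                 manifest = manifest))
}
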