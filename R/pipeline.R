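PIPELINE_DEFAULTS <- list(
  max_rank = 5L,
  allowed_confidence = c("high", "medium", "low"),
  lowess_fraction = 0.3,
  lowess_iterations = 3L,
  min_calibration_pairs = 10L,
  mass_window_ppm = 5,
  rt_window_frac = 0.05,
  cluster_max_iter = 50L,
  cluster_tol = 1e-6,
  min_members = 2L,
  mass_accuracy_ppm = 5,
  protein_count_by = "cluster",
  detection_fraction = 0.5,
  min_peptides = 2L,
  fold = 2,
  alpha = 0.05,
  mw_mode = "auto",
  split_rule = 2 / 3,
  seed = 1L
)

#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with its default:
#' peptide rank/confidence filters, LOWESS span, the 5 ppm / 5% clustering
#' windows, the 2-member cluster minimum, the strict 5 ppm mass-accuracy
#' bound, the 50% detection fraction, the 2-peptide / 2-fold / 0.05
#' differential-abundance thresholds, and the 2/3 discovery split. Unknown
#' keys are rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, overrides)
  stopifnot(cfg$mass_window_ppm > 0, cfg$rt_window_frac > 0,
            cfg$mass_accuracy_ppm > 0, cfg$min_members >= 1L,
            cfg$min_peptides >= 1L, cfg$detection_fraction >= 0,
            cfg$detection_fraction <= 1, cfg$fold >= 1,
            cfg$alpha > 0, cfg$alpha <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration file (YAML)
#'
#' @param path YAML file of configuration keys.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config` to serialize.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Orchestrates the end-to-end analysis: read (or accept in memory) the
#' per-sample peptide exports, apply the rank/confidence filters, calibrate
#' retention times to the reference by LOWESS, cluster features across runs,
#' keep clusters with at least two members, annotate representative
#' sequences and proteins under the mass-accuracy filter, quantify each set
#' (detection filter, imputation, ppm normalization, protein summation),
#' test differential abundance in the discovery set and verify it in the
#' test set. Stage-wise record counts are logged; all intermediate tables
#' and the final differential-abundance table are written when `out_dir` is
#' given.
#'
#' @param peptides either a named list of per-sample peptide-record data
#'   frames or the path of a manifest TSV (see [read_manifest()]).
#' @param design study design; ignored (taken from the manifest) when
#'   `peptides` is a path.
#' @param config a [pipeline_config()].
#' @param annotation optional annotation table.
#' @param out_dir optional output directory for all stage outputs, the run
#'   log and the resolved configuration snapshot.
#' @param quiet suppress progress messages.
#' @return list with `records` (filtered, calibrated), `models`,
#'   `cluster_set` (annotated), `discovery`, `test` (see [quantify_set()]),
#'   `de` (final table) and `log` (stage-count data frame).
#' @export
run_pipeline <- function(peptides, design = NULL,
                         config = pipeline_config(),
                         annotation = NULL, out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(peptides) && length(peptides) == 1L) {
    manifest <- read_manifest(peptides)
    design <- manifest$design
    peptides <- lapply(manifest$paths, read_peptide_export)
    names(peptides) <- names(manifest$paths)
  }
  design <- split_sets(design, seed = config$seed)
  validate_study_design(design)
  say <- function(...) if (!quiet) message(sprintf(...))
  log <- list()
  note <- function(stage, count) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, count = count,
                                           stringsAsFactors = FALSE)
    say("%-28s %d", stage, count)
  }

  note("records_read", sum(vapply(peptides, nrow, integer(1))))
  peptides <- lapply(peptides, filter_peptide_records,
                     max_rank = config$max_rank,
                     allowed_confidence = config$allowed_confidence)
  note("records_after_rank_filter",
       sum(vapply(peptides, nrow, integer(1))))

  cal <- calibrate_study(peptides, design,
                         fraction = config$lowess_fraction,
                         iterations = config$lowess_iterations,
                         min_pairs = config$min_calibration_pairs)
  cs <- build_clusters(cal$peptides,
                       mass_window_ppm = config$mass_window_ppm,
                       rt_window_frac = config$rt_window_frac,
                       max_iter = config$cluster_max_iter,
                       tol = config$cluster_tol)
  note("clusters_seeded", nrow(cs$clusters))
  cs <- filter_min_members(cs, config$min_members)
  note("clusters_min_members", nrow(cs$clusters))
  cs <- annotate_clusters(cs, annotation = annotation,
                          max_ppm = config$mass_accuracy_ppm,
                          min_members = config$min_members,
                          count_by = config$protein_count_by)
  check_cluster_invariants(cs)
  note("clusters_annotated", nrow(cs$clusters))

  discovery <- quantify_set(cs, design, "discovery",
                            min_fraction = config$detection_fraction,
                            apply_filter = TRUE)
  note("peptides_discovery", nrow(discovery$peptide$area))
  note("proteins_discovery", nrow(discovery$protein$matrix))
  test <- quantify_set(cs, design, "test",
                       min_fraction = config$detection_fraction,
                       apply_filter = FALSE)
  note("proteins_test", nrow(test$protein$matrix))

  de <- de_filter(discovery$protein,
                  min_peptides = config$min_peptides,
                  alpha = config$alpha, fold = config$fold,
                  mode = config$mw_mode)
  de <- verify_in_test(de, test$protein, fold = config$fold,
                       alpha = config$alpha, mode = config$mw_mode)
  if (!is.null(annotation)) {
    idx <- match(de$accession, annotation$accession)
    de <- cbind(de[, "accession", drop = FALSE],
                protein_name = ifelse(is.na(idx), "",
                                      annotation$protein_name[idx]),
                de[, setdiff(names(de), "accession"), drop = FALSE])
  }
  note("proteins_de_discovery", sum(de$is_de_discovery))
  note("proteins_verified_test", sum(de$is_verified_test))
  note("proteins_significant_test", sum(de$is_significant_test))

  log_df <- do.call(rbind, log)
  result <- list(records = cal$peptides, models = cal$models,
                 cluster_set = cs, discovery = discovery, test = test,
                 de = de, design = design, log = log_df)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pipeline_config(config, file.path(out_dir, "config.yaml"))
    write_study_design(design, file.path(out_dir, "design.tsv"))
    for (sid in names(cal$peptides)) {
      write_peptide_export(cal$peptides[[sid]][, PEPTIDE_COLUMNS],
                           file.path(out_dir,
                                     paste0("calibrated_", sid, ".tsv")))
    }
    calrep <- data.frame(
      sample_id = names(cal$models),
      n_pairs = vapply(cal$models, function(m) as.integer(m$n_pairs),
                       integer(1)),
      median_abs_residual = vapply(cal$models,
                                   function(m) m$median_abs_residual,
                                   numeric(1)),
      stringsAsFactors = FALSE
    )
    tsv_write(calrep, file.path(out_dir, "calibration_report.tsv"))
    write_cluster_list(as_cluster_list(cs),
                       file.path(out_dir, "cluster_list.tsv"))
    for (res in list(discovery, test)) {
      set <- res$protein$set
      write_abundance_matrix(res$peptide$area,
                             file.path(out_dir,
                                       paste0("peptide_", set, ".tsv")),
                             id_name = "cluster_id")
      write_abundance_matrix(res$protein$matrix,
                             file.path(out_dir,
                                       paste0("protein_", set, ".tsv")),
                             id_name = "accession",
                             peptide_count = res$protein$peptide_count)
    }
    write_de_table(de, file.path(out_dir, "de_table.tsv"))
    tsv_write(log_df, file.path(out_dir, "run_log.tsv"))
  }
  result
}
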