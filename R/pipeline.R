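# End-to-end orchestration: simulate or ingest a cohort, classify it with
# the two-stage FD rule, cluster it, and write CSV/JSON artifacts plus a
# reproducibility manifest.

#' Run the full analysis pipeline
#'
#' Obtains a lesion-record table (`id, diagnosis, fd`) either by simulating a
#' cohort (`cohort_spec`) or by batch image analysis (`image_dir` plus
#' `labels`), then applies the two-stage FD screen and the K-means stage,
#' writing every artifact and a JSON manifest (parameters, input hashes,
#' package version, seeds) into `out_dir`.
#'
#' @param out_dir Output directory, created if missing.
#' @param cohort_spec Simulation spec for [make_cohort()]; default
#'   [default_cohort_spec()]. Ignored when `image_dir` is given.
#' @param image_dir Directory of lesion images for [estimate_fd_batch()].
#' @param labels Label table (path or data frame) for the image branch.
#' @param t_malignant,t_melanoma Cutoffs for [screen_cohort()].
#' @param k,restarts Clustering parameters for [kmeans_stage()].
#' @param scheme Grouping scheme name used for the clustering label encoding
#'   and the composition report.
#' @param scaling,fd_only Passed to [kmeans_stage()].
#' @param seed Master seed; the simulation and clustering seeds derive from
#'   it and are recorded in the manifest.
#' @return Invisibly, a list with `records`, `screen`, `model`, `report`,
#'   `paths`.
#' @export
run_pipeline <- function(out_dir, cohort_spec = default_cohort_spec(),
                         image_dir = NULL, labels = NULL,
                         t_malignant = 1.74, t_melanoma = 1.755,
                         k = 2L, restarts = 100L,
                         scheme = "benign_malignant",
                         scaling = "standardized", fd_only = FALSE,
                         seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  input_hashes <- character()
  if (!is.null(image_dir)) {
    if (is.character(labels) && !file.exists(labels)) {
      stop_ingest(paste0("label table not found: ", labels))
    }
    records <- estimate_fd_batch(image_dir, labels = labels)
    records <- dplyr::rename(records, id = "image_id")
    files <- list.files(image_dir, full.names = TRUE)
    input_hashes <- as.character(tools::md5sum(files))
    names(input_hashes) <- basename(files)
  } else {
    records <- make_cohort(cohort_spec, seed = seed)
  }
  screen <- screen_cohort(records, t_malignant, t_melanoma)
  grouped <- assign_groups(records, scheme)
  features <- encode_labels(grouped, label_col = "group")
  model <- kmeans_stage(features, k = k, restarts = restarts,
                        seed = seed + 1L, scaling = scaling,
                        fd_only = fd_only)
  report <- cluster_report(model, grouped, scheme = scheme)
  calls <- decide_lesion(records$fd, t_malignant, t_melanoma)
  records_out <- dplyr::bind_cols(
    grouped, calls[c("stage1", "stage2")],
    tibble(cluster = model$assignments$cluster))

  paths <- list(records = file.path(out_dir, "records.csv"),
                screen = file.path(out_dir, "screen.csv"),
                clusters = file.path(out_dir, "clusters.csv"),
                metrics = file.path(out_dir, "metrics.json"),
                manifest = file.path(out_dir, "manifest.json"))
  readr::write_csv(records_out, paths$records)
  readr::write_csv(screen, paths$screen)
  readr::write_csv(report, paths$clusters)
  jsonlite::write_json(
    list(inertia = model$inertia, silhouette = model$silhouette,
         purity = setNames(as.list(report$purity),
                           paste0("cluster_", report$cluster))),
    paths$metrics, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "lesionfd",
    version = as.character(utils::packageVersion("lesionfd")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    parameters = list(
      t_malignant = t_malignant, t_melanoma = t_melanoma, k = k,
      restarts = restarts, scheme = scheme, scaling = scaling,
      fd_only = fd_only, seed = seed, clustering_seed = seed + 1L,
      source = if (is.null(image_dir)) "simulated" else "images"),
    cohort_spec = if (is.null(image_dir)) cohort_spec else NULL,
    input_hashes = as.list(input_hashes))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(records = records_out, screen = screen, model = model,
                 report = report, paths = paths))
}
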