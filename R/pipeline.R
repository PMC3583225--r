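#' Pipeline configuration
#'
#' Collects every input path and parameter for an end-to-end run:
#' screening, per-gene image extraction, deep-ratio validation, clustering
#' and zone summary. The configuration round-trips through YAML/JSON
#' unchanged ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param expression_tsv TSV of log2 RMA values (genes x samples, first
#'   column `gene_id`).
#' @param samples_tsv Two-column TSV `sample_id`, `group`.
#' @param images_dir Directory with one `<gene_id>.png` and
#'   `<gene_id>.roi.json` per gene.
#' @param controls_txt Optional one-column file of negative-control gene
#'   ids (used to derive the threshold when `threshold` is `NULL`).
#' @param annotations_tsv Optional TSV `gene_id`, `term`.
#' @param target_group,reference_group Group labels for the screen.
#' @param threshold Log2 eligibility threshold; `NULL` derives it from the
#'   controls.
#' @param fold_cutoff Linear fold cutoff (default 3).
#' @param density_mode `"linear"` or `"log10"` optical density.
#' @param variant Profile variant for validation/clustering.
#' @param linkage,k Clustering parameters.
#' @param zones A [zone_map()] (serialized as bin lists).
#' @param missing_image `"skip"` (record and exclude, the default) or
#'   `"fail"`.
#' @param seed Integer top-level seed (stages derive their own from it).
#' @param outdir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression_tsv, samples_tsv, images_dir,
                            controls_txt = NULL, annotations_tsv = NULL,
                            target_group = "gfp_pos",
                            reference_group = "gfp_neg",
                            threshold = NULL, fold_cutoff = 3,
                            density_mode = "linear", variant = "smoothed",
                            linkage = "average", k = 3,
                            zones = zone_map(), missing_image = "skip",
                            seed = 1, outdir = "qispr_out") {
  stopifnot(missing_image %in% c("skip", "fail"))
  structure(
    list(expression_tsv = expression_tsv, samples_tsv = samples_tsv,
         images_dir = images_dir, controls_txt = controls_txt,
         annotations_tsv = annotations_tsv,
         target_group = target_group, reference_group = reference_group,
         threshold = threshold, fold_cutoff = fold_cutoff,
         density_mode = density_mode, variant = variant,
         linkage = linkage, k = k,
         zones = lapply(unclass(zones), as.integer),
         missing_image = missing_image,
         seed = as.integer(seed), outdir = outdir),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$zones <- do.call(zone_map, lapply(x$zones, as.integer))
  do.call(pipeline_config, x[!vapply(x, is.null, TRUE)])
}

#' Run the full QISP pipeline
#'
#' Executes the stages in order: screen the expression matrix (deriving
#' the threshold from controls if not given); extract a QISP from each
#' up-regulated gene's image; validate by deep ratio; cluster the valid
#' profiles and assign laminar zones; summarize zone composition. Genes
#' without an image are recorded as unvalidatable and excluded (policy
#' `"skip"`) or abort the run (`"fail"`). A JSON manifest records
#' parameters, seed and per-stage counts; identical config and seed give
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `screen`, `qisps`, `validation`,
#'   `clusters`, `zone_summary` and `manifest`; all stage outputs are also
#'   written under `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$expression_tsv, config$samples_tsv, config$images_dir,
              config$controls_txt, config$annotations_tsv)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  expression <- tibble::as_tibble(
    utils::read.delim(config$expression_tsv, check.names = FALSE))
  samples <- tibble::as_tibble(
    utils::read.delim(config$samples_tsv, check.names = FALSE))

  threshold <- config$threshold
  if (is.null(threshold)) {
    if (is.null(config$controls_txt)) {
      stop("either threshold or controls_txt must be given", call. = FALSE)
    }
    controls <- readLines(config$controls_txt)
    target_samples <- samples$sample_id[samples$group == config$target_group]
    ctrl_vals <- unlist(
      expression[expression$gene_id %in% controls, target_samples])
    threshold <- derive_threshold(ctrl_vals)
  }

  screen <- screen_genes(expression, samples, config$target_group,
                         config$reference_group, threshold,
                         config$fold_cutoff)
  up <- screen_hits(screen, "up")

  img_path <- function(g) file.path(config$images_dir, paste0(g, ".png"))
  roi_path <- function(g) file.path(config$images_dir, paste0(g, ".roi.json"))
  has_image <- vapply(up, function(g) {
    file.exists(img_path(g)) && file.exists(roi_path(g))
  }, logical(1))
  if (any(!has_image) && config$missing_image == "fail") {
    stop("missing image for gene(s): ",
         paste(up[!has_image], collapse = ", "), call. = FALSE)
  }
  imaged <- up[has_image]
  missing <- up[!has_image]

  qisps <- purrr::map_dfr(imaged, function(g) {
    extract_qisp(read_ish_png(img_path(g)), read_roi_json(roi_path(g)),
                 g, mode = config$density_mode)
  })
  class(qisps) <- c("qisp", class(tibble::tibble()))

  validation <- validate_qisps(qisps, variant = config$variant)
  valid_ids <- validation$gene_id[validation$valid]

  clusters <- cluster_qisps(qisps[qisps$gene_id %in% valid_ids, ],
                            k = config$k, variant = config$variant,
                            linkage = config$linkage,
                            zones = do.call(zone_map, config$zones))
  zone_summary <- group_summary(clusters$labels$zone)

  manifest <- list(
    seed = config$seed,
    threshold = threshold,
    fold_cutoff = config$fold_cutoff,
    k = config$k, linkage = config$linkage,
    density_mode = config$density_mode, variant = config$variant,
    counts = list(
      genes_screened = nrow(screen),
      eligible = sum(screen$eligible),
      up = length(up), down = length(screen_hits(screen, "down")),
      imaged = length(imaged), missing_image = length(missing),
      valid = length(valid_ids),
      invalid = length(imaged) - length(valid_ids),
      clustered = sum(!is.na(clusters$labels$cluster)),
      zones = as.list(stats::setNames(zone_summary$n, zone_summary$zone))
    ),
    missing_image_genes = missing,
    package_version = as.character(utils::packageVersion("qispr"))
  )

  out <- config$outdir
  utils::write.table(tidy(screen), file.path(out, "screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(glance(screen), file.path(out, "screen_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_qisp_tsv(qisps, file.path(out, "qisps.tsv"))
  utils::write.table(validation, file.path(out, "validation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(clusters$labels, file.path(out, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cluster = rownames(clusters$centroids),
               zone = clusters$zone_of_cluster, clusters$centroids,
               check.names = FALSE),
    file.path(out, "centroids.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  export_newick(clusters, file.path(out, "tree.nwk"))
  utils::write.table(zone_summary, file.path(out, "zone_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(screen = screen, qisps = qisps, validation = validation,
                 clusters = clusters, zone_summary = zone_summary,
                 manifest = manifest))
}

#' Write a complete miniature demo study to disk
#'
#' Generates a small, fully self-contained dataset — expression TSV with
#' group labels and negative controls, one rendered ISH image plus ROI
#' JSON per gene, an annotation table, and the ground-truth bundle — sized
#' to run the whole pipeline in seconds.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed; the file set is deterministic under it.
#' @param n_genes Number of truth genes.
#' @param archetype_mix Named archetype proportions.
#' @param n_controls Negative-control genes.
#' @param render A [render_params()].
#' @param replicate_sd Expression replicate noise (log2 units).
#' @return Invisibly, a list with the generated `truth`, a ready
#'   [pipeline_config()] pointing at the files, and the config path.
#' @export
make_demo_dataset <- function(outdir, seed = 0, n_genes = 60,
                              archetype_mix = c(vz_peak = 0.3, iz_peak = 0.3,
                                                cp_peak = 0.3,
                                                deep_invalid = 0.1),
                              n_controls = 10,
                              render = render_params(),
                              replicate_sd = 0.25) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  img_dir <- file.path(outdir, "images")
  dir.create(img_dir, showWarnings = FALSE)

  seed <- as.integer(seed)
  truth <- generate_truth_profiles(n_genes, archetype_mix, seed = seed)
  expr <- generate_expression_matrix(truth, n_controls = n_controls,
                                     replicate_sd = replicate_sd,
                                     seed = seed + 1L)

  utils::write.table(expr$expression, file.path(outdir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$samples, file.path(outdir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(expr$controls, file.path(outdir, "controls.txt"))
  write_truth_bundle(truth, file.path(outdir, "truth.tsv"))

  anno <- tibble::tibble(
    gene_id = truth$genes$gene_id,
    term = paste0("archetype ", truth$genes$archetype)
  )
  utils::write.table(anno, file.path(outdir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  profs <- truth_profile_matrix(truth)
  for (i in seq_len(n_genes)) {
    g <- truth$genes$gene_id[i]
    r <- render_ish_image(profs[i, ], render, seed = seed + 100L + i)
    write_ish_png(r$image, file.path(img_dir, paste0(g, ".png")))
    write_roi_json(r$roi, file.path(img_dir, paste0(g, ".roi.json")))
  }

  n_arch <- length(setdiff(names(archetype_mix)[archetype_mix > 0],
                           c("deep_invalid", "flat")))
  config <- pipeline_config(
    expression_tsv = file.path(outdir, "expression.tsv"),
    samples_tsv = file.path(outdir, "samples.tsv"),
    images_dir = img_dir,
    controls_txt = file.path(outdir, "controls.txt"),
    annotations_tsv = file.path(outdir, "annotations.tsv"),
    k = max(2L, n_arch), seed = seed,
    outdir = file.path(outdir, "results")
  )
  config_path <- file.path(outdir, "config.yaml")
  write_pipeline_config(config, config_path)
  invisible(list(truth = truth, config = config, config_path = config_path))
}
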