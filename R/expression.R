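#' Derive the "not expressed" RMA threshold from negative controls
#'
#' Genes known to be silent in the profiled tissue (e.g. eye-specific
#' genes in embryonic cortex) provide an internal standard: the threshold
#' is their mean plus `multiplier` sample standard deviations, rounded up
#' to the nearest multiple of `grain`. With the canonical internal
#' standard of mean 5.5 and SD 0.7 log2 units, the default rule yields
#' 5.5 + 2 x 0.7 = 6.9, rounded up to 7.0.
#'
#' @param control_rmas Numeric vector of log2-scale RMA values for the
#'   negative-control genes (at least 2, so the SD is defined).
#' @param multiplier SD multiplier, default 2.
#' @param grain Rounding grain in log2 units, default 0.5 (round up).
#' @return The threshold, a single number in log2 RMA units.
#' @export
#' @examples
#' derive_threshold(c(4.0, 6.0))  # mean 5, SD 1.41 -> 7.83 -> 8.0
derive_threshold <- function(control_rmas, multiplier = 2, grain = 0.5) {
  if (length(control_rmas) < 2) {
    stop("need at least 2 control values (sample SD undefined otherwise)",
         call. = FALSE)
  }
  stopifnot(grain > 0)
  x <- mean(control_rmas) + multiplier * stats::sd(control_rmas)
  ceiling(x / grain) * grain
}

#' Linear fold change between two log2 RMA values
#'
#' RMA values are log2-scale, so their difference is a log2 fold-change:
#' the linear fold is `2^(rma_target - rma_reference)`. Values above 1
#' mean up-regulation in the target.
#'
#' @param rma_target,rma_reference Log2-scale expression values.
#' @return Linear fold change (> 0).
#' @export
#' @examples
#' fold_change(7.0, 5.5)  # 2.83
fold_change <- function(rma_target, rma_reference) {
  2^(rma_target - rma_reference)
}

#' Screen an expression matrix for fold-regulated genes
#'
#' Computes per-gene group means on the log2 scale; a gene is eligible
#' when the larger of the two group means reaches `threshold` (so genes
#' genuinely expressed in either population are kept, while
#' never-expressed genes are excluded). Eligible genes with linear fold
#' (target over reference) at or above `fold_cutoff` are up-regulated;
#' those at or below `1/fold_cutoff` are down-regulated. Ties at exactly
#' the cutoff are included.
#'
#' @param expression Tibble/data frame with a `gene_id` column and one
#'   numeric column per sample (log2 RMA values).
#' @param samples Tibble with columns `sample_id` and `group` covering
#'   every sample column of `expression`.
#' @param target_group,reference_group Group labels to compare (fold =
#'   target over reference).
#' @param threshold Log2 eligibility threshold (e.g. from
#'   [derive_threshold()]).
#' @param fold_cutoff Linear fold cutoff, default 3.
#' @return A tibble of class `qisp_screen`, one row per gene, sorted by
#'   descending |log2 fold|: `gene_id`, `mean_target`, `mean_reference`,
#'   `log2fc`, `fold`, `eligible`, `direction` (`"up"`, `"down"` or
#'   `"none"`; ineligible genes are always `"none"`). Attributes record
#'   threshold, cutoff and groups; see [tidy()]/[glance()].
#' @export
screen_genes <- function(expression, samples, target_group, reference_group,
                         threshold, fold_cutoff = 3) {
  stopifnot(is.data.frame(expression), "gene_id" %in% names(expression),
            all(c("sample_id", "group") %in% names(samples)),
            fold_cutoff > 0)
  sample_cols <- setdiff(names(expression), "gene_id")
  missing <- setdiff(sample_cols, samples$sample_id)
  if (length(missing) > 0) {
    stop("samples table lacks group labels for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyNA(expression[sample_cols])) {
    stop("expression matrix contains missing values", call. = FALSE)
  }
  grp <- stats::setNames(samples$group, samples$sample_id)[sample_cols]
  for (g in c(target_group, reference_group)) {
    if (!any(grp == g)) stop("group not present in samples: ", g, call. = FALSE)
  }
  m <- as.matrix(expression[sample_cols])
  mean_t <- rowMeans(m[, grp == target_group, drop = FALSE])
  mean_r <- rowMeans(m[, grp == reference_group, drop = FALSE])
  log2fc <- mean_t - mean_r
  fold <- 2^log2fc
  eligible <- pmax(mean_t, mean_r) >= threshold
  direction <- dplyr::case_when(
    !eligible ~ "none",
    fold >= fold_cutoff ~ "up",
    fold <= 1 / fold_cutoff ~ "down",
    TRUE ~ "none"
  )
  out <- tibble::tibble(
    gene_id = expression$gene_id,
    mean_target = mean_t, mean_reference = mean_r,
    log2fc = log2fc, fold = fold,
    eligible = eligible, direction = direction
  )
  out <- out[order(-abs(out$log2fc), out$gene_id), ]
  structure(out,
            class = c("qisp_screen", class(tibble::tibble())),
            threshold = threshold, fold_cutoff = fold_cutoff,
            target_group = target_group, reference_group = reference_group)
}

#' Up- or down-regulated gene ids from a screen
#'
#' @param screen A `qisp_screen` tibble.
#' @param direction `"up"` or `"down"`.
#' @return Character vector of gene ids, in screen order (descending
#'   |log2 fold|).
#' @export
screen_hits <- function(screen, direction = c("up", "down")) {
  direction <- match.arg(direction)
  screen$gene_id[screen$direction == direction]
}

#' @export
tidy.qisp_screen <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "threshold") <- NULL
  attr(out, "fold_cutoff") <- NULL
  attr(out, "target_group") <- NULL
  attr(out, "reference_group") <- NULL
  out
}

#' @export
glance.qisp_screen <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_eligible = sum(x$eligible),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    threshold = attr(x, "threshold"),
    fold_cutoff = attr(x, "fold_cutoff"),
    target_group = attr(x, "target_group"),
    reference_group = attr(x, "reference_group")
  )
}

#' Generate a synthetic expression matrix with planted fold-changes
#'
#' Each truth gene gets a reference-group expression level drawn around a
#' gene-level mean (well above the "not expressed" baseline, so planted
#' effects are screenable), and target-group values offset by its planted
#' log2 fold-change; replicate noise is Gaussian on the log2 scale.
#' Negative-control genes are drawn i.i.d. from
#' Normal(baseline_mean, baseline_sd) in every sample, emulating an
#' internal standard of genes not expressed in the tissue.
#'
#' @param truth A `qisp_truth` bundle ([generate_truth_profiles()]).
#' @param baseline_mean,baseline_sd "Not expressed" baseline in log2 RMA
#'   units; defaults 5.5 and 0.7.
#' @param n_controls Number of negative-control genes.
#' @param replicate_sd Per-sample Gaussian noise SD (log2 units).
#' @param n_reps_per_group Samples per group (>= 1); default 3.
#' @param expressed_mean,expressed_sd Distribution of reference-group
#'   gene-level means for truth genes.
#' @param target_group,reference_group Group labels.
#' @param seed Integer seed; output is deterministic under it.
#' @return List with `expression` (tibble: gene_id + one column per
#'   sample), `samples` (tibble: sample_id, group) and `controls`
#'   (character vector of control gene ids).
#' @export
generate_expression_matrix <- function(truth,
                                       baseline_mean = 5.5,
                                       baseline_sd = 0.7,
                                       n_controls = 10,
                                       replicate_sd = 0.25,
                                       n_reps_per_group = 3,
                                       expressed_mean = 9,
                                       expressed_sd = 0.8,
                                       target_group = "gfp_pos",
                                       reference_group = "gfp_neg",
                                       seed = 1) {
  stopifnot(inherits(truth, "qisp_truth"), n_reps_per_group >= 1,
            n_controls >= 0)
  if (baseline_sd < 0) stop("baseline_sd must be non-negative", call. = FALSE)

  n_genes <- nrow(truth$genes)
  ctrl_ids <- if (n_controls > 0) {
    sprintf("control_%03d", seq_len(n_controls))
  } else {
    character()
  }
  samp <- tibble::tibble(
    sample_id = c(paste0(target_group, "_", seq_len(n_reps_per_group)),
                  paste0(reference_group, "_", seq_len(n_reps_per_group))),
    group = rep(c(target_group, reference_group), each = n_reps_per_group)
  )
  n_samp <- nrow(samp)

  withr::with_seed(as.integer(seed), {
    mu_ref <- stats::rnorm(n_genes, expressed_mean, expressed_sd)
    noise <- matrix(stats::rnorm(n_genes * n_samp, 0, replicate_sd),
                    n_genes, n_samp)
    vals <- matrix(mu_ref, n_genes, n_samp) + noise
    is_target <- samp$group == target_group
    vals[, is_target] <- vals[, is_target] + truth$genes$log2fc
    ctrl <- if (n_controls > 0) {
      matrix(stats::rnorm(n_controls * n_samp, baseline_mean, baseline_sd),
             n_controls, n_samp)
    } else {
      matrix(numeric(), 0, n_samp)
    }
  })

  all_vals <- rbind(vals, ctrl)
  expr <- tibble::as_tibble(as.data.frame(all_vals),
                            .name_repair = "minimal")
  names(expr) <- samp$sample_id
  expr <- tibble::add_column(expr,
                             gene_id = c(truth$genes$gene_id, ctrl_ids),
                             .before = 1)
  list(expression = expr, samples = samp, controls = ctrl_ids)
}
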