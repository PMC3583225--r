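#' Deep ratio of a radial profile
#'
#' Ratio of the mean optical density in the two ventricular-most bins
#' (sROIs 1-2) to the mean over the remaining bins (sROIs 3-20). Profiles
#' whose signal is strongest at the deep ventricular surface — a pattern
#' inconsistent with the differentiating excitatory-neuron lineage, which
#' by this stage has moved superficially — have a ratio above 1. The ratio
#' is invariant to multiplying the profile by any positive scalar.
#'
#' @param qisp A `qisp` tibble for one gene, or a numeric 20-vector.
#' @param variant Which profile variant to use when a tibble is given;
#'   default `"smoothed"`.
#' @return A non-negative number, or `NA` when the superficial mean is
#'   zero (no superficial signal: the ratio is undefined and the gene is
#'   treated as invalid downstream).
#' @export
#' @examples
#' deep_ratio(c(2, 2, rep(1, 18)))  # 2
deep_ratio <- function(qisp, variant = c("smoothed", "corrected", "raw")) {
  variant <- match.arg(variant)
  p <- if (is.numeric(qisp)) {
    stopifnot(length(qisp) == 20)
    qisp
  } else {
    qisp_vector(qisp, variant = variant)
  }
  deep <- mean(p[1:2])
  sup <- mean(p[3:20])
  if (sup == 0) return(NA_real_)
  deep / sup
}

#' Validate QISPs with the deep-ratio criterion
#'
#' A gene is invalid when its deep ratio strictly exceeds 1.0 (expression
#' strongest in the deep ventricular zone) or is undefined (no superficial
#' signal at all). A ratio of exactly 1.0 — e.g. a uniform profile — is
#' valid. Counts of input, flagged and retained genes are reported as a
#' message.
#'
#' @param qisps A `qisp` tibble covering one or more genes.
#' @param variant Profile variant fed to [deep_ratio()]; default smoothed.
#' @return A tibble with one row per gene: `gene_id`, `deep_ratio`,
#'   `valid`, `reason` (`NA` for valid genes). Retained genes are
#'   `dplyr::filter(report, valid)`.
#' @export
validate_qisps <- function(qisps, variant = c("smoothed", "corrected", "raw")) {
  variant <- match.arg(variant)
  ids <- unique(qisps$gene_id)
  if (length(ids) == 0) {
    return(tibble::tibble(gene_id = character(), deep_ratio = numeric(),
                          valid = logical(), reason = character()))
  }
  ratios <- vapply(ids, function(g) {
    deep_ratio(qisps[qisps$gene_id == g, ], variant = variant)
  }, numeric(1))
  valid <- unname(!is.na(ratios) & ratios <= 1.0)
  reason <- dplyr::case_when(
    is.na(ratios) ~ "no superficial signal",
    ratios > 1.0 ~ "deep ratio exceeds 1.0",
    TRUE ~ NA_character_
  )
  report <- tibble::tibble(gene_id = ids, deep_ratio = unname(ratios),
                           valid = valid, reason = reason)
  message(sprintf("validate_qisps: %d genes in, %d flagged invalid, %d retained",
                  length(ids), sum(!valid), sum(valid)))
  report
}

#' Replicate concordance of repeated QISP measurements
#'
#' Computes all pairwise Pearson correlations between replicate 20-bin
#' profiles of the same gene, the per-replicate peak sROI, and the largest
#' pairwise peak displacement. Replicates with zero variance have
#' undefined correlations; these are reported as `NA`, excluded from the
#' summary statistics, and flagged with a warning.
#'
#' @param qisps A `qisp` tibble whose gene ids identify replicates, or a
#'   list of numeric 20-vectors.
#' @param variant Profile variant; default smoothed.
#' @return An object of class `qisp_concordance`: list with `pairwise_r`
#'   (symmetric matrix, unit diagonal), `r_min`, `r_max`, `r_mean` (upper
#'   triangle only), `peak_srois` (per-replicate argmax) and
#'   `max_peak_deviation` (sROI units).
#' @export
replicate_concordance <- function(qisps,
                                  variant = c("smoothed", "corrected", "raw")) {
  variant <- match.arg(variant)
  profs <- if (is.list(qisps) && !is.data.frame(qisps)) {
    stopifnot(all(vapply(qisps, length, 1L) == 20))
    m <- do.call(rbind, lapply(qisps, as.numeric))
    rownames(m) <- names(qisps) %||% sprintf("rep_%d", seq_along(qisps))
    m
  } else {
    ids <- unique(qisps$gene_id)
    m <- t(vapply(ids, function(g) qisp_vector(qisps, g, variant), numeric(20)))
    rownames(m) <- ids
    m
  }
  n <- nrow(profs)
  if (n < 2) stop("need at least 2 replicates", call. = FALSE)

  sds <- apply(profs, 1, stats::sd)
  if (any(sds == 0)) {
    warning("replicate(s) with zero variance: ",
            paste(rownames(profs)[sds == 0], collapse = ", "),
            "; their correlations are undefined and excluded from r_mean")
  }
  r <- suppressWarnings(stats::cor(t(profs)))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  upper <- r[upper.tri(r)]
  peaks <- apply(profs, 1, which.max)
  structure(
    list(pairwise_r = r,
         r_min = min(upper, na.rm = TRUE),
         r_max = max(upper, na.rm = TRUE),
         r_mean = mean(upper, na.rm = TRUE),
         peak_srois = peaks,
         max_peak_deviation = max(stats::dist(peaks))),
    class = "qisp_concordance"
  )
}

#' @export
print.qisp_concordance <- function(x, ...) {
  cat(sprintf(
    "<qisp_concordance> %d replicates: r in [%.3f, %.3f], mean %.3f; max peak deviation %d sROI\n",
    nrow(x$pairwise_r), x$r_min, x$r_max, x$r_mean,
    as.integer(x$max_peak_deviation)))
  invisible(x)
}

#' @export
tidy.qisp_concordance <- function(x, ...) {
  n <- nrow(x$pairwise_r)
  idx <- which(upper.tri(x$pairwise_r), arr.ind = TRUE)
  tibble::tibble(
    rep_a = rownames(x$pairwise_r)[idx[, 1]],
    rep_b = rownames(x$pairwise_r)[idx[, 2]],
    r = x$pairwise_r[upper.tri(x$pairwise_r)]
  )
}

#' @export
glance.qisp_concordance <- function(x, ...) {
  tibble::tibble(n_replicates = nrow(x$pairwise_r), r_min = x$r_min,
                 r_max = x$r_max, r_mean = x$r_mean,
                 max_peak_deviation = as.integer(x$max_peak_deviation))
}
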