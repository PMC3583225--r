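#' Radial expression archetypes
#'
#' An archetype is a parameterised shape for a gene's radial expression
#' profile across the 20 sub-regions of interest (sROIs) spanning the
#' cerebral wall, sROI 1 at the ventricular surface and sROI 20 at the pial
#' surface. Profiles are sums of Gaussian bumps on the sROI axis, which
#' covers the qualitative pattern classes seen in embryonic cortex:
#' single peaks in the ventricular zone (VZ), intermediate zone (IZ) or
#' cortical plate (CP), Dab1-like dual VZ+CP peaks, VZ-dominant
#' ("deep-invalid") patterns that fail the deep-ratio criterion, and flat
#' (uniform) expression.
#'
#' @param name Archetype label.
#' @param peak_positions Numeric vector of peak centres on the 1-20 sROI
#'   axis (1 = ventricular surface).
#' @param peak_widths Gaussian SDs in sROI units, one per peak.
#' @param amplitudes Non-negative peak amplitudes in optical-density units,
#'   one per peak.
#' @param baseline Constant optical density added to every bin (used by the
#'   `flat` archetype).
#' @return An object of class `archetype_spec`.
#' @export
#' @examples
#' spec <- archetype_spec("cp_peak", peak_positions = 18,
#'                        peak_widths = 2, amplitudes = 0.6)
#' archetype_profile(spec)
archetype_spec <- function(name, peak_positions = numeric(),
                           peak_widths = numeric(), amplitudes = numeric(),
                           baseline = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(peak_positions) > 0) {
    if (any(peak_positions < 1 | peak_positions > 20)) {
      stop("every peak position must lie in [1, 20]", call. = FALSE)
    }
    if (length(peak_widths) != length(peak_positions) ||
        length(amplitudes) != length(peak_positions)) {
      stop("peak_widths and amplitudes must match peak_positions in length",
           call. = FALSE)
    }
    if (any(peak_widths <= 0)) stop("peak widths must be positive", call. = FALSE)
    if (any(amplitudes < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  }
  if (baseline < 0) stop("baseline must be non-negative", call. = FALSE)
  structure(
    list(name = name, peak_positions = peak_positions,
         peak_widths = peak_widths, amplitudes = amplitudes,
         baseline = baseline),
    class = "archetype_spec"
  )
}

#' Noise-free profile of an archetype
#'
#' Evaluates the sum-of-Gaussians shape on the integer sROI grid 1..20.
#'
#' @param spec An [archetype_spec()].
#' @param amplitude_scale Multiplier applied to the whole profile (per-gene
#'   amplitude jitter uses this).
#' @return Numeric 20-vector of non-negative optical densities.
#' @export
archetype_profile <- function(spec, amplitude_scale = 1) {
  stopifnot(inherits(spec, "archetype_spec"), amplitude_scale >= 0)
  x <- seq_len(20)
  p <- rep(spec$baseline, 20)
  for (j in seq_along(spec$peak_positions)) {
    p <- p + spec$amplitudes[j] *
      exp(-((x - spec$peak_positions[j])^2) / (2 * spec$peak_widths[j]^2))
  }
  p * amplitude_scale
}

#' Default archetype vocabulary
#'
#' Six built-in shapes. Peak placements respect the laminar geometry used
#' throughout the package (deep = sROIs 1-10, middle = 11-15, upper =
#' 16-20): `vz_peak` at sROI 6, `iz_peak` at 12, `cp_peak` at 18,
#' `dual_peak` at 4 and 17 (Dab1-like), `deep_invalid` at sROI 1 (a
#' VZ-surface-dominant pattern whose deep ratio exceeds 1), and `flat`
#' (constant). All non-`deep_invalid` archetypes have a noise-free deep
#' ratio (mean sROIs 1-2 over mean sROIs 3-20) at or below 1.
#'
#' @return Named list of [archetype_spec()] objects.
#' @export
default_archetypes <- function() {
  list(
    vz_peak      = archetype_spec("vz_peak", 6, 2, 0.6),
    iz_peak      = archetype_spec("iz_peak", 12, 2, 0.6),
    cp_peak      = archetype_spec("cp_peak", 18, 2, 0.6),
    dual_peak    = archetype_spec("dual_peak", c(5, 17), c(1.8, 1.8), c(0.5, 0.6)),
    deep_invalid = archetype_spec("deep_invalid", 1, 1.2, 0.6),
    flat         = archetype_spec("flat", baseline = 0.4)
  )
}

#' Largest-remainder apportionment of counts
#'
#' Deterministically converts proportions into integer counts summing to
#' `n`: floors each quota, then distributes the remaining units to the
#' largest fractional remainders (ties to earlier entries).
#'
#' @param n Total count.
#' @param proportions Named numeric vector summing to 1.
#' @return Named integer vector summing to `n`.
#' @keywords internal
largest_remainder <- function(n, proportions) {
  quotas <- n * proportions
  base <- floor(quotas)
  rem <- quotas - base
  left <- n - sum(base)
  if (left > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}

#' Generate ground-truth radial profiles
#'
#' Draws a synthetic cohort of genes with known archetype memberships,
#' noise-free 20-bin radial profiles (with small per-gene multiplicative
#' amplitude jitter) and planted log2 fold-changes. This is the ground
#' truth against which screening, extraction, validation and clustering
#' are checked.
#'
#' @param n_genes Number of genes (>= 1).
#' @param archetype_mix Named numeric vector of archetype proportions
#'   (names must be archetypes in `archetypes`); must sum to 1 within 1e-9.
#'   Counts are apportioned by largest remainder, so totals are exact.
#' @param seed Integer seed; the same arguments and seed reproduce the
#'   bundle bit-for-bit.
#' @param archetypes Archetype vocabulary, default [default_archetypes()].
#' @param amplitude_jitter_sd SD of the per-gene log-normal amplitude
#'   jitter (0 disables it).
#' @param log2fc_range Range from which each gene's planted log2
#'   fold-change (target minus reference group) is drawn uniformly.
#' @return A `qisp_truth` object: list with `genes` (tibble: gene_id,
#'   archetype, log2fc), `profiles` (long tibble: gene_id, sroi, density),
#'   and `seed`.
#' @export
#' @examples
#' truth <- generate_truth_profiles(
#'   30, c(vz_peak = 1 / 3, iz_peak = 1 / 3, cp_peak = 1 / 3), seed = 1)
#' dplyr::count(truth$genes, archetype)
generate_truth_profiles <- function(n_genes, archetype_mix, seed,
                                    archetypes = default_archetypes(),
                                    amplitude_jitter_sd = 0.1,
                                    log2fc_range = c(log2(3) + 0.2, 6)) {
  stopifnot(n_genes >= 1)
  mix <- unlist(archetype_mix)
  if (is.null(names(mix)) || any(!nzchar(names(mix)))) {
    stop("archetype_mix must be named", call. = FALSE)
  }
  unknown <- setdiff(names(mix), names(archetypes))
  if (length(unknown) > 0) {
    stop("unknown archetype name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(mix < 0)) stop("archetype proportions must be non-negative", call. = FALSE)
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("archetype proportions must sum to 1", call. = FALSE)
  }

  counts <- largest_remainder(n_genes, mix)
  arch_of <- rep(names(counts), counts)
  width <- max(3L, nchar(as.character(n_genes)))
  gene_ids <- sprintf("gene_%0*d", width, seq_len(n_genes))

  withr::with_seed(as.integer(seed), {
    scale <- if (amplitude_jitter_sd > 0) {
      exp(stats::rnorm(n_genes, 0, amplitude_jitter_sd))
    } else {
      rep(1, n_genes)
    }
    log2fc <- stats::runif(n_genes, log2fc_range[1], log2fc_range[2])
    prof <- t(vapply(
      seq_len(n_genes),
      function(i) archetype_profile(archetypes[[arch_of[i]]], scale[i]),
      numeric(20)
    ))
  })
  rownames(prof) <- gene_ids

  structure(
    list(
      genes = tibble::tibble(gene_id = gene_ids, archetype = arch_of,
                             log2fc = log2fc),
      profiles = tibble::tibble(
        gene_id = rep(gene_ids, each = 20),
        sroi = rep(seq_len(20), n_genes),
        density = as.vector(t(prof))
      ),
      seed = as.integer(seed)
    ),
    class = "qisp_truth"
  )
}

#' @export
print.qisp_truth <- function(x, ...) {
  cat("<qisp_truth> ", nrow(x$genes), " genes, seed ", x$seed, "\n", sep = "")
  print(table(x$genes$archetype))
  invisible(x)
}

#' True profiles as a gene-by-sROI matrix
#'
#' @param truth A `qisp_truth` object.
#' @return Numeric matrix, one row per gene (rownames = gene ids), 20 columns.
#' @export
truth_profile_matrix <- function(truth) {
  stopifnot(inherits(truth, "qisp_truth"))
  wide <- tidyr::pivot_wider(truth$profiles, names_from = "sroi",
                             values_from = "density")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene_id
  colnames(m) <- paste0("sroi_", seq_len(20))
  m
}

#' Write a truth bundle to disk
#'
#' Writes the profiles and memberships as one TSV (gene_id, archetype,
#' log2fc, sroi_1..sroi_20) plus a JSON sidecar recording the seed.
#'
#' @param truth A `qisp_truth` object.
#' @param path Output TSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_truth_bundle <- function(truth, path) {
  stopifnot(inherits(truth, "qisp_truth"))
  m <- truth_profile_matrix(truth)
  out <- cbind(truth$genes, as.data.frame(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = truth$seed, n_genes = nrow(truth$genes)),
    sub("\\.[^.]+$", ".json", path),
    auto_unbox = TRUE
  )
  invisible(path)
}
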