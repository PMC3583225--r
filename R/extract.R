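#' Partition the radial band into 20 sROI pixel masks
#'
#' Projects every pixel centre onto the ROI axis; pixels whose
#' perpendicular offset lies within the band are assigned to sub-region k
#' when their axial position s (in pixels from the ventricular endpoint)
#' falls in the half-open interval [round((k-1)L/20), round(kL/20)), the
#' last interval closed at L. The 20 masks are disjoint, their union is
#' the band, and segment sizes differ by at most one pixel row for any
#' axis length. Works for arbitrarily oriented (e.g. jittered, rotated)
#' axes.
#'
#' @param roi A [roi_spec()].
#' @param dim Image dimensions `c(rows, cols)`.
#' @return List of 20 integer vectors of linear pixel indices (column-major,
#'   matching R matrix indexing), ventricular segment first.
#' @export
#' @examples
#' roi <- roi_spec(c(15.5, 0.5), c(15.5, 200.5), 30, c(2, 2, 4, 4))
#' masks <- place_sroi_grid(roi, dim = c(220, 64))
#' lengths(masks)  # 20 x 300 pixels
place_sroi_grid <- function(roi, dim) {
  stopifnot(inherits(roi, "roi_spec"), length(dim) == 2)
  H <- dim[1]; W <- dim[2]
  v <- roi$pial - roi$ventricular
  L <- sqrt(sum(v^2))
  u <- v / L
  # pixel centres: x = column, y = row
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  dx <- xs - roi$ventricular[1]
  dy <- ys - roi$ventricular[2]
  s <- dx * u[1] + dy * u[2]             # axial position
  d <- -dx * u[2] + dy * u[1]            # perpendicular offset
  half <- roi$band_width_px / 2
  in_band <- d >= -half & d < half & s >= 0 & s <= L
  bounds <- round(seq_len(19) * L / 20)
  bin <- findInterval(s, bounds) + 1L    # 1..20 inside [0, L]
  masks <- lapply(seq_len(20), function(k) which(in_band & bin == k))
  if (any(lengths(masks) == 0)) {
    stop("ROI band extends outside the image or is degenerate", call. = FALSE)
  }
  masks
}

#' Mean optical density over a pixel mask
#'
#' The default `"linear"` mode is a linear absorbance proxy,
#' mean((white - I) / white), in [0, 1]; `"log10"` computes
#' mean(-log10(I / white)) with intensities floored at 1 count to avoid
#' divergence at full black.
#'
#' @param image Intensity matrix (counts).
#' @param mask Integer vector of pixel indices; must be non-empty.
#' @param white_reference Maximum intensity of the bit depth (defaults to
#'   2^bit_depth - 1 from the image's `bit_depth` attribute, else 255).
#' @param mode `"linear"` (default) or `"log10"`.
#' @return A single non-negative number.
#' @export
measure_optical_density <- function(image, mask,
                                    white_reference = NULL,
                                    mode = c("linear", "log10")) {
  mode <- match.arg(mode)
  if (length(mask) == 0) stop("mask must be non-empty", call. = FALSE)
  if (is.null(white_reference)) {
    white_reference <- 2^(attr(image, "bit_depth") %||% 8L) - 1
  }
  px <- as.numeric(image[mask])
  if (mode == "linear") {
    mean((white_reference - px) / white_reference)
  } else {
    mean(-log10(pmax(px, 1) / white_reference))
  }
}

#' Background-correct a raw profile
#'
#' Subtracts a scalar background optical density from every bin, flooring
#' at zero.
#'
#' @param raw Numeric 20-vector.
#' @param background_value Non-negative scalar.
#' @return Numeric 20-vector.
#' @export
background_correct <- function(raw, background_value) {
  stopifnot(length(raw) == 20, background_value >= 0)
  pmax(raw - background_value, 0)
}

#' Smooth a radial profile by adjacent-bin averaging
#'
#' Each interior bin is replaced by the mean of itself and its two
#' neighbours; the end bins are averaged with their single neighbour
#' (window of 2 — no padding beyond the wall). Constant profiles are fixed
#' points, monotone profiles stay monotone, and output values never leave
#' the input's range.
#'
#' @param profile Numeric 20-vector.
#' @return Numeric 20-vector.
#' @export
smooth_profile <- function(profile) {
  stopifnot(length(profile) == 20)
  n <- 20L
  out <- numeric(n)
  out[1] <- mean(profile[1:2])
  out[n] <- mean(profile[(n - 1):n])
  out[2:(n - 1)] <- (profile[1:(n - 2)] + profile[2:(n - 1)] + profile[3:n]) / 3
  out
}

#' Extract a quantified in situ pattern (QISP) from an image
#'
#' Measures the mean optical density of each of the 20 sROIs along the
#' ROI axis (ventricular to pial), measures scalar background from the
#' ROI's background rectangle, subtracts it (floored at 0), and smooths by
#' adjacent-bin averaging.
#'
#' @param image Grayscale intensity matrix (counts), e.g. from
#'   [render_ish_image()] or [read_ish_png()].
#' @param roi A [roi_spec()].
#' @param gene_id Gene label recorded in the output.
#' @param white_reference,mode Passed to [measure_optical_density()].
#' @return A tibble of class `qisp` with 20 rows and columns `gene_id`,
#'   `sroi` (1 = ventricular surface, 20 = pial), `raw`, `corrected`,
#'   `smoothed`, `background`.
#' @export
#' @examples
#' p <- archetype_profile(default_archetypes()$iz_peak)
#' r <- render_ish_image(p, render_params(noise_sd = 0), seed = 1)
#' q <- extract_qisp(r$image, r$roi, "demo")
#' q$sroi[which.max(q$smoothed)]
extract_qisp <- function(image, roi, gene_id,
                         white_reference = NULL,
                         mode = c("linear", "log10")) {
  mode <- match.arg(mode)
  masks <- place_sroi_grid(roi, dim = dim(image))
  bg <- roi$background_region
  cols <- seq(ceiling(bg[1]), floor(bg[3]))
  rows <- seq(ceiling(bg[2]), floor(bg[4]))
  if (length(rows) == 0 || length(cols) == 0 ||
      min(rows) < 1 || max(rows) > nrow(image) ||
      min(cols) < 1 || max(cols) > ncol(image)) {
    stop("background region lies outside the image", call. = FALSE)
  }
  bg_mask <- as.vector(outer(rows, (cols - 1) * nrow(image), `+`))
  background <- measure_optical_density(image, bg_mask, white_reference, mode)
  raw <- vapply(masks, function(m) {
    measure_optical_density(image, m, white_reference, mode)
  }, numeric(1))
  corrected <- background_correct(raw, background)
  out <- tibble::tibble(
    gene_id = gene_id, sroi = seq_len(20),
    raw = raw, corrected = corrected, smoothed = smooth_profile(corrected),
    background = background
  )
  class(out) <- c("qisp", class(out))
  out
}

#' Build a QISP table directly from noise-free profiles
#'
#' Treats each true profile as an already background-corrected density
#' vector (raw = corrected, background 0) and smooths it. Useful for
#' validating and clustering ground-truth profiles without rendering.
#'
#' @param profiles Numeric matrix, one row per gene with rownames as gene
#'   ids (e.g. [truth_profile_matrix()]), or a single named 20-vector.
#' @return A `qisp` tibble (20 rows per gene).
#' @export
qisp_from_profiles <- function(profiles) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  if (nrow(profiles) == 0) {
    out <- tibble::tibble(gene_id = character(), sroi = integer(),
                          raw = numeric(), corrected = numeric(),
                          smoothed = numeric(), background = numeric())
    class(out) <- c("qisp", class(out))
    return(out)
  }
  stopifnot(ncol(profiles) == 20)
  ids <- rownames(profiles) %||% sprintf("gene_%03d", seq_len(nrow(profiles)))
  out <- purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    p <- as.numeric(profiles[i, ])
    tibble::tibble(gene_id = ids[i], sroi = seq_len(20),
                   raw = p, corrected = p,
                   smoothed = smooth_profile(p), background = 0)
  })
  class(out) <- c("qisp", class(out))
  out
}

#' Write / read QISP tables as TSV
#'
#' One row per gene: gene_id, background, raw_1..raw_20,
#' corrected_1..corrected_20, smoothed_1..smoothed_20.
#'
#' @param qisps A `qisp` tibble (any number of genes).
#' @param path TSV path.
#' @return `path` invisibly for write; a `qisp` tibble for read.
#' @export
write_qisp_tsv <- function(qisps, path) {
  wide <- tidyr::pivot_wider(
    qisps,
    id_cols = c("gene_id", "background"),
    names_from = "sroi",
    values_from = c("raw", "corrected", "smoothed"),
    names_sep = "_"
  )
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qisp_tsv
#' @export
read_qisp_tsv <- function(path) {
  wide <- utils::read.delim(path, check.names = FALSE)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(wide),
    cols = -c("gene_id", "background"),
    names_to = c("variant", "sroi"),
    names_pattern = "(raw|corrected|smoothed)_(\\d+)",
    values_to = "value"
  )
  long$sroi <- as.integer(long$sroi)
  out <- tidyr::pivot_wider(long, names_from = "variant", values_from = "value")
  out <- dplyr::select(out, "gene_id", "sroi", "raw", "corrected",
                       "smoothed", "background")
  out <- dplyr::arrange(out, .data$gene_id, .data$sroi)
  class(out) <- c("qisp", class(out))
  out
}

#' One gene's profile as a numeric 20-vector
#'
#' @param qisps A `qisp` tibble.
#' @param gene_id Gene to pull (default: the single gene present).
#' @param variant `"raw"`, `"corrected"` or `"smoothed"`.
#' @return Numeric 20-vector ordered by sROI.
#' @export
qisp_vector <- function(qisps, gene_id = NULL,
                        variant = c("smoothed", "corrected", "raw")) {
  variant <- match.arg(variant)
  if (is.null(gene_id)) {
    ids <- unique(qisps$gene_id)
    if (length(ids) != 1) stop("specify gene_id: table has several genes",
                               call. = FALSE)
    gene_id <- ids
  }
  g <- qisps[qisps$gene_id == gene_id, ]
  g <- g[order(g$sroi), ]
  if (nrow(g) != 20) stop("gene ", gene_id, " does not have 20 sROIs",
                          call. = FALSE)
  g[[variant]]
}
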