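#' Standardize a radial profile for clustering
#'
#' Row-wise standardization: subtract the mean, divide by the sample SD.
#' Because the clustering distance is Pearson-based this changes no
#' distance, only the centroids; it gives every gene unit weight in the
#' cluster means. Zero-variance (constant) profiles map to the zero vector
#' and are tagged degenerate via the `"degenerate"` attribute.
#'
#' @param profile Numeric 20-vector.
#' @return Numeric 20-vector with a logical `"degenerate"` attribute.
#' @export
normalize_qisp <- function(profile) {
  stopifnot(length(profile) == 20)
  s <- stats::sd(profile)
  if (s == 0) {
    return(structure(rep(0, 20), degenerate = TRUE))
  }
  structure((profile - mean(profile)) / s, degenerate = FALSE)
}

#' Pearson correlation distance between two profiles
#'
#' `1 - r`, with `r` the sample Pearson correlation over the 20 bins, so
#' distances lie in [0, 2]: identical shapes (regardless of magnitude or
#' offset) are at distance 0, perfectly anticorrelated shapes at 2.
#'
#' @param a,b Numeric 20-vectors; both must have non-zero variance.
#' @return A number in [0, 2].
#' @export
#' @examples
#' a <- sin(seq_len(20))
#' pearson_distance(a, 3 * a + 7)  # 0
pearson_distance <- function(a, b) {
  stopifnot(length(a) == 20, length(b) == 20)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("Pearson distance is undefined for zero-variance profiles; ",
         "exclude degenerate genes or give them a singleton cluster",
         call. = FALSE)
  }
  1 - stats::cor(a, b)
}

#' Agglomerative clustering of profiles under Pearson distance
#'
#' Builds the full pairwise Pearson-distance matrix and runs agglomerative
#' hierarchical clustering. Genes are ordered lexicographically by id
#' before clustering so that ties in the distance matrix break
#' deterministically.
#'
#' @param profiles Numeric matrix, one row per gene (rownames = gene ids)
#'   — typically normalized profiles — or a `qisp` tibble (its smoothed
#'   variant is used).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An [stats::hclust] tree with gene ids as labels.
#' @export
hierarchical_cluster <- function(profiles,
                                 linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  m <- profiles_as_matrix(profiles)
  if (nrow(m) < 2) stop("need at least 2 genes to cluster", call. = FALSE)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance profile(s): ",
         paste(rownames(m)[sds == 0], collapse = ", "),
         "; exclude degenerate genes before clustering", call. = FALSE)
  }
  m <- m[order(rownames(m)), , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(t(m)))
  stats::hclust(d, method = linkage)
}

profiles_as_matrix <- function(profiles) {
  if (inherits(profiles, "qisp") || (is.data.frame(profiles) &&
                                     all(c("gene_id", "sroi") %in% names(profiles)))) {
    ids <- unique(profiles$gene_id)
    m <- t(vapply(ids, function(g) qisp_vector(profiles, g), numeric(20)))
    rownames(m) <- ids
    return(m)
  }
  m <- as.matrix(profiles)
  stopifnot(ncol(m) == 20)
  if (is.null(rownames(m))) rownames(m) <- sprintf("gene_%03d", seq_len(nrow(m)))
  m
}

#' Cut a tree into k flat clusters
#'
#' Standard k-cluster cut (removes the k-1 highest merges); cluster
#' numbers are reassigned so that cluster 1 is the one whose first member
#' appears first in the tree's label order, and so on.
#'
#' @param tree An [stats::hclust] tree.
#' @param k Number of clusters, between 1 and the leaf count.
#' @return Named integer vector of cluster labels (1..k), names = gene ids.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be between 1 and the leaf count (", n, ")",
                           call. = FALSE)
  raw <- stats::cutree(tree, k = k)
  relabel <- match(raw, unique(raw))
  stats::setNames(as.integer(relabel), names(raw))
}

#' Laminar zone map over the 20 sROIs
#'
#' Partitions the radial axis into three contiguous compartments: deep
#' (ventricular zone; must contain sROI 1), middle (intermediate zone) and
#' upper (cortical plate and marginal zone; must contain sROI 20). The
#' default — deep 1-10, middle 11-15, upper 16-20 — follows the convention
#' that the VZ compartment spans the deep half of the wall at this stage.
#'
#' @param deep,middle,upper Integer vectors of sROI indices.
#' @return An object of class `zone_map`.
#' @export
zone_map <- function(deep = 1:10, middle = 11:15, upper = 16:20) {
  bins <- c(deep, middle, upper)
  if (!setequal(bins, 1:20) || length(bins) != 20) {
    stop("zones must partition sROIs 1..20", call. = FALSE)
  }
  for (z in list(deep, middle, upper)) {
    if (!all(diff(sort(z)) == 1)) stop("each zone must be contiguous", call. = FALSE)
  }
  if (!(1 %in% deep)) stop("deep zone must contain sROI 1", call. = FALSE)
  if (!(20 %in% upper)) stop("upper zone must contain sROI 20", call. = FALSE)
  structure(list(deep = sort(deep), middle = sort(middle), upper = sort(upper)),
            class = "zone_map")
}

#' Assign a profile to a laminar zone by its peak
#'
#' The zone is the compartment containing the profile's argmax; exact ties
#' break toward the more superficial (higher-index) bin. Degenerate
#' (constant) profiles are `"unassigned"`.
#'
#' @param centroid Numeric 20-vector (typically a cluster centroid).
#' @param zones A [zone_map()].
#' @return `"deep"`, `"middle"`, `"upper"` or `"unassigned"`.
#' @export
assign_zone <- function(centroid, zones = zone_map()) {
  stopifnot(length(centroid) == 20, inherits(zones, "zone_map"))
  if (stats::sd(centroid) == 0) return("unassigned")
  peak <- max(which(centroid == max(centroid)))  # tie -> most superficial
  if (peak %in% zones$deep) "deep"
  else if (peak %in% zones$middle) "middle"
  else "upper"
}

#' Cluster validated QISPs and assign laminar zones
#'
#' End-to-end grouping: standardizes each gene's profile, builds the
#' Pearson-distance tree, cuts it into `k` clusters, computes cluster
#' centroids (means of the normalized member profiles), assigns each
#' cluster to a zone by its centroid peak, and induces per-gene zones.
#' Degenerate (constant) profiles are excluded from the tree and reported
#' with cluster `NA` and zone `"unassigned"`.
#'
#' @param qisps A `qisp` tibble (or gene-by-20 matrix) of validated
#'   profiles.
#' @param k Number of flat clusters.
#' @param variant Profile variant when a tibble is given; default smoothed.
#' @param linkage Linkage for [hierarchical_cluster()].
#' @param zones A [zone_map()].
#' @return An object of class `qisp_clusters`: list with `tree` (hclust),
#'   `labels` (tibble: gene_id, cluster, zone), `centroids` (k x 20
#'   matrix), `zone_of_cluster` (named character), `normalized` (gene x 20
#'   matrix), `zones`, `k`, `linkage`.
#' @export
cluster_qisps <- function(qisps, k,
                          variant = c("smoothed", "corrected", "raw"),
                          linkage = c("average", "complete", "single"),
                          zones = zone_map()) {
  variant <- match.arg(variant)
  linkage <- match.arg(linkage)
  m <- if (is.data.frame(qisps)) {
    ids <- unique(qisps$gene_id)
    mm <- t(vapply(ids, function(g) qisp_vector(qisps, g, variant), numeric(20)))
    rownames(mm) <- ids
    mm
  } else {
    profiles_as_matrix(qisps)
  }
  sds <- apply(m, 1, stats::sd)
  degen <- rownames(m)[sds == 0]
  if (length(degen) > 0) {
    message("excluding ", length(degen),
            " degenerate (constant) profile(s) from clustering")
  }
  keep <- m[sds > 0, , drop = FALSE]
  norm <- t(apply(keep, 1, normalize_qisp))
  rownames(norm) <- rownames(keep)

  tree <- hierarchical_cluster(norm, linkage = linkage)
  labels <- cut_clusters(tree, k)

  centroids <- t(vapply(seq_len(k), function(cl) {
    colMeans(norm[names(labels)[labels == cl], , drop = FALSE])
  }, numeric(20)))
  rownames(centroids) <- as.character(seq_len(k))
  colnames(centroids) <- paste0("sroi_", seq_len(20))

  zone_of_cluster <- vapply(seq_len(k), function(cl) {
    assign_zone(centroids[cl, ], zones)
  }, character(1))
  names(zone_of_cluster) <- as.character(seq_len(k))

  lab_tbl <- tibble::tibble(
    gene_id = c(names(labels), degen),
    cluster = c(unname(labels), rep(NA_integer_, length(degen))),
    zone = c(unname(zone_of_cluster[as.character(labels)]),
             rep("unassigned", length(degen)))
  )
  lab_tbl <- lab_tbl[match(rownames(m), lab_tbl$gene_id), ]

  structure(
    list(tree = tree, labels = lab_tbl, centroids = centroids,
         zone_of_cluster = zone_of_cluster, normalized = norm,
         zones = zones, k = k, linkage = linkage),
    class = "qisp_clusters"
  )
}

#' @export
print.qisp_clusters <- function(x, ...) {
  cat("<qisp_clusters> ", nrow(x$labels), " genes in ", x$k,
      " clusters (", x$linkage, " linkage, Pearson distance)\n", sep = "")
  print(table(zone = x$labels$zone))
  invisible(x)
}

#' @export
tidy.qisp_clusters <- function(x, ...) x$labels

#' @export
glance.qisp_clusters <- function(x, ...) {
  zc <- table(factor(x$labels$zone,
                     levels = c("deep", "middle", "upper", "unassigned")))
  tibble::tibble(
    n_genes = nrow(x$labels), k = x$k, linkage = x$linkage,
    n_deep = as.integer(zc["deep"]), n_middle = as.integer(zc["middle"]),
    n_upper = as.integer(zc["upper"]),
    n_unassigned = as.integer(zc["unassigned"])
  )
}

#' Per-zone counts and percentages
#'
#' Tallies genes per laminar zone and reports integer percentages
#' (rounded half-up, so they sum to 100 within +/- 1) alongside
#' one-decimal percentages.
#'
#' @param zone_of_gene Character vector of zone labels (e.g.
#'   `tidy(clusters)$zone`), or a named vector/tibble from which zones are
#'   taken.
#' @return Tibble: `zone`, `n`, `pct` (integer, half-up), `pct_1dp`.
#' @export
#' @examples
#' group_summary(rep(c("deep", "middle", "upper"), c(44, 49, 224)))
group_summary <- function(zone_of_gene) {
  if (is.data.frame(zone_of_gene)) zone_of_gene <- zone_of_gene$zone
  if (length(zone_of_gene) == 0) stop("no genes to summarize", call. = FALSE)
  lev <- intersect(c("deep", "middle", "upper", "unassigned"),
                   unique(zone_of_gene))
  counts <- table(factor(zone_of_gene, levels = lev))
  total <- sum(counts)
  pct_exact <- 100 * as.numeric(counts) / total
  tibble::tibble(
    zone = names(counts),
    n = as.integer(counts),
    pct = as.integer(floor(pct_exact + 0.5)),  # half-up, not banker's rounding
    pct_1dp = floor(pct_exact * 10 + 0.5) / 10
  )
}

#' Subset genes by annotation term
#'
#' Case-insensitive substring filter on a user-supplied gene-to-term
#' table: a gene is kept when any of its terms contains `term_query`.
#' Input order is preserved; genes absent from the table are dropped.
#'
#' @param genes Character vector of gene ids.
#' @param annotations Tibble/data frame with columns `gene_id` and `term`
#'   (one row per gene-term pair).
#' @param term_query Substring to match (case-insensitive).
#' @return Character vector, a subset of `genes` in the original order.
#' @export
subset_by_annotation <- function(genes, annotations, term_query) {
  stopifnot(all(c("gene_id", "term") %in% names(annotations)),
            is.character(term_query), length(term_query) == 1)
  hit <- grepl(tolower(term_query), tolower(annotations$term), fixed = TRUE)
  keep <- unique(annotations$gene_id[hit])
  genes[genes %in% keep]
}

#' Export a cluster tree as Newick
#'
#' Branch lengths are derived from the merge heights of the hierarchical
#' tree.
#'
#' @param clusters A `qisp_clusters` object (or an hclust tree).
#' @param path Output path for the Newick file.
#' @return `path`, invisibly.
#' @export
export_newick <- function(clusters, path) {
  tree <- if (inherits(clusters, "qisp_clusters")) clusters$tree else clusters
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
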