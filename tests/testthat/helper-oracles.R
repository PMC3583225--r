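# Independent brute-force oracles, deliberately written with per-gene loops
# and direct arithmetic so they share no code path with the implementation.

# Exhaustive per-gene re-implementation of the fold/threshold screen.
brute_screen <- function(expression, samples, target_group, reference_group,
                         threshold, fold_cutoff = 3) {
  grp <- setNames(samples$group, samples$sample_id)
  up <- character(); down <- character(); fold_of <- numeric()
  for (i in seq_len(nrow(expression))) {
    g <- expression$gene_id[i]
    vals <- unlist(expression[i, setdiff(names(expression), "gene_id")])
    mt <- mean(vals[grp[names(vals)] == target_group])
    mr <- mean(vals[grp[names(vals)] == reference_group])
    fold <- 2^(mt - mr)
    fold_of[g] <- fold
    if (max(mt, mr) >= threshold) {
      if (fold >= fold_cutoff) up <- c(up, g)
      if (fold <= 1 / fold_cutoff) down <- c(down, g)
    }
  }
  list(up = up, down = down, fold_of = fold_of)
}

# Direct deep-ratio arithmetic on a plain vector.
brute_deep_ratio <- function(p) {
  num <- (p[1] + p[2]) / 2
  den <- sum(p[3:20]) / 18
  if (den == 0) return(NA_real_)
  num / den
}

# Naive O(n^3) average-linkage agglomeration on a precomputed distance
# matrix; returns the sorted merge heights.
naive_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  D <- matrix(Inf, n + (n - 1), n + (n - 1))
  D[1:n, 1:n] <- as.matrix(d)
  diag(D) <- Inf
  active[(n + 1):(n + n - 1)] <- FALSE
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    pos <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    a <- idx[pos[1]]; b <- idx[pos[2]]
    heights[step] <- D[a, b]
    new <- n + step
    members[[new]] <- c(members[[a]], members[[b]])
    active[c(a, b)] <- FALSE
    active[new] <- TRUE
    for (o in which(active)) {
      if (o == new) next
      # average linkage: mean pairwise original distance between members
      dm <- as.matrix(d)[members[[new]], members[[o]], drop = FALSE]
      D[new, o] <- D[o, new] <- mean(dm)
    }
  }
  sort(heights)
}

# Best label-permutation accuracy of predicted vs true cluster labels.
permutation_accuracy <- function(pred, truth) {
  truth <- as.integer(factor(truth))
  pred <- as.integer(factor(pred))
  k <- max(truth, pred)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(k))) {
    best <- max(best, mean(p[pred] == truth))
  }
  best
}

# Render + extract one gene's profile, returning the smoothed vector.
extract_from_profile <- function(profile, render = render_params(), seed = 1) {
  r <- render_ish_image(profile, render, seed = seed)
  qisp_vector(extract_qisp(r$image, r$roi, "g"), variant = "smoothed")
}
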