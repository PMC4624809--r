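#' Posterior-probability map of a term given activation
#'
#' Reverse inference by Bayes' rule at every voxel:
#' `p(Term | Actv.) = p(Actv. | Term) p(Term) / (p(Actv. | Term) p(Term) +
#' p(Actv. | notTerm) (1 - p(Term)))`, with the two conditional activation
#' probabilities estimated as the activation fractions among articles
#' with/without the term. The prior `p(Term)` defaults to 0.5 (so the map
#' reflects specificity rather than term base rates); the empirical term
#' frequency can be supplied instead.
#'
#' @param term term name.
#' @param termdb a [term_database()].
#' @param masks an [activation_masks()] built from the matching foci
#'   database.
#' @param prior prior probability of the term, or `"empirical"` for its
#'   corpus frequency.
#' @return a [statmap()] of posterior probabilities; voxels where no
#'   article is active are `NA`.
#' @export
term_posterior_map <- function(term, termdb, masks, prior = 0.5) {
  stopifnot(inherits(termdb, "term_database"),
            inherits(masks, "activation_masks"))
  with_term <- term_members(termdb, term)[masks$article_ids]
  if (identical(prior, "empirical")) prior <- mean(with_term)
  if (prior < 0 || prior > 1) stop("'prior' must be in [0, 1]")
  n1 <- sum(with_term)
  n0 <- sum(!with_term)
  if (n1 == 0 || n0 == 0) stop("need articles both with and without the term")
  p_act_term <- colSums(masks$masks[with_term, , drop = FALSE]) / n1
  p_act_not <- colSums(masks$masks[!with_term, , drop = FALSE]) / n0
  num <- p_act_term * prior
  den <- num + p_act_not * (1 - prior)
  post <- ifelse(den > 0, num / den, NA_real_)
  statmap(masks$grid, post)
}

#' Posterior-z map of a term
#'
#' Association strength between the term and activation at every voxel:
#' Pearson chi-square (no continuity correction) on the 2x2 term-by-active
#' article counts, converted to a two-sided p-value and then an absolute
#' z-value, signed positive iff the with-term activation fraction exceeds
#' the without-term fraction. Both the number of articles mentioning the
#' term and the activation contrast influence the statistic. Voxels with a
#' degenerate margin (all or no articles active) are `NA`.
#'
#' @inheritParams term_posterior_map
#' @return a [statmap()] of signed z-values.
#' @export
term_posterior_z <- function(term, termdb, masks) {
  stopifnot(inherits(termdb, "term_database"),
            inherits(masks, "activation_masks"))
  with_term <- term_members(termdb, term)[masks$article_ids]
  n1 <- sum(with_term)
  n0 <- sum(!with_term)
  if (n1 < 2 || n0 < 2) {
    stop("need at least 2 articles each with and without the term")
  }
  N <- n1 + n0
  a <- colSums(masks$masks[with_term, , drop = FALSE])  # with term, active
  c_ <- colSums(masks$masks[!with_term, , drop = FALSE]) # without term, active
  b <- n1 - a
  d <- n0 - c_
  act <- a + c_
  inact <- b + d
  chi2 <- N * (a * d - b * c_)^2 / (as.double(n1) * n0 * act * inact)
  chi2[act == 0 | inact == 0] <- NA_real_
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  z <- qnorm(p / 2, lower.tail = FALSE)
  z <- z * ifelse(a / n1 >= c_ / n0, 1, -1)
  statmap(masks$grid, z)
}

#' Local maxima of a thresholded statistic map
#'
#' Voxels above `z_thresh` that are 26-connected local maxima, selected
#' greedily in descending order with a minimum mutual distance: any
#' candidate within `min_distance_mm` of an already accepted peak is
#' suppressed (the 3 cm default mirrors common cluster-tool settings).
#' Peaks are labelled with the connected component (cluster, 26-
#' connectivity above threshold) they belong to.
#'
#' @param map a [statmap()].
#' @param z_thresh voxel threshold.
#' @param min_distance_mm minimum distance between reported peaks.
#' @return data frame with columns `x`, `y`, `z` (mm), `value`, `cluster`;
#'   zero rows when nothing is above threshold.
#' @export
local_maxima <- function(map, z_thresh = 2.3, min_distance_mm = 30) {
  stopifnot(inherits(map, "statmap"))
  v <- map$values
  dim <- map$grid$dim
  above <- which(!is.na(v) & v > z_thresh, arr.ind = TRUE)
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      value = numeric(), cluster = integer())
  if (!nrow(above)) return(empty)

  is_local_max <- apply(above, 1, function(idx) {
    val <- v[idx[1], idx[2], idx[3]]
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      i <- idx[1] + dx; j <- idx[2] + dy; k <- idx[3] + dz
      if (i < 1 || j < 1 || k < 1 || i > dim[1] || j > dim[2] || k > dim[3]) next
      w <- v[i, j, k]
      if (!is.na(w) && w > val) return(FALSE)
    }
    TRUE
  })
  cand <- above[is_local_max, , drop = FALSE]
  if (!nrow(cand)) return(empty)

  # cluster labels: connected components of the suprathreshold set
  labels <- cluster_labels(v > z_thresh & !is.na(v), dim)

  mm <- function(idx) map$grid$origin + (idx - 1) * map$grid$spacing
  vals <- v[cand]
  ord <- order(-vals)
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  acc <- matrix(numeric(), 0, 3)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- mm(cand[i, ])
    if (!nrow(acc) ||
        all(sqrt(rowSums((acc - matrix(p, nrow(acc), 3, byrow = TRUE))^2)) >=
            min_distance_mm)) {
      keep[i] <- TRUE
      acc <- rbind(acc, p)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(t(apply(cand, 1, mm)))
  names(out) <- c("x", "y", "z")
  out$value <- vals[keep]
  out$cluster <- labels[cand]
  rownames(out) <- NULL
  out
}

# connected components (26-connectivity) of a logical 3-D array
cluster_labels <- function(mask, dim) {
  labels <- array(0L, dim)
  nextlab <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    labels[start] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(cur, dim)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        i <- ai[1] + dx; j <- ai[2] + dy; k <- ai[3] + dz
        if (i < 1 || j < 1 || k < 1 || i > dim[1] || j > dim[2] || k > dim[3]) next
        if (mask[i, j, k] && labels[i, j, k] == 0L) {
          lin <- i + (j - 1) * dim[1] + (k - 1) * dim[1] * dim[2]
          labels[lin] <- nextlab
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

#' Contrast-weighted average posterior z in a spherical ROI
#'
#' Within a sphere of `radius_mm` around a peak, averages the term's
#' posterior z-values using the contrast z-statistics as weights,
#' normalized to sum to 1 over the sphere. Non-positive contrast weights
#' are clamped to zero before normalization (the weights form a convex
#' combination), and missing posterior-z voxels are dropped with the
#' remaining weights renormalized; if every positive-weight voxel is
#' missing, the non-missing voxels are averaged with equal weights.
#'
#' @param peak numeric `c(x, y, z)` in mm.
#' @param posterior_z_map a [statmap()] of term posterior z-values.
#' @param contrast_map a [statmap()] of contrast z-statistics on the same
#'   grid.
#' @param radius_mm ROI radius.
#' @return weighted mean posterior z.
#' @export
roi_weighted_posterior_z <- function(peak, posterior_z_map, contrast_map,
                                     radius_mm = 5) {
  stopifnot(inherits(posterior_z_map, "statmap"),
            inherits(contrast_map, "statmap"))
  if (!identical(posterior_z_map$grid$dim, contrast_map$grid$dim)) {
    stop("maps must share one grid")
  }
  xyz <- voxel_centers(posterior_z_map$grid)
  d2 <- (xyz[, 1] - peak[1])^2 + (xyz[, 2] - peak[2])^2 +
    (xyz[, 3] - peak[3])^2
  sel <- d2 <= radius_mm^2
  if (!any(sel)) stop("sphere contains no voxel")
  pz <- as.vector(posterior_z_map$values)[sel]
  cz <- as.vector(contrast_map$values)[sel]
  ok <- !is.na(pz)
  if (!any(ok)) stop("all posterior-z voxels in the sphere are missing")
  w <- pmax(cz[ok], 0)
  if (sum(w) <= 0) w <- rep(1, sum(ok))
  w <- w / sum(w)
  sum(w * pz[ok])
}

#' Evidence scores for all (peak, term) pairs of a contrast
#'
#' For each local maximum of the contrast map and each term in the
#' database: evidence score = peak contrast z-value x ROI-averaged
#' posterior z of the term in a 5 mm sphere around the peak. The
#' multiplicative combination favours terms that are specific to strongly
#' activated locations.
#'
#' @param contrast a [statmap()] of contrast z-statistics.
#' @param termdb a [term_database()].
#' @param masks an [activation_masks()] on the same grid.
#' @param z_thresh,min_distance_mm peak detection settings
#'   (see [local_maxima()]).
#' @param roi_radius_mm ROI radius around each peak.
#' @param terms terms to score; default: all database terms.
#' @param contrast_id label written in the output.
#' @return data frame (one row per peak x term) with columns `contrast`,
#'   `peak_x`, `peak_y`, `peak_z`, `cluster`, `term`, `peak_z_value`,
#'   `roi_post_z`, `evidence_score`.
#' @export
evidence_scores <- function(contrast, termdb, masks, z_thresh = 2.3,
                            min_distance_mm = 30, roi_radius_mm = 5,
                            terms = NULL, contrast_id = "contrast") {
  stopifnot(inherits(contrast, "statmap"))
  peaks <- local_maxima(contrast, z_thresh, min_distance_mm)
  if (!nrow(peaks)) stop("no peaks above threshold")
  if (is.null(terms)) terms <- termdb$terms
  rows <- list()
  for (tm in terms) {
    pz_map <- term_posterior_z(tm, termdb, masks)
    for (i in seq_len(nrow(peaks))) {
      roi_z <- roi_weighted_posterior_z(
        c(peaks$x[i], peaks$y[i], peaks$z[i]), pz_map, contrast,
        roi_radius_mm)
      rows[[length(rows) + 1]] <- data.frame(
        contrast = contrast_id, peak_x = peaks$x[i], peak_y = peaks$y[i],
        peak_z = peaks$z[i], cluster = peaks$cluster[i], term = tm,
        peak_z_value = peaks$value[i], roi_post_z = roi_z,
        evidence_score = peaks$value[i] * roi_z)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top terms of a contrast by evidence score
#'
#' Each term is first deduplicated to its highest-scoring peak within the
#' contrast; terms are then ranked by evidence score. For contrasts with
#' more than one cluster the top `k` terms are returned; for a
#' single-cluster contrast the top `per_cluster_k` terms per cluster.
#'
#' @param rows an [evidence_scores()] table (one contrast).
#' @param k number of terms for multi-cluster contrasts.
#' @param per_cluster_k terms per cluster for single-cluster contrasts.
#' @return the selected rows, ranked by descending evidence score.
#' @export
top_terms <- function(rows, k = 8, per_cluster_k = 3) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0)
  best <- do.call(rbind, lapply(split(rows, rows$term), function(g) {
    g[which.max(g$evidence_score), ]
  }))
  best <- best[order(-best$evidence_score), ]
  n_clusters <- length(unique(rows$cluster))
  out <- if (n_clusters == 1) {
    head(best, per_cluster_k)
  } else {
    head(best, k)
  }
  rownames(out) <- NULL
  out
}
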