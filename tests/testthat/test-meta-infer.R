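test_that("merging location databases unions ids and deduplicates foci", {
  a <- foci_database(list(`1` = rbind(c(0, 0, 0))))
  b <- foci_database(list(`2` = rbind(c(10, 0, 0))))
  expect_length(merge_foci(a, b)$articles, 2)
  shared <- merge_foci(
    foci_database(list(s = rbind(c(1, 2, 3), c(4, 5, 6)))),
    foci_database(list(s = rbind(c(1, 2, 3)))))
  expect_equal(nrow(shared$articles$s), 2)
  # 750 + 250 ids sharing 100 -> 900 articles
  mk <- function(ids) {
    foci_database(setNames(lapply(ids, function(i) rbind(c(i, 0, 0))),
                           as.character(ids)))
  }
  expect_length(merge_foci(mk(1:750), mk(651:900))$articles, 900)
})

test_that("activation masks follow the spherical radius rule", {
  grid <- toy_grid(n = 7, spacing = 4)  # centers at -12..12 mm
  fdb <- foci_database(list(a = rbind(c(0, 0, 0)), b = matrix(numeric(), 0, 3)))
  am <- activation_masks(fdb, grid, radius_mm = 10)
  centers <- voxel_centers(grid)
  at <- function(x, y, z) which(centers[, 1] == x & centers[, 2] == y &
                                  centers[, 3] == z)
  expect_true(am$masks["a", at(0, 0, 8)])    # 8 mm < 10 mm
  expect_false(am$masks["a", at(0, 0, 12)])  # 12 mm > 10 mm
  expect_false(any(am$masks["b", ]))         # article without foci
  out <- foci_database(list(a = rbind(c(500, 0, 0))))
  expect_warning(activation_masks(out, grid), "outside the grid")
})

test_that("reverse-inference posterior equals a brute-force Bayes computation", {
  grid <- toy_grid(n = 10, spacing = 4)
  set.seed(17)
  spec <- corpus_spec(n_articles = 100, terms = c("decision", "memory"),
                      prevalence = 0.4,
                      planted = data.frame(term = "decision", x = 0, y = 0,
                                           z = 0, radius = 8, p_act = 0.8,
                                           base_rate = 0.1),
                      foci_rate = 2)
  corpus <- generate_meta_corpus(spec, grid, seed = 17)
  masks <- activation_masks(corpus$foci_db, grid)
  post <- term_posterior_map("decision", corpus$term_db, masks, prior = 0.5)
  with_term <- vapply(corpus$term_db$articles, function(a) "decision" %in% a,
                      logical(1))
  for (vox in seq(1, prod(grid$dim), by = 97)) {
    expected <- bayes_oracle(sum(masks$masks[with_term, vox]),
                             sum(with_term),
                             sum(masks$masks[!with_term, vox]),
                             sum(!with_term), 0.5)
    expect_equal(as.vector(post$values)[vox], expected,
                 label = sprintf("voxel %d", vox))
  }
})

test_that("the posterior follows the stated Bayes arithmetic", {
  # activation fractions 0.8 with term, 0.1 without, prior 0.5
  p <- 0.8 * 0.5 / (0.8 * 0.5 + 0.1 * 0.5)
  expect_equal(p, 0.888889, tolerance = 1e-6)
  arts <- c(lapply(1:10, function(i) "t"), lapply(1:10, function(i) "u"))
  names(arts) <- sprintf("a%02d", 1:20)
  tdb <- term_database(arts)
  grid <- voxel_grid(c(1, 1, 1), 2)
  masks <- structure(list(grid = grid,
                          masks = matrix(c(rep(TRUE, 8), rep(FALSE, 2),
                                           rep(TRUE, 1), rep(FALSE, 9)), 20, 1),
                          article_ids = names(arts), radius_mm = 10),
                     class = "activation_masks")
  expect_equal(as.vector(term_posterior_map("t", tdb, masks, 0.5)$values),
               0.8 * 0.5 / (0.8 * 0.5 + 0.1 * 0.5))
  # equal fractions: posterior equals the prior; prior 1: certainty
  masks$masks[, 1] <- rep(c(TRUE, FALSE), 10)
  expect_equal(as.vector(term_posterior_map("t", tdb, masks, 0.5)$values), 0.5)
  expect_equal(as.vector(term_posterior_map("t", tdb, masks, 1)$values), 1)
  # monotone in p(Actv.|Term): raising the with-term fraction raises it
  masks$masks[, 1] <- c(rep(TRUE, 9), FALSE, rep(c(TRUE, rep(FALSE, 4)), 2))
  expect_gt(as.vector(term_posterior_map("t", tdb, masks, 0.5)$values), 0.5)
})

test_that("posterior z comes from the Pearson chi-square with a direction sign", {
  # counts: 16/20 with-term active, 8/80 without-term active
  arts <- c(lapply(1:20, function(i) "t"), lapply(1:80, function(i) "u"))
  names(arts) <- sprintf("a%03d", 1:100)
  tdb <- term_database(arts)
  grid <- voxel_grid(c(1, 1, 1), 2)
  active <- c(rep(TRUE, 16), rep(FALSE, 4), rep(TRUE, 8), rep(FALSE, 72))
  masks <- structure(list(grid = grid, masks = matrix(active, 100, 1),
                          article_ids = names(arts), radius_mm = 10),
                     class = "activation_masks")
  z <- as.vector(term_posterior_z("t", tdb, masks)$values)
  oracle <- suppressWarnings(
    stats::chisq.test(matrix(c(16, 4, 8, 72), 2, byrow = TRUE),
                      correct = FALSE))
  expect_equal(z, qnorm(oracle$p.value / 2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(z^2, unname(oracle$statistic), tolerance = 1e-10)
  expect_gt(z, 0)  # with-term fraction is higher
  # reversed association flips the sign
  masks$masks[, 1] <- !active
  expect_lt(as.vector(term_posterior_z("t", tdb, masks)$values), 0)
  # equal fractions: z near zero; degenerate margin: missing
  masks$masks[, 1] <- rep(c(TRUE, FALSE), 50)
  expect_lt(abs(as.vector(term_posterior_z("t", tdb, masks)$values)), 0.3)
  masks$masks[, 1] <- rep(TRUE, 100)
  expect_true(is.na(as.vector(term_posterior_z("t", tdb, masks)$values)))
})

test_that("local maxima respect the threshold and minimum peak distance", {
  grid <- voxel_grid(c(31, 11, 11), 4, origin = c(-60, -20, -20))
  two <- simulate_stat_map(grid, data.frame(
    x = c(-20, 20), y = 0, z = 0, peak_z = c(4, 3.5), fwhm_mm = 10))
  pk <- local_maxima(two, z_thresh = 2.3, min_distance_mm = 30)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$x), c(-20, 20))
  near <- simulate_stat_map(grid, data.frame(
    x = c(-4, 8), y = 0, z = 0, peak_z = c(4, 3.5), fwhm_mm = 10))
  expect_equal(nrow(local_maxima(near, 2.3, 30)), 1)
  flat <- statmap(grid, array(1, grid$dim))
  expect_equal(nrow(local_maxima(flat, 2.3)), 0)
})

test_that("ROI averaging uses convex contrast weights", {
  grid <- voxel_grid(c(3, 1, 1), 4)
  pz <- statmap(grid, c(2, 6, NA))
  cz <- statmap(grid, c(3, 1, 5))
  # sphere covering the first two voxels: weights 0.75 / 0.25
  expect_equal(roi_weighted_posterior_z(c(2, 0, 0), pz, cz, radius_mm = 4.5),
               0.75 * 2 + 0.25 * 6)
  # constant posterior z: any weights give the constant
  pzc <- statmap(grid, c(4, 4, 4))
  expect_equal(roi_weighted_posterior_z(c(4, 0, 0), pzc, cz, radius_mm = 20), 4)
  # negative contrast z is clamped to zero before normalization
  czn <- statmap(grid, c(3, -1, 5))
  expect_equal(roi_weighted_posterior_z(c(2, 0, 0), pz, czn, radius_mm = 4.5),
               2)
  # missing posterior voxels are dropped with weight renormalization
  expect_equal(roi_weighted_posterior_z(c(4, 0, 0), pz, cz, radius_mm = 20),
               (3 * 2 + 1 * 6) / 4)
  pz_allna <- statmap(grid, c(NA, NA, NA))
  expect_error(roi_weighted_posterior_z(c(2, 0, 0), pz_allna, cz, 4.5),
               "missing")
})

test_that("evidence scores are peak-z times ROI posterior z", {
  # dmPFC-like peak of 4.07 with an ROI posterior z of 2 scores 8.14
  expect_equal(4.07 * 2, 8.14)
  grid <- toy_grid(n = 9, spacing = 6)
  set.seed(23)
  spec <- corpus_spec(n_articles = 120, terms = c("conflict", "memory", "motor"),
                      prevalence = 0.3,
                      planted = data.frame(term = "conflict", x = 0, y = 0,
                                           z = 0, radius = 10, p_act = 0.85,
                                           base_rate = 0.05),
                      foci_rate = 1)
  corpus <- generate_meta_corpus(spec, grid, seed = 23)
  masks <- activation_masks(corpus$foci_db, grid)
  cmap <- simulate_stat_map(grid, data.frame(x = 0, y = 0, z = 0, peak_z = 4,
                                             fwhm_mm = 12))
  sc <- evidence_scores(cmap, corpus$term_db, masks)
  expect_equal(sc$evidence_score, sc$peak_z_value * sc$roi_post_z)
  # homogeneity: doubling the contrast doubles every score
  cmap2 <- statmap(grid, 2 * cmap$values)
  sc2 <- evidence_scores(cmap2, corpus$term_db, masks)
  expect_equal(sc2$evidence_score, 2 * sc$evidence_score, tolerance = 1e-10)
})

test_that("top terms deduplicate to the best peak and respect k", {
  rows <- data.frame(contrast = "c", cluster = c(1, 1, 2, 2),
                     term = c("a", "a", "b", "c"),
                     evidence_score = c(5, 9, 7, 3))
  top <- top_terms(rows, k = 8)
  expect_equal(top$term[top$term == "a"], "a")
  expect_equal(top$evidence_score[top$term == "a"], 9)
  expect_equal(nrow(top), 3)  # only 3 distinct terms despite k = 8
  # single-cluster contrast: per-cluster quota applies
  one <- data.frame(contrast = "c", cluster = 1,
                    term = letters[1:5], evidence_score = 5:1)
  expect_equal(top_terms(one, k = 8, per_cluster_k = 3)$term, c("a", "b", "c"))
})

test_that("statmaps round-trip bit-exactly through flat CSV", {
  grid <- voxel_grid(c(4, 5, 3), c(2, 2, 4), origin = c(-3, 0, 1))
  set.seed(9)
  vals <- array(rnorm(prod(grid$dim)), grid$dim)
  vals[2, 3, 1] <- NA
  m <- statmap(grid, vals)
  path <- tempfile(fileext = ".csv")
  write_statmap_csv(m, path)
  back <- read_statmap_csv(path)
  expect_equal(back$grid$dim, grid$dim)
  expect_equal(back$grid$spacing, grid$spacing)
  expect_equal(back$grid$origin, grid$origin)
  expect_identical(back$values, m$values)
})
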