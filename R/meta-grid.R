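#' Voxel grid
#'
#' A regular 3-D grid in millimetre (MNI-style) coordinates: array
#' dimensions, isotropic-or-not voxel spacing and the world coordinate of
#' the first voxel's centre.
#'
#' @param dim integer vector of length 3.
#' @param spacing voxel size in mm (length 1 or 3).
#' @param origin mm coordinate of voxel `[1,1,1]`'s centre (length 3).
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(dim, spacing = 2, origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1))
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("'spacing' must be positive")
  structure(list(dim = dim, spacing = spacing, origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' MNI-like whole-brain grid
#'
#' Standard-space bounding box (-90..90, -126..90, -72..108 mm) at the
#' requested isotropic spacing; 2 mm gives the familiar 91 x 109 x 91
#' grid.
#'
#' @param spacing voxel size, mm.
#' @return a [voxel_grid()].
#' @export
mni_grid <- function(spacing = 2) {
  dim <- floor(c(180, 216, 180) / spacing) + 1
  voxel_grid(dim, spacing, origin = c(-90, -126, -72))
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid %dx%dx%d, spacing %s mm, origin (%s) mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(x$spacing, collapse = "x"),
              paste(x$origin, collapse = ", ")))
  invisible(x)
}

#' Voxel centre coordinates
#'
#' @param grid a [voxel_grid()].
#' @return matrix `prod(dim) x 3` of mm coordinates in array order (first
#'   index fastest).
#' @export
voxel_centers <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  ax <- lapply(1:3, function(k) {
    grid$origin[k] + (seq_len(grid$dim[k]) - 1) * grid$spacing[k]
  })
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

grid_bbox <- function(grid) {
  lo <- grid$origin
  hi <- grid$origin + (grid$dim - 1) * grid$spacing
  rbind(lo = lo, hi = hi)
}

#' Statistic map on a voxel grid
#'
#' @param grid a [voxel_grid()].
#' @param values numeric array (or vector in array order) of per-voxel
#'   statistic values; `NA` encodes voxels where the statistic is
#'   undefined.
#' @return object of class `statmap`.
#' @export
statmap <- function(grid, values) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(dim(values))) {
    stopifnot(length(values) == prod(grid$dim))
    values <- array(values, grid$dim)
  }
  stopifnot(all(dim(values) == grid$dim))
  if (any(is.infinite(values))) stop("statmap values must be finite or NA")
  structure(list(grid = grid, values = values), class = "statmap")
}

#' @export
print.statmap <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("statmap %dx%dx%d, range [%.3g, %.3g], %d missing\n",
              x$grid$dim[1], x$grid$dim[2], x$grid$dim[3], rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

#' Flat-CSV round trip for statistic maps
#'
#' Plain-text serialization: one `x,y,z,value` row per voxel (mm
#' coordinates of voxel centres, full grid). The grid geometry is
#' reconstructed exactly from the coordinate columns on read, so a
#' write/read cycle is lossless.
#'
#' @param map a [statmap()].
#' @param path file path.
#' @return `read_statmap_csv` returns the [statmap()].
#' @export
write_statmap_csv <- function(map, path) {
  stopifnot(inherits(map, "statmap"))
  xyz <- voxel_centers(map$grid)
  # %.17g preserves doubles exactly across the round trip
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  lines <- c("x,y,z,value",
             paste(fmt(xyz[, 1]), fmt(xyz[, 2]), fmt(xyz[, 3]),
                   fmt(as.vector(map$values)), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_statmap_csv
#' @export
read_statmap_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("x", "y", "z", "value") %in% names(df)))
  ax <- lapply(df[c("x", "y", "z")], function(v) sort(unique(v)))
  dim <- vapply(ax, length, integer(1))
  spacing <- vapply(ax, function(v) if (length(v) > 1) v[2] - v[1] else 1,
                    numeric(1))
  origin <- vapply(ax, `[`, numeric(1), 1)
  grid <- voxel_grid(dim, spacing, origin)
  # rows are written in array order; rebuild directly
  statmap(grid, array(df$value, unname(dim)))
}

#' Synthetic contrast statistic map with planted clusters
#'
#' Builds a z-statistic map as a sum of isotropic Gaussian bumps over a
#' zero background, emulating a thresholdable group-contrast image.
#'
#' @param grid a [voxel_grid()].
#' @param clusters data frame with columns `x`, `y`, `z` (mm centre),
#'   `peak_z` and `fwhm_mm`.
#' @param noise_sd sd of optional i.i.d. Gaussian background noise.
#' @param seed seed used when `noise_sd > 0`.
#' @return a [statmap()].
#' @export
simulate_stat_map <- function(grid, clusters, noise_sd = 0, seed = 1) {
  stopifnot(inherits(grid, "voxel_grid"),
            all(c("x", "y", "z", "peak_z", "fwhm_mm") %in% names(clusters)))
  xyz <- voxel_centers(grid)
  vals <- numeric(nrow(xyz))
  for (i in seq_len(nrow(clusters))) {
    sigma <- clusters$fwhm_mm[i] / (2 * sqrt(2 * log(2)))
    d2 <- (xyz[, 1] - clusters$x[i])^2 + (xyz[, 2] - clusters$y[i])^2 +
      (xyz[, 3] - clusters$z[i])^2
    vals <- vals + clusters$peak_z[i] * exp(-d2 / (2 * sigma^2))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + rnorm(length(vals), 0, noise_sd)
  }
  statmap(grid, vals)
}

#' Activation-foci database
#'
#' Maps article ids to MNI activation coordinates (mm).
#'
#' @param articles named list: article id -> numeric matrix with 3 columns
#'   (0-row matrices allowed for articles without foci).
#' @return object of class `foci_database`.
#' @export
foci_database <- function(articles) {
  stopifnot(is.list(articles), !is.null(names(articles)))
  articles <- lapply(articles, function(m) {
    m <- as.matrix(m)
    if (nrow(m) && ncol(m) != 3) stop("foci must have 3 columns (x, y, z)")
    if (!nrow(m)) m <- matrix(numeric(), 0, 3)
    colnames(m) <- c("x", "y", "z")
    m
  })
  structure(list(articles = articles), class = "foci_database")
}

#' @export
print.foci_database <- function(x, ...) {
  n <- sum(vapply(x$articles, nrow, integer(1)))
  cat(sprintf("foci_database: %d articles, %d foci\n", length(x$articles), n))
  invisible(x)
}

#' Merge two activation-location databases
#'
#' Union keyed by article id: an id present in both keeps the union of its
#' foci, with exact duplicates stored once.
#'
#' @param db_a,db_b [foci_database()] objects.
#' @return merged [foci_database()].
#' @export
merge_foci <- function(db_a, db_b) {
  stopifnot(inherits(db_a, "foci_database"), inherits(db_b, "foci_database"))
  ids <- union(names(db_a$articles), names(db_b$articles))
  merged <- lapply(ids, function(id) {
    m <- rbind(if (id %in% names(db_a$articles)) db_a$articles[[id]],
               if (id %in% names(db_b$articles)) db_b$articles[[id]])
    unique(m)
  })
  names(merged) <- ids
  foci_database(merged)
}

#' Per-article activation masks on a voxel grid
#'
#' A voxel counts as activated for an article iff its centre lies within
#' `radius_mm` of any of the article's foci (10 mm default on an MNI-like
#' grid, the convention of coordinate-based meta-analysis). Foci outside
#' the grid bounding box are dropped with a warning.
#'
#' @param foci a [foci_database()].
#' @param grid a [voxel_grid()].
#' @param radius_mm activation radius around each focus.
#' @return object of class `activation_masks`: logical matrix `articles x
#'   voxels` plus the grid.
#' @export
activation_masks <- function(foci, grid, radius_mm = 10) {
  stopifnot(inherits(foci, "foci_database"), inherits(grid, "voxel_grid"))
  if (radius_mm <= 0) stop("'radius_mm' must be positive")
  xyz <- voxel_centers(grid)
  bbox <- grid_bbox(grid)
  ids <- names(foci$articles)
  masks <- matrix(FALSE, length(ids), nrow(xyz),
                  dimnames = list(ids, NULL))
  r2 <- radius_mm^2
  n_dropped <- 0
  for (i in seq_along(ids)) {
    f <- foci$articles[[i]]
    if (!nrow(f)) next
    strict <- f[, 1] >= bbox["lo", 1] & f[, 1] <= bbox["hi", 1] &
      f[, 2] >= bbox["lo", 2] & f[, 2] <= bbox["hi", 2] &
      f[, 3] >= bbox["lo", 3] & f[, 3] <= bbox["hi", 3]
    n_dropped <- n_dropped + sum(!strict)
    f <- f[strict, , drop = FALSE]
    for (k in seq_len(nrow(f))) {
      d2 <- (xyz[, 1] - f[k, 1])^2 + (xyz[, 2] - f[k, 2])^2 +
        (xyz[, 3] - f[k, 3])^2
      masks[i, d2 <= r2] <- TRUE
    }
  }
  if (n_dropped > 0) {
    warning(sprintf("%d focus/foci outside the grid were ignored", n_dropped))
  }
  structure(list(grid = grid, masks = masks, article_ids = ids,
                 radius_mm = radius_mm),
            class = "activation_masks")
}
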