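#' Specification of a synthetic meta-analysis corpus
#'
#' Describes an article corpus emulating a merged coordinate-based
#' meta-analysis database: per-article term annotations (independent
#' Bernoulli per term) and activation foci, with optional planted
#' term-region associations (articles carrying the term activate near a
#' centre with elevated probability; others at a base rate) over uniform
#' background foci in a brain box.
#'
#' @param n_articles number of articles.
#' @param terms term vocabulary.
#' @param prevalence per-term probability of appearing in an article
#'   (scalar or named per term).
#' @param planted data frame with columns `term`, `x`, `y`, `z` (mm
#'   centre), `radius` (mm), `p_act` (activation probability given the
#'   term) and `base_rate` (without the term); may have zero rows.
#' @param foci_rate mean Poisson count of background foci per article.
#' @return object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_articles = 1000, terms, prevalence = 0.15,
                        planted = NULL, foci_rate = 6) {
  if (!length(terms)) stop("empty term list")
  if (n_articles < 1) stop("'n_articles' must be >= 1")
  prev <- if (length(prevalence) == 1) {
    setNames(rep(prevalence, length(terms)), terms)
  } else {
    stopifnot(all(terms %in% names(prevalence)))
    prevalence[terms]
  }
  if (any(prev < 0 | prev > 1)) stop("prevalences must be in [0, 1]")
  if (is.null(planted)) {
    planted <- data.frame(term = character(), x = numeric(), y = numeric(),
                          z = numeric(), radius = numeric(),
                          p_act = numeric(), base_rate = numeric())
  }
  stopifnot(all(c("term", "x", "y", "z", "radius", "p_act", "base_rate") %in%
                  names(planted)))
  if (nrow(planted)) {
    if (any(planted$radius <= 0)) stop("planted radius must be positive")
    if (any(planted$p_act < 0 | planted$p_act > 1 |
            planted$base_rate < 0 | planted$base_rate > 1)) {
      stop("planted probabilities must be in [0, 1]")
    }
    stopifnot(all(planted$term %in% terms))
  }
  structure(list(n_articles = as.integer(n_articles), terms = terms,
                 prevalence = prev, planted = planted,
                 foci_rate = foci_rate),
            class = "corpus_spec")
}

# uniform point in a sphere around `center`
runif_sphere <- function(center, radius) {
  repeat {
    p <- runif(3, -radius, radius)
    if (sum(p^2) <= radius^2) return(center + p)
  }
}

#' Generate a synthetic meta-analysis corpus
#'
#' Draws a corpus from a [corpus_spec()]: per article, independent
#' Bernoulli term annotations; Poisson-many background foci uniform over
#' the grid's bounding box; and, for each planted association, a focus
#' uniform in the planted sphere with probability `p_act` when the
#' article carries the term and `base_rate` otherwise. Also emits a small
#' pseudo-text per article (its terms joined with filler words) so the
#' text-based [build_term_db()] path can be exercised end to end. The
#' same seed reproduces the corpus exactly.
#'
#' @param spec a [corpus_spec()].
#' @param grid a [voxel_grid()] defining the brain box.
#' @param seed integer seed.
#' @return list with `term_db` ([term_database()]), `foci_db`
#'   ([foci_database()]), `planted` (the planted table) and `texts`
#'   (named character vector).
#' @export
generate_meta_corpus <- function(spec, grid, seed) {
  stopifnot(inherits(spec, "corpus_spec"), inherits(grid, "voxel_grid"))
  set.seed(seed)
  bbox <- grid_bbox(grid)
  ids <- sprintf("a%04d", seq_len(spec$n_articles))
  term_sets <- vector("list", spec$n_articles)
  foci <- vector("list", spec$n_articles)
  texts <- character(spec$n_articles)
  filler <- c("study", "results", "participants", "activation", "signal")
  for (i in seq_len(spec$n_articles)) {
    has <- runif(length(spec$terms)) < spec$prevalence
    term_sets[[i]] <- spec$terms[has]
    n_bg <- rpois(1, spec$foci_rate)
    pts <- matrix(0, 0, 3)
    if (n_bg > 0) {
      pts <- cbind(runif(n_bg, bbox["lo", 1], bbox["hi", 1]),
                   runif(n_bg, bbox["lo", 2], bbox["hi", 2]),
                   runif(n_bg, bbox["lo", 3], bbox["hi", 3]))
    }
    if (nrow(spec$planted)) {
      for (p in seq_len(nrow(spec$planted))) {
        pl <- spec$planted[p, ]
        prob <- if (pl$term %in% term_sets[[i]]) pl$p_act else pl$base_rate
        if (runif(1) < prob) {
          pts <- rbind(pts, runif_sphere(c(pl$x, pl$y, pl$z), pl$radius))
        }
      }
    }
    foci[[i]] <- pts
    texts[i] <- paste(c(term_sets[[i]], filler), collapse = " ")
  }
  names(term_sets) <- ids
  names(foci) <- ids
  names(texts) <- ids
  list(term_db = term_database(term_sets),
       foci_db = foci_database(foci),
       planted = spec$planted,
       texts = texts)
}

#' Corpus JSON round trip
#'
#' Serializes a corpus as JSON: a schema tag plus one record per article
#' with `id`, `terms`, `foci` (list of `[x, y, z]` mm triplets) and
#' `text`.
#'
#' @param corpus a list as returned by [generate_meta_corpus()].
#' @param path file path.
#' @return `read_corpus` returns the corpus list (without `planted`).
#' @export
write_corpus <- function(corpus, path) {
  ids <- names(corpus$term_db$articles)
  arts <- lapply(ids, function(id) {
    f <- corpus$foci_db$articles[[id]]
    list(id = id,
         terms = as.list(corpus$term_db$articles[[id]]),
         foci = lapply(seq_len(nrow(f)), function(k) as.numeric(f[k, ])),
         text = if (!is.null(corpus$texts)) corpus$texts[[id]] else "")
  })
  jsonlite::write_json(list(schema = "accumaint/corpus-v1", articles = arts),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  obj <- jsonlite::read_json(path)
  arts <- obj$articles
  ids <- vapply(arts, function(a) a$id, character(1))
  term_sets <- lapply(arts, function(a) unlist(a$terms) %||% character())
  foci <- lapply(arts, function(a) {
    if (!length(a$foci)) return(matrix(numeric(), 0, 3))
    do.call(rbind, lapply(a$foci, function(p) as.numeric(unlist(p))))
  })
  texts <- vapply(arts, function(a) a$text %||% "", character(1))
  names(term_sets) <- ids
  names(foci) <- ids
  names(texts) <- ids
  list(term_db = term_database(term_sets),
       foci_db = foci_database(foci),
       texts = texts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
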