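#' Porter stemmer
#'
#' Classic Porter (1980) suffix-stripping stemmer, implemented in full
#' (steps 1a--5b with the measure, vowel, double-consonant and cvc
#' conditions). Used to collapse inflected forms ("decisions",
#' "deciding") onto shared stems when building term databases.
#'
#' @param words character vector.
#' @return character vector of stems.
#' @examples
#' porter_stem(c("decisions", "accumulation", "memories"))
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem_word, character(1), USE.NAMES = FALSE)
}

porter_stem_word <- function(w) {
  w <- tolower(w)
  if (nchar(w) <= 2) return(w)

  vowels <- c("a", "e", "i", "o", "u")
  cons_flags <- function(s) {
    ch <- strsplit(s, "")[[1]]
    f <- logical(length(ch))
    for (i in seq_along(ch)) {
      if (ch[i] %in% vowels) {
        f[i] <- FALSE
      } else if (ch[i] == "y") {
        f[i] <- if (i == 1) TRUE else !f[i - 1]
      } else {
        f[i] <- TRUE
      }
    }
    f
  }
  measure <- function(s) {
    if (!nchar(s)) return(0L)
    f <- cons_flags(s)
    m <- 0L
    for (i in seq_along(f)[-1]) if (!f[i - 1] && f[i]) m <- m + 1L
    m
  }
  has_vowel <- function(s) nchar(s) > 0 && any(!cons_flags(s))
  ends_double_cons <- function(s) {
    n <- nchar(s)
    if (n < 2) return(FALSE)
    a <- substr(s, n - 1, n - 1)
    b <- substr(s, n, n)
    a == b && utils::tail(cons_flags(s), 1)
  }
  ends_cvc <- function(s) {
    n <- nchar(s)
    if (n < 3) return(FALSE)
    f <- utils::tail(cons_flags(s), 3)
    last <- substr(s, n, n)
    f[1] && !f[2] && f[3] && !(last %in% c("w", "x", "y"))
  }
  ends_with <- function(s, suf) {
    n <- nchar(s)
    k <- nchar(suf)
    n > k && substr(s, n - k + 1, n) == suf
  }
  chop <- function(s, k) substr(s, 1, nchar(s) - k)

  # step 1a
  if (ends_with(w, "sses")) {
    w <- chop(w, 2)
  } else if (ends_with(w, "ies")) {
    w <- paste0(chop(w, 3), "i")
  } else if (!ends_with(w, "ss") && ends_with(w, "s")) {
    w <- chop(w, 1)
  }
  # step 1b
  if (ends_with(w, "eed")) {
    if (measure(chop(w, 3)) > 0) w <- chop(w, 1)
  } else {
    stripped <- FALSE
    if (ends_with(w, "ing") && has_vowel(chop(w, 3))) {
      w <- chop(w, 3)
      stripped <- TRUE
    } else if (ends_with(w, "ed") && has_vowel(chop(w, 2))) {
      w <- chop(w, 2)
      stripped <- TRUE
    }
    if (stripped) {
      if (ends_with(w, "at") || ends_with(w, "bl") || ends_with(w, "iz")) {
        w <- paste0(w, "e")
      } else if (ends_double_cons(w) &&
                 !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
        w <- chop(w, 1)
      } else if (measure(w) == 1 && ends_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }
  # step 1c
  if (ends_with(w, "y") && has_vowel(chop(w, 1))) {
    w <- paste0(chop(w, 1), "i")
  }

  apply_rules <- function(w, rules, cond) {
    sufs <- names(rules)
    sufs <- sufs[order(-nchar(sufs))]
    for (suf in sufs) {
      if (ends_with(w, suf)) {
        stem <- chop(w, nchar(suf))
        if (cond(stem, suf)) w <- paste0(stem, rules[[suf]])
        return(w)  # longest match decides; no fall-through
      }
    }
    w
  }
  # step 2
  w <- apply_rules(w, c(ational = "ate", tional = "tion", enci = "ence",
                        anci = "ance", izer = "ize", abli = "able",
                        alli = "al", entli = "ent", eli = "e", ousli = "ous",
                        ization = "ize", ation = "ate", ator = "ate",
                        alism = "al", iveness = "ive", fulness = "ful",
                        ousness = "ous", aliti = "al", iviti = "ive",
                        biliti = "ble"),
                   function(stem, suf) measure(stem) > 0)
  # step 3
  w <- apply_rules(w, c(icate = "ic", ative = "", alize = "al", iciti = "ic",
                        ical = "ic", ful = "", ness = ""),
                   function(stem, suf) measure(stem) > 0)
  # step 4
  w <- apply_rules(w, c(al = "", ance = "", ence = "", er = "", ic = "",
                        able = "", ible = "", ant = "", ement = "",
                        ment = "", ent = "", ion = "", ou = "", ism = "",
                        ate = "", iti = "", ous = "", ive = "", ize = ""),
                   function(stem, suf) {
                     if (measure(stem) <= 1) return(FALSE)
                     if (suf == "ion") {
                       last <- substr(stem, nchar(stem), nchar(stem))
                       return(last %in% c("s", "t"))
                     }
                     TRUE
                   })
  # step 5a
  if (ends_with(w, "e")) {
    stem <- chop(w, 1)
    m <- measure(stem)
    if (m > 1 || (m == 1 && !ends_cvc(stem))) w <- stem
  }
  # step 5b
  if (measure(w) > 1 && ends_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l") {
    w <- chop(w, 1)
  }
  w
}

#' English stop words
#'
#' The stop-word list shipped with the package (plain text, one word per
#' line), applied before stemming when building term databases.
#'
#' @return character vector.
#' @export
stop_words <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "accumaint")
  readLines(path, warn = FALSE)
}

# lowercase, strip non-letters, drop stop words, stem
tokenize_text <- function(text, stopwords = stop_words()) {
  toks <- strsplit(gsub("[^a-z]+", " ", tolower(text)), " +")[[1]]
  toks <- toks[nzchar(toks) & !toks %in% stopwords]
  porter_stem(toks)
}

# stemmed form of a (possibly two-word) term
stem_term <- function(term, stopwords = stop_words()) {
  words <- strsplit(tolower(term), "[^a-z]+")[[1]]
  words <- words[nzchar(words)]
  paste(porter_stem(words), collapse = " ")
}

term_excluded <- function(term, excluded) {
  for (e in excluded) {
    if (endsWith(e, "*")) {
      if (startsWith(term, substr(e, 1, nchar(e) - 1))) return(TRUE)
    } else if (term == e) {
      return(TRUE)
    }
  }
  FALSE
}

#' Term database
#'
#' Maps article ids to the set of terms they mention. Constructed either
#' directly (synthetic corpora) or from article texts via
#' [build_term_db()].
#'
#' @param articles named list: article id -> character vector of terms.
#' @return object of class `term_database` with fields `articles`, `terms`
#'   and per-term article `counts`.
#' @export
term_database <- function(articles) {
  stopifnot(is.list(articles), !is.null(names(articles)))
  all_terms <- sort(unique(unlist(articles)))
  counts <- vapply(all_terms, function(tm) {
    sum(vapply(articles, function(a) tm %in% a, logical(1)))
  }, integer(1))
  structure(list(articles = articles, terms = all_terms, counts = counts),
            class = "term_database")
}

#' @export
print.term_database <- function(x, ...) {
  cat(sprintf("term_database: %d articles, %d terms\n",
              length(x$articles), length(x$terms)))
  invisible(x)
}

term_members <- function(termdb, term) {
  if (!term %in% termdb$terms) stop(sprintf("term '%s' not in database", term))
  vapply(termdb$articles, function(a) term %in% a, logical(1))
}

#' Build a term database from article texts
#'
#' For each article the title/abstract/keyword string is lowercased,
#' stop-word filtered and stemmed; a term (one- or two-word) is assigned
#' to the article iff its stemmed form occurs at least once (two-word
#' terms must occur as consecutive stemmed tokens). Terms occurring in
#' fewer than `min_articles` articles and terms on the exclusion list
#' (prefix patterns allowed via a trailing `*`) are removed.
#'
#' @param article_texts named character vector or list: article id ->
#'   concatenated title + abstract + keywords.
#' @param term_list candidate terms (raw, unstemmed; at most two words).
#' @param min_articles minimum number of articles per retained term.
#' @param excluded_terms terms removed as redundant or overly general.
#' @return a [term_database()]; article entries hold the raw term names.
#' @export
build_term_db <- function(article_texts, term_list, min_articles = 15,
                          excluded_terms = c("face*", "house", "picture",
                                             "actor")) {
  if (!length(article_texts)) stop("empty article corpus")
  if (!length(term_list)) stop("empty term list")
  sw <- stop_words()
  term_list <- unique(term_list)
  keep <- !vapply(term_list, term_excluded, logical(1),
                  excluded = excluded_terms)
  term_list <- term_list[keep]
  stems <- vapply(term_list, stem_term, character(1), stopwords = sw)
  ok <- nzchar(stems) & lengths(strsplit(stems, " ")) <= 2
  term_list <- term_list[ok]
  stems <- stems[ok]

  articles <- lapply(article_texts, function(txt) {
    toks <- tokenize_text(txt, sw)
    uni <- unique(toks)
    bi <- if (length(toks) > 1) {
      unique(paste(toks[-length(toks)], toks[-1]))
    } else {
      character()
    }
    term_list[stems %in% c(uni, bi)]
  })
  names(articles) <- names(article_texts)
  counts <- vapply(term_list, function(tm) {
    sum(vapply(articles, function(a) tm %in% a, logical(1)))
  }, integer(1))
  retained <- term_list[counts >= min_articles]
  articles <- lapply(articles, function(a) a[a %in% retained])
  db <- term_database(articles)
  # keep retained-but-unobserved bookkeeping consistent
  db$terms <- sort(retained)
  db$counts <- counts[match(db$terms, term_list)]
  db
}
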