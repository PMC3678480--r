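#' Configuration for q-gram fuzzy matching
#'
#' Names are compared by breaking each string into overlapping chunks of
#' `q` letters ("q-grams") after prefixing `q - 1` padding characters.
#' Unlike the standard q-gram construction, *no* trailing pads are added:
#' the front pads up-weight the beginning of a name, while the ending —
#' where spellings most often differ (Latin gender endings, doubled
#' letters) — gets no extra weight. Similarity between two names is the
#' Jaccard ratio of their gram sets, and candidates scoring at or above
#' `threshold` are accepted.
#'
#' @param q Gram size; default 3.
#' @param threshold Acceptance threshold on the similarity score, a
#'   fraction in (0, 1]; default 0.70.
#' @param pad_char Single padding character; must not occur in normalized
#'   names. Defaults to the logical-and sign.
#' @return An object of class `fuzzy_config`.
#' @export
fuzzy_config <- function(q = 3L, threshold = 0.70, pad_char = "\u2227") {
  q <- as.integer(q)
  stopifnot(q >= 2L, threshold > 0, threshold <= 1,
            is_scalar_chr(pad_char), nchar(pad_char) == 1L)
  structure(
    list(q = q, n_front_pads = q - 1L, threshold = threshold,
         pad_char = pad_char),
    class = "fuzzy_config"
  )
}

#' Front-padded q-grams of a string
#'
#' Breaks `s` into its overlapping length-`q` chunks after prefixing
#' `q - 1` pad characters; no trailing pads are added and duplicate grams
#' are collapsed (set semantics, first occurrence kept for display order).
#' `"Mucuna holtoni"` yields the grams `"\u2227\u2227M"`, `"\u2227Mu"`,
#' `"Muc"`, `"ucu"`, and so on — 14 distinct grams in all.
#'
#' The case of `s` is preserved here; [similarity()] and the fuzzy index
#' case-fold before gramming so that scores are case-insensitive.
#'
#' @param s A string; the empty string yields an empty gram set.
#' @param cfg A [fuzzy_config()].
#' @return Character vector of distinct grams, in order of first
#'   occurrence.
#' @examples
#' qgrams("Mucuna holtoni")
#' @export
qgrams <- function(s, cfg = fuzzy_config()) {
  stopifnot(inherits(cfg, "fuzzy_config"))
  if (!is_scalar_chr(s) || !nzchar(s)) return(character())
  padded <- paste0(strrep(cfg$pad_char, cfg$n_front_pads), s)
  n <- nchar(padded)
  starts <- seq_len(n - cfg$q + 1L)
  unique(substring(padded, starts, starts + cfg$q - 1L))
}

#' Q-gram similarity between two strings
#'
#' The Jaccard ratio of the two front-padded q-gram sets:
#' size of the intersection over size of the union. The score is symmetric,
#' lies in \[0, 1\], equals 1 exactly when the gram sets coincide, and is 0
#' when either string is empty. Both strings are case-folded before
#' gramming.
#'
#' @param a,b Strings to compare.
#' @inheritParams qgrams
#' @return Similarity score in \[0, 1\].
#' @examples
#' similarity("Mucuna holtoni", "Mucuna holtonii")  # ~0.93
#' similarity("Mucuna restonii", "Mucuna holtonii") # below 0.70
#' @export
similarity <- function(a, b, cfg = fuzzy_config()) {
  ga <- qgrams(casefold_lower(a), cfg)
  gb <- qgrams(casefold_lower(b), cfg)
  if (!length(ga) || !length(gb)) return(0)
  length(intersect(ga, gb)) / length(union(ga, gb))
}

#' Blocked fuzzy lookup index over name strings
#'
#' To keep lookups fast, candidate comparisons are restricted to names
#' whose first `q` characters match the query's exactly (case-folded):
#' the index buckets names by that prefix and precomputes their gram sets.
#' A misspelling inside the first `q` characters therefore cannot be
#' recovered — the price of the blocking speed-up.
#'
#' @param names Character vector of names to index.
#' @inheritParams qgrams
#' @return An object of class `fuzzy_index`.
#' @export
build_index <- function(names, cfg = fuzzy_config()) {
  stopifnot(is.character(names))
  names <- names[nzchar(names)]
  folded <- casefold_lower(names)
  keys <- substr(folded, 1L, cfg$q)
  buckets <- split(seq_along(names), keys)
  entries <- lapply(seq_along(names), function(i) {
    list(name = names[i], grams = qgrams(folded[i], cfg))
  })
  structure(
    list(buckets = buckets, entries = entries, cfg = cfg),
    class = "fuzzy_index"
  )
}

#' @export
print.fuzzy_index <- function(x, ...) {
  cat("<fuzzy_index> ", length(x$entries), " names in ",
      length(x$buckets), " buckets (q = ", x$cfg$q,
      ", threshold = ", x$cfg$threshold, ")\n", sep = "")
  invisible(x)
}

#' Fuzzy lookup of a query against an index
#'
#' Scores the query against every indexed name sharing its first-`q`
#' character prefix and returns those at or above the threshold, sorted by
#' descending score with ties broken lexicographically.
#'
#' @param index A [build_index()] result.
#' @param query Query string.
#' @param cfg Optional [fuzzy_config()] overriding the index's threshold
#'   (the gram size must match the one the index was built with).
#' @return A data frame with columns `name` and `score`, best first;
#'   zero rows when nothing reaches the threshold or the prefix bucket is
#'   empty.
#' @export
lookup_fuzzy <- function(index, query, cfg = NULL) {
  stopifnot(inherits(index, "fuzzy_index"), is_scalar_chr(query))
  cfg <- cfg %||% index$cfg
  stopifnot(cfg$q == index$cfg$q)
  folded <- casefold_lower(query)
  key <- substr(folded, 1L, cfg$q)
  idx <- index$buckets[[key]]
  if (is.null(idx)) {
    return(data.frame(name = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  qg <- qgrams(folded, cfg)
  scores <- vapply(idx, function(i) {
    g <- index$entries[[i]]$grams
    if (!length(qg) || !length(g)) return(0)
    length(intersect(qg, g)) / length(union(qg, g))
  }, numeric(1))
  nm <- vapply(idx, function(i) index$entries[[i]]$name, character(1))
  keep <- scores >= cfg$threshold
  nm <- nm[keep]; scores <- scores[keep]
  ord <- order(-scores, nm, method = "radix")
  data.frame(name = nm[ord], score = scores[ord], stringsAsFactors = FALSE)
}
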