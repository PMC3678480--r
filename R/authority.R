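#' Parsed author citations
#'
#' Author citations ("authorities") disambiguate homonymous names: the same
#' binomial published by different authors denotes different taxa. An
#' `authority` object holds the citation broken into author groups:
#'
#' * `primary_authors` — the publishing author(s);
#' * `basionym_authors` — the parenthesized authors of the basionym,
#'   e.g. the `(L.)` in `"(L.) Merr."`;
#' * `ex_authors` — authors before an `"ex"` (the proposer, as opposed to
#'   the validating publisher);
#' * `excluded_authors` — authors after a `"non"` qualifier, which states
#'   the name is *not* the one those authors defined;
#' * `year` — a publication year, when one appears.
#'
#' Each author is an `author_token`: a surname (possibly an abbreviation
#' ending in a period, e.g. `"Ledeb."`) plus optional initials.
#'
#' @param primary_authors,basionym_authors,ex_authors,excluded_authors Lists
#'   of [author_token()] objects.
#' @param year Integer publication year or `NA`.
#' @param raw The original citation string.
#' @return An object of class `tm_authority`.
#' @seealso [parse_authority()], [compare_authorities()]
#' @export
authority <- function(primary_authors = list(), basionym_authors = list(),
                      ex_authors = list(), excluded_authors = list(),
                      year = NA_integer_, raw = "") {
  structure(
    list(
      primary_authors = primary_authors,
      basionym_authors = basionym_authors,
      ex_authors = ex_authors,
      excluded_authors = excluded_authors,
      year = as.integer(year),
      raw = as.character(raw)
    ),
    class = "tm_authority"
  )
}

new_authority <- function() authority()

#' @rdname authority
#' @param surname Author surname; `is_abbreviation` is set when it ends in a
#'   period.
#' @param initials Character vector of single-letter-with-period initials.
#' @export
author_token <- function(surname, initials = character()) {
  stopifnot(is_scalar_chr(surname), nzchar(surname))
  structure(
    list(
      surname = surname,
      initials = as.character(initials),
      is_abbreviation = endsWith(surname, ".")
    ),
    class = "author_token"
  )
}

#' Is an authority empty?
#'
#' @param a A [authority()] object.
#' @return `TRUE` when the citation carries no authors and no year.
#' @export
authority_is_empty <- function(a) {
  length(a$primary_authors) == 0L && length(a$basionym_authors) == 0L &&
    length(a$ex_authors) == 0L && length(a$excluded_authors) == 0L &&
    is.na(a$year)
}

#' Parse an author citation
#'
#' Tokenizes a citation string into author groups. The grammar is a
#' tolerant tokenizer plus a small state machine, not a full grammar of the
#' nomenclatural codes: a leading parenthesized group becomes the basionym
#' authors, `"ex"` separates proposer from publisher, `"non"` switches to
#' the excluded-author group, `"&"`, `"et"` and commas separate authors
#' within a group, and a four-digit token in 1750–2100 is read as the year.
#' Unrecognized fragments are attached to the nearest author group; the
#' parse never fails, so matching stays tolerant of messy citations.
#'
#' @param raw Citation string; the empty string yields an empty authority.
#' @return A [authority()] object.
#' @examples
#' parse_authority("(L.) Merr.")
#' parse_authority("Hook. & Arn. 1832")
#' parse_authority("non Vahl")
#' @export
parse_authority <- function(raw) {
  if (is.null(raw) || length(raw) == 0L || is.na(raw)) raw <- ""
  s <- str_norm(as.character(raw))
  if (!nzchar(s)) return(authority(raw = as.character(raw)))

  basionym <- list()
  # leading parenthesized group -> basionym authors
  m <- regmatches(s, regexec("^\\(([^)]*)\\)\\s*", s))[[1]]
  if (length(m)) {
    basionym <- parse_author_group(m[2])$authors
    s <- substr(s, nchar(m[1]) + 1L, nchar(s))
  }

  # split off a trailing "non ..." group (word-bounded, case-insensitive)
  excluded <- list()
  nx <- regexpr("(?i)(^|\\s)non(\\s|$)", s, perl = TRUE)
  if (nx > 0L) {
    head_part <- trimws(substr(s, 1L, nx - 1L))
    tail_part <- trimws(sub("(?i)^\\s*non\\s*", "",
                            substr(s, nx, nchar(s)), perl = TRUE))
    excluded <- parse_author_group(tail_part)$authors
    s <- head_part
  }

  year <- NA_integer_
  main <- parse_author_group(s)
  year <- main$year
  primary <- main$authors
  ex_authors <- main$ex_authors

  authority(
    primary_authors = primary, basionym_authors = basionym,
    ex_authors = ex_authors, excluded_authors = excluded,
    year = year, raw = as.character(raw)
  )
}

# Parse one author group: returns authors, ex_authors and a year if seen.
parse_author_group <- function(s) {
  out <- list(authors = list(), ex_authors = list(), year = NA_integer_)
  s <- trimws(s)
  if (!nzchar(s)) return(out)

  # normalize separators to a single split token
  s <- gsub("\\s*(&|,|\\bet\\b)\\s*", "\x1f", s, perl = TRUE)
  phrases <- strsplit(s, "\x1f", fixed = TRUE)[[1]]
  phrases <- phrases[nzchar(trimws(phrases))]

  current <- "authors"
  for (ph in phrases) {
    toks <- strsplit(trimws(ph), " ", fixed = TRUE)[[1]]
    # an "ex" inside a phrase: authors so far move to ex_authors
    exi <- which(casefold_lower(toks) == "ex")
    if (length(exi)) {
      before <- toks[seq_len(exi[1] - 1L)]
      after <- toks[-seq_len(exi[1])]
      out$ex_authors <- c(out$ex_authors, out$authors)
      out$authors <- list()
      if (length(before)) {
        tok <- phrase_to_token(before)
        if (!is.null(tok$author)) out$ex_authors <- c(out$ex_authors, list(tok$author))
        if (!is.na(tok$year)) out$year <- tok$year
      }
      toks <- after
    }
    if (!length(toks)) next
    tok <- phrase_to_token(toks)
    if (!is.null(tok$author)) out[[current]] <- c(out[[current]], list(tok$author))
    if (!is.na(tok$year) && is.na(out$year)) out$year <- tok$year
  }
  out
}

# Turn the tokens of one author phrase into an author_token (+ year).
# Leading single-letter-with-period tokens are initials while more tokens
# follow; the remainder joins into the surname (keeps particles like "de").
phrase_to_token <- function(toks) {
  year <- NA_integer_
  is_year <- grepl("^\\(?[0-9]{4}\\)?[.,]?$", toks) &
    vapply(toks, function(t) {
      y <- suppressWarnings(as.integer(gsub("[^0-9]", "", t)))
      !is.na(y) && y >= 1750L && y <= 2100L
    }, logical(1))
  if (any(is_year)) {
    year <- as.integer(gsub("[^0-9]", "", toks[which(is_year)[1]]))
    toks <- toks[!is_year]
  }
  if (!length(toks)) return(list(author = NULL, year = year))

  initials <- character()
  while (length(toks) > 1L && grepl("^[A-Z]\\.$", toks[1])) {
    initials <- c(initials, toks[1])
    toks <- toks[-1]
  }
  surname <- paste(toks, collapse = " ")
  list(author = author_token(surname, initials), year = year)
}

#' Format an author citation
#'
#' Renders an [authority()] back to its canonical string form:
#' `"(basionym) ex-authors ex primary year non excluded"`, with authors in a
#' group joined by `" & "`. Parsing the result reproduces the structured
#' fields.
#'
#' @param a A [authority()] object.
#' @return A single string; `""` for an empty authority.
#' @export
format_authority <- function(a) {
  stopifnot(inherits(a, "tm_authority"))
  if (authority_is_empty(a)) return("")
  fmt_group <- function(g) {
    paste(vapply(g, format_author_token, character(1)), collapse = " & ")
  }
  parts <- character()
  if (length(a$basionym_authors)) {
    parts <- c(parts, paste0("(", fmt_group(a$basionym_authors), ")"))
  }
  if (length(a$ex_authors)) {
    parts <- c(parts, fmt_group(a$ex_authors), "ex")
  }
  if (length(a$primary_authors)) parts <- c(parts, fmt_group(a$primary_authors))
  if (!is.na(a$year)) parts <- c(parts, as.character(a$year))
  if (length(a$excluded_authors)) {
    parts <- c(parts, "non", fmt_group(a$excluded_authors))
  }
  paste(parts, collapse = " ")
}

format_author_token <- function(tok) {
  paste(c(tok$initials, tok$surname), collapse = " ")
}

#' @export
print.tm_authority <- function(x, ...) {
  if (authority_is_empty(x)) cat("<authority> (empty)\n")
  else cat("<authority> ", format_authority(x), "\n", sep = "")
  invisible(x)
}

authority_equal <- function(a, b) {
  tok_eq <- function(x, y) {
    identical(x$surname, y$surname) && identical(x$initials, y$initials)
  }
  grp_eq <- function(g, h) {
    if (length(g) != length(h)) return(FALSE)
    if (!length(g)) return(TRUE)
    all(mapply(tok_eq, g, h))
  }
  grp_eq(a$primary_authors, b$primary_authors) &&
    grp_eq(a$basionym_authors, b$basionym_authors) &&
    grp_eq(a$ex_authors, b$ex_authors) &&
    grp_eq(a$excluded_authors, b$excluded_authors) &&
    identical(is.na(a$year), is.na(b$year)) &&
    (is.na(a$year) || a$year == b$year)
}
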