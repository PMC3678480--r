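#' Matching configuration
#'
#' Controls the cascade [match_name()] runs for every query:
#'
#' 1. exact match — binomial plus a literally identical author citation;
#' 2. name-only match — the binomial matches and the authorities are
#'    compatible (either side missing, or agreeing under the bespoke
#'    comparator; a plain disagreement is accepted with a warning note
#'    unless `allow_authority_mismatch = FALSE`). A candidate whose
#'    authority is *incompatible* — the query's author appears after a
#'    "non" qualifier, or vice versa — is vetoed outright;
#' 3. infraspecific promotion — an unmatched name below species rank is
#'    retried as its parent binomial, for all infraspecific names, only
#'    nominal ones (epithet repeated, e.g. "Zea mays subsp. mays"), or
#'    never;
#' 4. fuzzy match — blocked q-gram lookup at `fuzzy$threshold`, followed
#'    by the same authority filtering.
#'
#' When several candidates survive (homonyms), `homonym_policy` decides:
#' `"prefer_accepted"` takes the single candidate hit via an accepted
#' name when exactly one such candidate exists (otherwise the query is
#' ambiguous); `"interactive"` hands the candidates to the `decider`
#' callback; `"reject"` marks the query ambiguous. The default `"auto"`
#' uses `prefer_accepted` for queries without an authority and
#' `interactive` for queries that have one.
#'
#' @param allow_authority_mismatch Accept name-only matches whose
#'   authorities disagree (non-excluding); default `TRUE`, with a warning
#'   note in the result.
#' @param infraspecific_promotion `"nominal_only"` (default), `"all"` or
#'   `"off"`.
#' @param fuzzy A [fuzzy_config()].
#' @param homonym_policy `"auto"` (default), `"prefer_accepted"`,
#'   `"interactive"` or `"reject"`.
#' @param max_fuzzy_candidates Cap on the alternatives listed in a fuzzy
#'   result.
#' @return An object of class `match_config`.
#' @export
match_config <- function(allow_authority_mismatch = TRUE,
                         infraspecific_promotion = c("nominal_only", "all", "off"),
                         fuzzy = fuzzy_config(),
                         homonym_policy = c("auto", "prefer_accepted",
                                            "interactive", "reject"),
                         max_fuzzy_candidates = 5L) {
  infraspecific_promotion <- match.arg(infraspecific_promotion)
  homonym_policy <- match.arg(homonym_policy)
  stopifnot(inherits(fuzzy, "fuzzy_config"), max_fuzzy_candidates >= 1L)
  structure(
    list(allow_authority_mismatch = isTRUE(allow_authority_mismatch),
         infraspecific_promotion = infraspecific_promotion,
         fuzzy = fuzzy, homonym_policy = homonym_policy,
         max_fuzzy_candidates = as.integer(max_fuzzy_candidates)),
    class = "match_config"
  )
}

#' Compare two author citations
#'
#' Author citations are short and abbreviation-ridden, so they are
#' compared component-wise rather than by string similarity. The verdict
#' is one of:
#'
#' * `"incompatible"` — one side's primary or basionym author appears in
#'   the other's excluded ("non") authors: explicit evidence the names
#'   denote different taxa. A naive string comparison would happily match
#'   "Vahl" against "non Vahl"; this comparator vetoes it.
#' * `"neutral"` — either citation is empty, or one side has no primary
#'   authors to compare: missing information, not evidence.
#' * `"agree"` — the primary surnames match pairwise, abbreviation-aware
#'   ("Ledeb." matches "Ledebour"); initials and years are compared only
#'   when present on both sides, and basionym authors only when both
#'   citations carry them.
#' * `"disagree"` — anything else.
#'
#' @param a,b [authority()] objects.
#' @return A single string: `"agree"`, `"neutral"`, `"disagree"` or
#'   `"incompatible"`.
#' @examples
#' compare_authorities(parse_authority("Vahl"), parse_authority("non Vahl"))
#' compare_authorities(parse_authority("Ledeb"), parse_authority("Ledeb."))
#' @export
compare_authorities <- function(a, b) {
  stopifnot(inherits(a, "tm_authority"), inherits(b, "tm_authority"))
  pos_a <- c(a$primary_authors, a$basionym_authors, a$ex_authors)
  pos_b <- c(b$primary_authors, b$basionym_authors, b$ex_authors)
  if (cross_match(pos_a, b$excluded_authors) ||
      cross_match(pos_b, a$excluded_authors)) {
    return("incompatible")
  }
  if (authority_is_empty(a) || authority_is_empty(b)) return("neutral")
  if (!length(a$primary_authors) || !length(b$primary_authors)) {
    return("neutral")
  }
  agree <- group_match(a$primary_authors, b$primary_authors) &&
    years_compatible(a$year, b$year) &&
    (!length(a$basionym_authors) || !length(b$basionym_authors) ||
       group_match(a$basionym_authors, b$basionym_authors))
  if (agree) "agree" else "disagree"
}

cross_match <- function(authors, excluded) {
  if (!length(authors) || !length(excluded)) return(FALSE)
  any(vapply(authors, function(x) {
    any(vapply(excluded, function(y) author_match(x, y), logical(1)))
  }, logical(1)))
}

group_match <- function(g, h) {
  if (length(g) != length(h)) return(FALSE)
  all(mapply(author_match, g, h))
}

years_compatible <- function(y1, y2) {
  is.na(y1) || is.na(y2) || y1 == y2
}

# Abbreviation-aware surname comparison: equal after stripping the
# trailing period, or the abbreviated side is a prefix of the full one.
# Initials only count when both sides carry them.
author_match <- function(x, y) {
  sx <- casefold_lower(sub("\\.$", "", x$surname))
  sy <- casefold_lower(sub("\\.$", "", y$surname))
  surname_ok <- sx == sy ||
    (x$is_abbreviation && nzchar(sx) && startsWith(sy, sx)) ||
    (y$is_abbreviation && nzchar(sy) && startsWith(sx, sy))
  if (!surname_ok) return(FALSE)
  if (length(x$initials) && length(y$initials)) {
    k <- min(length(x$initials), length(y$initials))
    return(identical(x$initials[seq_len(k)], y$initials[seq_len(k)]))
  }
  TRUE
}

new_match_result <- function(query, outcome, matched_taxon = NULL,
                             accepted_name = NULL, step = NA_character_,
                             score = NA_real_, alternatives = list(),
                             notes = character()) {
  structure(
    list(query = query, outcome = outcome, matched_taxon = matched_taxon,
         accepted_name = accepted_name, step = step, score = score,
         alternatives = alternatives, notes = notes),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", format_name(x$query), " -> ", sep = "")
  if (x$outcome == "matched") {
    cat(format_name(x$accepted_name), " [", x$step,
        if (!is.na(x$score)) sprintf(", score %.3f", x$score), "]\n",
        sep = "")
  } else {
    cat(x$outcome, "\n")
  }
  if (length(x$notes)) cat("  ", paste(x$notes, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Match one name against a reference synonymy
#'
#' Runs the cascade described in [match_config()] and returns a
#' `match_result` recording the outcome, the step that produced it, the
#' fuzzy score when relevant, the alternatives that were in play, and
#' notes on every non-obvious decision — so a batch run leaves a full
#' audit trail.
#'
#' @param query A [taxon_name()] (or a string, parsed botanically).
#' @param reference A [taxon_set()].
#' @param cfg A [match_config()].
#' @param decider Callback for interactive homonym resolution:
#'   `function(query, candidates)` returning `list(action = "pick",
#'   index = i)`, `list(action = "replace", name = <taxon_name>)` or
#'   `list(action = "reject")`. Required when the homonym policy resolves
#'   to `"interactive"`; a policy of `"interactive"` with no decider is a
#'   configuration error.
#' @return A `match_result` with outcome `"matched"`, `"ambiguous"`,
#'   `"unmatched"` or `"rejected_by_user"`.
#' @export
match_name <- function(query, reference, cfg = match_config(),
                       decider = NULL) {
  if (is.character(query)) query <- parse_name(query)
  stopifnot(inherits(query, "taxon_name"), inherits(reference, "taxon_set"),
            inherits(cfg, "match_config"))

  res <- match_binomial_step(query, reference, cfg, decider)
  if (!is.null(res) && res$outcome != "unmatched") return(res)
  carried <- if (is.null(res)) character() else res$notes

  # step 3: infraspecific promotion
  if (query$rank %in% c("subspecies", "variety", "form") &&
      cfg$infraspecific_promotion != "off") {
    nominal <- identical(query$infraspecific_epithet, query$epithet)
    if (cfg$infraspecific_promotion == "all" || nominal) {
      parent <- taxon_name(
        genus = query$genus, epithet = query$epithet, rank = "species",
        hybrid = query$hybrid, authority = query$authority,
        raw = query$raw
      )
      res <- match_binomial_step(parent, reference, cfg, decider,
                                 original_query = query)
      if (!is.null(res) && res$outcome == "matched") {
        res$step <- "infraspecific_promotion"
        res$notes <- c(sprintf("promoted '%s' to parent species '%s'",
                               format_name(query, FALSE),
                               format_name(parent, FALSE)), res$notes)
        res$query <- query
        return(res)
      }
    }
  }

  # step 4: fuzzy lookup over the reference's binomial keys
  res <- match_fuzzy_step(query, reference, cfg, decider)
  if (!is.null(res)) {
    res$notes <- unique(c(carried, res$notes))
    return(res)
  }

  new_match_result(query, "unmatched", notes = carried)
}

# Steps 1-2: exact binomial hit, authority handling. Returns NULL when the
# binomial is absent or every candidate is filtered away.
match_binomial_step <- function(query, reference, cfg, decider,
                                original_query = NULL, fuzzy_score = NA_real_,
                                pre_notes = character()) {
  key <- binomial_key(query)
  hits <- reference$index[[key]]
  if (is.null(hits)) return(NULL)
  entries <- lapply(hits, function(e) {
    list(taxon = reference$taxa[[e$taxon_i]], name = e$name,
         is_accepted = e$is_accepted)
  })
  resolve_candidates(query, entries, cfg, decider, reference,
                     fuzzy_score = fuzzy_score, pre_notes = pre_notes)
}

# Shared by the exact and fuzzy paths: authority filtering + homonym policy.
resolve_candidates <- function(query, entries, cfg, decider, reference,
                               fuzzy_score = NA_real_,
                               pre_notes = character()) {
  q_auth_norm <- casefold_lower(format_authority(query$authority))
  verdicts <- vapply(entries, function(e) {
    compare_authorities(query$authority, e$name$authority)
  }, character(1))

  vetoed <- verdicts == "incompatible"
  notes <- pre_notes
  if (any(vetoed)) {
    notes <- c(notes, vapply(which(vetoed), function(i) {
      sprintf("candidate '%s' vetoed: authorities incompatible",
              format_name(entries[[i]]$name))
    }, character(1)))
  }
  entries <- entries[!vetoed]
  verdicts <- verdicts[!vetoed]
  if (!length(entries)) {
    if (length(notes)) {
      return(new_match_result(query, "unmatched", notes = notes))
    }
    return(NULL)
  }

  is_fuzzy <- !is.na(fuzzy_score)

  # step 1: literal authority equality (both-empty counts as equal)
  if (!is_fuzzy) {
    exact <- vapply(entries, function(e) {
      identical(q_auth_norm, casefold_lower(format_authority(e$name$authority)))
    }, logical(1))
    if (any(exact)) {
      return(finish_match(query, entries[exact], cfg, decider,
                          step = "exact_with_authority", notes = notes))
    }
  }

  # step 2 (or fuzzy tail): keep the best verdict class available
  if (any(verdicts == "agree")) {
    entries <- entries[verdicts == "agree"]
  } else if (any(verdicts == "neutral")) {
    entries <- entries[verdicts == "neutral"]
  } else {
    if (!cfg$allow_authority_mismatch) {
      return(new_match_result(
        query, "unmatched",
        notes = c(notes, "name matched but authorities disagree and authority mismatches are disallowed")
      ))
    }
    notes <- c(notes, "authorities disagree; match accepted under allow_authority_mismatch")
  }
  finish_match(query, entries, cfg, decider,
               step = if (is_fuzzy) "fuzzy" else "name_only",
               score = fuzzy_score, notes = notes)
}

finish_match <- function(query, entries, cfg, decider, step,
                         score = NA_real_, notes = character()) {
  # collapse entries pointing at the same taxon (accepted + synonym hit)
  ids <- vapply(entries, function(e) accepted_identity(e$taxon$accepted_name),
                character(1))
  if (length(unique(ids)) == 1L) {
    e <- entries[[1]]
    return(new_match_result(query, "matched", matched_taxon = e$taxon,
                            accepted_name = e$taxon$accepted_name,
                            step = step, score = score,
                            alternatives = list(), notes = notes))
  }
  entries <- entries[!duplicated(ids)]
  alternatives <- lapply(entries, function(e) e$name)

  policy <- cfg$homonym_policy
  if (policy == "auto") {
    policy <- if (authority_is_empty(query$authority)) "prefer_accepted"
              else "interactive"
  }

  if (policy == "prefer_accepted") {
    acc <- vapply(entries, function(e) e$is_accepted, logical(1))
    if (sum(acc) == 1L) {
      e <- entries[[which(acc)]]
      return(new_match_result(
        query, "matched", matched_taxon = e$taxon,
        accepted_name = e$taxon$accepted_name, step = step, score = score,
        alternatives = alternatives,
        notes = c(notes, "homonym resolved in favour of the accepted name")
      ))
    }
    return(new_match_result(query, "ambiguous", alternatives = alternatives,
                            step = step, score = score,
                            notes = c(notes, "homonym: no single accepted-name candidate")))
  }

  if (policy == "reject") {
    return(new_match_result(query, "ambiguous", alternatives = alternatives,
                            step = step, score = score,
                            notes = c(notes, "homonym: rejected by policy")))
  }

  # interactive
  if (is.null(decider)) {
    abort_tm("homonym policy 'interactive' requires a decider callback",
             "taxonmatch_config_error")
  }
  choice <- decider(query, entries)
  action <- choice$action %||% "reject"
  if (identical(action, "pick")) {
    e <- entries[[choice$index]]
    return(new_match_result(query, "matched", matched_taxon = e$taxon,
                            accepted_name = e$taxon$accepted_name,
                            step = step, score = score,
                            alternatives = alternatives,
                            notes = c(notes, "homonym resolved by user")))
  }
  if (identical(action, "replace")) {
    return(new_match_result(
      query, "rejected_by_user", alternatives = alternatives,
      notes = c(notes, sprintf("user supplied replacement '%s'",
                               format_name(choice$name)))
    ))
  }
  new_match_result(query, "rejected_by_user", alternatives = alternatives,
                   notes = c(notes, "homonym: all candidates rejected by user"))
}

match_fuzzy_step <- function(query, reference, cfg, decider) {
  fidx <- reference_fuzzy_index(reference, cfg$fuzzy)
  key <- binomial_key(query)
  cand <- lookup_fuzzy(fidx, key, cfg$fuzzy)
  if (!nrow(cand)) return(NULL)
  notes <- character()
  n_alt <- min(nrow(cand), cfg$max_fuzzy_candidates)
  if (nrow(cand) > 1L) {
    notes <- sprintf("fuzzy candidates: %s",
                     paste(sprintf("%s (%.2f)", cand$name[seq_len(n_alt)],
                                   cand$score[seq_len(n_alt)]),
                           collapse = "; "))
  }
  for (i in seq_len(nrow(cand))) {
    hits <- reference$index[[cand$name[i]]]
    if (is.null(hits)) next
    entries <- lapply(hits, function(e) {
      list(taxon = reference$taxa[[e$taxon_i]], name = e$name,
           is_accepted = e$is_accepted)
    })
    res <- resolve_candidates(query, entries, cfg, decider, reference,
                              fuzzy_score = cand$score[i],
                              pre_notes = notes)
    if (!is.null(res) && res$outcome != "unmatched") return(res)
    if (!is.null(res) && res$outcome == "unmatched") notes <- res$notes
  }
  if (length(notes)) {
    return(new_match_result(query, "unmatched", notes = notes))
  }
  NULL
}

# The fuzzy index over a reference's binomial keys is cached on the set.
reference_fuzzy_index <- function(reference, fcfg) {
  cached <- attr(reference, "fuzzy_index")
  if (!is.null(cached) && identical(cached$cfg, fcfg)) return(cached)
  build_index(names(reference$index), fcfg)
}

#' Precompute and cache a reference's fuzzy index
#'
#' [match_name()] builds the blocked q-gram index over a reference's
#' binomials on the fly; for batch runs, attach it once with this helper.
#'
#' @param reference A [taxon_set()].
#' @param fcfg A [fuzzy_config()].
#' @return The reference with the index cached in an attribute.
#' @export
prepare_reference <- function(reference, fcfg = fuzzy_config()) {
  stopifnot(inherits(reference, "taxon_set"))
  attr(reference, "fuzzy_index") <- build_index(names(reference$index), fcfg)
  reference
}

#' Match a whole dataset against a reference
#'
#' Matches each `(name, data)` record in input order, reassigning matched
#' records to their reference accepted names: the output taxon set is
#' keyed by those accepted names, and each matched record's data mapping
#' is attached to its taxon (later records win on key collision, noted in
#' the log). Unmatched and ambiguous queries appear only in the log.
#'
#' @param queries A list of records, each `list(name = <taxon_name>,
#'   data = <named list>)` (as produced by [read_records_csv()]).
#' @param reference A [taxon_set()].
#' @param cfg A [match_config()].
#' @param decider Optional interactive callback; see [match_name()].
#' @return `list(taxa = <taxon_set>, log = <list of match_result>)`.
#' @export
match_dataset <- function(queries, reference, cfg = match_config(),
                          decider = NULL) {
  stopifnot(inherits(reference, "taxon_set"))
  reference <- prepare_reference(reference, cfg$fuzzy)
  out <- list()   # identity -> taxon
  log <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    if (is.null(q$name)) {
      log[[i]] <- new_match_result(
        taxon_name("Unknown", raw = q$raw %||% ""), "unmatched",
        notes = sprintf("unparseable input row skipped: %s",
                        q$reason %||% "no name")
      )
      next
    }
    res <- match_name(q$name, reference, cfg, decider)
    log[[i]] <- res
    if (res$outcome == "matched") {
      id <- accepted_identity(res$accepted_name)
      t <- out[[id]] %||% res$matched_taxon
      for (k in names(q$data %||% list())) {
        if (!is.null(t$data[[k]]) && !identical(t$data[[k]], q$data[[k]])) {
          log[[i]]$notes <- c(log[[i]]$notes,
                              sprintf("data key '%s' overwritten", k))
        }
        t$data[[k]] <- q$data[[k]]
      }
      out[[id]] <- t
    }
  }
  list(taxa = taxon_set(unname(out)), log = log)
}

#' Tabulate a match log
#'
#' Flattens a list of `match_result` objects into the standard match-log
#' data frame (one row per query, input order): original name and
#' authority, matched accepted name and authority, cascade step, score,
#' outcome, semicolon-joined alternatives and notes.
#'
#' @param results List of `match_result` objects.
#' @return A data frame.
#' @export
match_log_df <- function(results) {
  fmt_or <- function(x, f, default = "") if (is.null(x)) default else f(x)
  data.frame(
    original_name = vapply(results, function(r) format_name(r$query, FALSE),
                           character(1)),
    original_authority = vapply(results, function(r)
      format_authority(r$query$authority), character(1)),
    matched_accepted_name = vapply(results, function(r)
      fmt_or(r$accepted_name, function(n) format_name(n, FALSE)),
      character(1)),
    matched_authority = vapply(results, function(r)
      fmt_or(r$accepted_name, function(n) format_authority(n$authority)),
      character(1)),
    step = vapply(results, function(r)
      if (is.na(r$step)) "" else r$step, character(1)),
    score = vapply(results, function(r) r$score, numeric(1)),
    outcome = vapply(results, function(r) r$outcome, character(1)),
    alternatives = vapply(results, function(r)
      paste(vapply(r$alternatives, format_name, character(1)),
            collapse = "; "), character(1)),
    notes = vapply(results, function(r) paste(r$notes, collapse = "; "),
                   character(1)),
    stringsAsFactors = FALSE
  )
}
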