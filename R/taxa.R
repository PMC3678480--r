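#' Taxa and taxon sets
#'
#' A `taxon` holds one accepted name, a set of synonyms, an arbitrary
#' data mapping (trait values, provenance, anything attached to the
#' species), and an optional distribution as a set of region codes. A
#' `taxon_set` is a collection of taxa with an index over *all* their
#' names — accepted and synonym alike — keyed by the case-folded binomial
#' (authority excluded), so a taxon can be found quickly from a binomial
#' string. Because the key omits the authority, homonyms collide in the
#' index by design and are pulled apart downstream by authority
#' comparison.
#'
#' @param accepted_name A [taxon_name()], the name the reference source
#'   treats as current.
#' @param synonyms List of [taxon_name()] objects; must not repeat the
#'   accepted name or each other (by formatted string).
#' @param data Named list of attached values.
#' @param distribution Character vector of region codes.
#' @return `taxon()` returns an object of class `taxon`.
#' @export
taxon <- function(accepted_name, synonyms = list(), data = list(),
                  distribution = character()) {
  stopifnot(inherits(accepted_name, "taxon_name"))
  if (inherits(synonyms, "taxon_name")) synonyms <- list(synonyms)
  fmt <- vapply(synonyms, format_name, character(1))
  if (anyDuplicated(fmt)) {
    abort_tm("duplicate synonyms in taxon", "taxonmatch_taxon_error")
  }
  if (format_name(accepted_name) %in% fmt) {
    abort_tm("accepted name listed among its own synonyms",
             "taxonmatch_taxon_error")
  }
  structure(
    list(accepted_name = accepted_name, synonyms = synonyms,
         data = as.list(data), distribution = as.character(distribution)),
    class = "taxon"
  )
}

#' @export
print.taxon <- function(x, ...) {
  cat("<taxon> ", format_name(x$accepted_name), "\n", sep = "")
  if (length(x$synonyms)) {
    cat("  synonyms: ",
        paste(vapply(x$synonyms, format_name, character(1)), collapse = "; "),
        "\n", sep = "")
  }
  if (length(x$data)) {
    cat("  data: ", paste(names(x$data), collapse = ", "), "\n", sep = "")
  }
  if (length(x$distribution)) {
    cat("  distribution: ", paste(x$distribution, collapse = " "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @rdname taxon
#' @param taxa List of `taxon` objects to index.
#' @return `taxon_set()` returns an object of class `taxon_set`.
#' @export
taxon_set <- function(taxa = list()) {
  if (inherits(taxa, "taxon")) taxa <- list(taxa)
  ts <- structure(list(taxa = list(), index = list(), ids = character()),
                  class = "taxon_set")
  for (t in taxa) ts <- add_taxon(ts, t)
  ts
}

#' @export
print.taxon_set <- function(x, ...) {
  cat("<taxon_set> ", length(x$taxa), " taxa, ",
      length(x$index), " indexed binomials\n", sep = "")
  invisible(x)
}

#' @export
length.taxon_set <- function(x) length(x$taxa)

# Identity of an accepted name for duplicate detection: binomial + authority.
accepted_identity <- function(name) {
  paste(binomial_key(name), casefold_lower(format_authority(name$authority)),
        sep = " | ")
}

index_add <- function(index, key, entry) {
  index[[key]] <- c(index[[key]], list(entry))
  index
}

#' Add a taxon to a set
#'
#' Indexes the taxon's accepted name and every synonym. Adding a second
#' taxon with the same accepted binomial *and* the same authority is
#' rejected; the same binomial under a different authority is a homonym
#' and is allowed.
#'
#' @param ts A [taxon_set()].
#' @param t A [taxon()].
#' @return The updated `taxon_set`.
#' @export
add_taxon <- function(ts, t) {
  stopifnot(inherits(ts, "taxon_set"), inherits(t, "taxon"))
  id <- accepted_identity(t$accepted_name)
  if (id %in% ts$ids) {
    abort_tm(sprintf("duplicate accepted name %s",
                     dQuote(format_name(t$accepted_name))),
             "taxonmatch_duplicate_error")
  }
  ts$taxa <- c(ts$taxa, list(t))
  ts$ids <- c(ts$ids, id)
  ti <- length(ts$taxa)
  ts$index <- index_add(ts$index, binomial_key(t$accepted_name),
                        list(taxon_i = ti, name = t$accepted_name,
                             is_accepted = TRUE))
  for (syn in t$synonyms) {
    ts$index <- index_add(ts$index, binomial_key(syn),
                          list(taxon_i = ti, name = syn,
                               is_accepted = FALSE))
  }
  ts
}

#' Look up a binomial in a taxon set
#'
#' Returns every index entry whose binomial (authority ignored) matches
#' the query string, accepted-name hits ordered before synonym hits.
#' Homonyms therefore return several entries.
#'
#' @param ts A [taxon_set()].
#' @param binomial A binomial string (or a [taxon_name()]).
#' @return A list of entries, each `list(taxon, name, is_accepted)` where
#'   `name` is the name exactly as recorded in the set; empty list when
#'   the binomial is unknown.
#' @export
get_by_binomial <- function(ts, binomial) {
  stopifnot(inherits(ts, "taxon_set"))
  key <- if (inherits(binomial, "taxon_name")) {
    binomial_key(binomial)
  } else {
    binomial_key(parse_name(binomial))
  }
  hits <- ts$index[[key]]
  if (is.null(hits)) return(list())
  acc <- vapply(hits, function(e) e$is_accepted, logical(1))
  hits <- hits[order(!acc)]
  lapply(hits, function(e) {
    list(taxon = ts$taxa[[e$taxon_i]], name = e$name,
         is_accepted = e$is_accepted)
  })
}

#' Combine several taxon sets into one
#'
#' Merges collections that have already been matched against the same
#' reference: taxa with equal accepted names (binomial + authority) are
#' merged — synonym sets unioned, data mappings merged with later sets
#' winning on key collision, distributions unioned. Collisions are
#' recorded in the returned set's `"merge_log"` attribute.
#'
#' @param sets A list of [taxon_set()] objects.
#' @return A single `taxon_set`; inspect `attr(result, "merge_log")` for
#'   data-key collisions.
#' @export
combine_taxon_sets <- function(sets) {
  if (inherits(sets, "taxon_set")) sets <- list(sets)
  stopifnot(all(vapply(sets, inherits, logical(1), "taxon_set")))
  merged <- list()   # identity -> taxon
  log <- character()
  for (si in seq_along(sets)) {
    for (t in sets[[si]]$taxa) {
      id <- accepted_identity(t$accepted_name)
      if (is.null(merged[[id]])) {
        merged[[id]] <- t
        next
      }
      old <- merged[[id]]
      syn_fmt <- vapply(old$synonyms, format_name, character(1))
      for (syn in t$synonyms) {
        f <- format_name(syn)
        if (!(f %in% syn_fmt) && f != format_name(old$accepted_name)) {
          old$synonyms <- c(old$synonyms, list(syn))
          syn_fmt <- c(syn_fmt, f)
        }
      }
      for (k in names(t$data)) {
        if (!is.null(old$data[[k]]) && !identical(old$data[[k]], t$data[[k]])) {
          log <- c(log, sprintf(
            "%s: key '%s' overwritten by set %d",
            format_name(old$accepted_name), k, si))
        }
        old$data[[k]] <- t$data[[k]]
      }
      old$distribution <- union(old$distribution, t$distribution)
      merged[[id]] <- old
    }
  }
  out <- taxon_set(unname(merged))
  attr(out, "merge_log") <- log
  out
}
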