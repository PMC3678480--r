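#' Region index for distribution standardization
#'
#' Different sources describe a species' range with different region
#' vocabularies — country names, historical names, informal "major
#' regions". A `region_index` maps all of these onto one canonical scheme
#' (such as the TDWG World Geographical Scheme, which defines regions at
#' four nested levels): each canonical region has a code and a name,
#' `aliases` map alternative spellings to one or more codes, and `groups`
#' name larger units that expand to a set of member codes. Name lookup
#' normalizes case and strips diacritics, so "Côte d'Ivoire" and "cote
#' d'ivoire" hit the same entry.
#'
#' The loader takes any table with this schema — the bundled
#' `regions_synthetic.csv` fixture (an invented 12-region scheme used by
#' the test-suite) or a user-supplied extract of the published TDWG
#' tables, which are not bundled.
#'
#' @param path CSV with columns `code`, `name`, `level`, `aliases`
#'   (pipe-separated alternative names) and `groups` (pipe-separated
#'   group names the region belongs to).
#' @return An object of class `region_index`.
#' @export
load_region_index <- function(path) {
  if (!file.exists(path)) {
    abort_tm(sprintf("no such file: %s", path), "taxonmatch_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8-BOM")
  required <- c("code", "name", "level", "aliases", "groups")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_tm(sprintf("region table lacks columns: %s",
                     paste(missing, collapse = ", ")),
             "taxonmatch_schema_error")
  }
  canonical <- stats::setNames(df$name, df$code)
  aliases <- list()
  groups <- list()
  add_alias <- function(aliases, nm, code) {
    k <- fold_key(nm)
    aliases[[k]] <- union(aliases[[k]], code)
    aliases
  }
  for (i in seq_len(nrow(df))) {
    code <- df$code[i]
    aliases <- add_alias(aliases, df$name[i], code)
    for (al in split_pipe(df$aliases[i])) aliases <- add_alias(aliases, al, code)
    for (g in split_pipe(df$groups[i])) {
      k <- fold_key(g)
      groups[[k]] <- union(groups[[k]], code)
    }
  }
  # codes are resolvable spellings of themselves
  for (code in df$code) aliases <- add_alias(aliases, code, code)
  bad <- setdiff(unique(unlist(c(aliases, groups))), names(canonical))
  if (length(bad)) {
    abort_tm(sprintf("alias/group references unknown codes: %s",
                     paste(bad, collapse = ", ")),
             "taxonmatch_integrity_error")
  }
  structure(
    list(level = suppressWarnings(as.integer(df$level[1])) %||% NA_integer_,
         canonical = canonical, aliases = aliases, groups = groups),
    class = "region_index"
  )
}

split_pipe <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character())
  trimws(strsplit(x, "|", fixed = TRUE)[[1]])
}

#' @export
print.region_index <- function(x, ...) {
  cat("<region_index> ", length(x$canonical), " regions",
      if (!is.na(x$level)) sprintf(" (level %d)", x$level),
      ", ", length(x$aliases), " aliases, ", length(x$groups),
      " groups\n", sep = "")
  invisible(x)
}

#' Resolve one region name to canonical codes
#'
#' Exact (normalized) hits on a canonical name, code or alias return the
#' corresponding code set; a group name expands to its member codes. An
#' unknown name resolves to the empty set with `resolved = FALSE` — it
#' is a value, not an error.
#'
#' @param name A free-text region name.
#' @param idx A [load_region_index()] result.
#' @return `list(codes = <character>, resolved = <logical>)`.
#' @export
resolve_region <- function(name, idx) {
  stopifnot(inherits(idx, "region_index"))
  k <- fold_key(name)
  codes <- idx$aliases[[k]]
  if (is.null(codes)) codes <- idx$groups[[k]]
  if (is.null(codes)) {
    return(list(codes = character(), resolved = FALSE))
  }
  list(codes = sort(codes), resolved = TRUE)
}

#' Standardize a distribution's region list
#'
#' Resolves every name in a free-text region list and unions the code
#' sets; names that resolve nowhere are reported in input order, each
#' once. Standardizing an already-canonical code list is the identity,
#' and adding names to the input can only grow the output set.
#'
#' @param names Character vector of region names.
#' @param idx A [load_region_index()] result.
#' @return `list(codes = <sorted character>, unresolved = <character>)`.
#' @export
standardize_distribution <- function(names, idx) {
  stopifnot(inherits(idx, "region_index"))
  codes <- character()
  unresolved <- character()
  for (nm in names) {
    r <- resolve_region(nm, idx)
    if (r$resolved) {
      codes <- union(codes, r$codes)
    } else if (!fold_key(nm) %in% vapply(unresolved, fold_key, character(1))) {
      unresolved <- c(unresolved, nm)
    }
  }
  list(codes = sort(codes), unresolved = unresolved)
}
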