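#' Read species records from a CSV file
#'
#' Biodiversity CSVs come in many shapes: the name and author citation
#' may share one field or sit in two, and any other columns carry trait
#' data. `read_records_csv()` is tolerant by construction: every input
#' row yields exactly one record — either a parsed name with its data
#' mapping, or an explicit skip record for a row whose name cannot be
#' parsed (never a silent drop), so row counts are conserved.
#'
#' @param path CSV file (comma-delimited by default, double-quote
#'   quoting, UTF-8 with BOM tolerance, header row required).
#' @param name_field Column holding the name; when `authority_field` is
#'   empty the author citation is assumed embedded in this field.
#' @param authority_field Optional column holding the author citation.
#' @param style Passed to [parse_name()].
#' @param data_fields Either `"keep_all"` (default: every other column
#'   becomes part of the record's data mapping) or a character vector of
#'   columns to keep.
#' @param delim Field delimiter; `","` by default, `"\t"` for TSV.
#' @return A list of records: `list(name = <taxon_name>, data = <named
#'   list>, row = <row number>)`, or for unparseable rows
#'   `list(name = NULL, raw = <string>, reason = <message>, row = <n>)`.
#' @export
read_records_csv <- function(path, name_field, authority_field = NULL,
                             style = c("botanical", "zoological"),
                             data_fields = "keep_all", delim = ",") {
  style <- match.arg(style)
  if (!file.exists(path)) {
    abort_tm(sprintf("no such file: %s", path), "taxonmatch_io_error")
  }
  df <- utils::read.table(
    path, header = TRUE, sep = delim, quote = "\"",
    stringsAsFactors = FALSE, check.names = FALSE, fileEncoding = "UTF-8-BOM",
    colClasses = "character", comment.char = ""
  )
  if (!name_field %in% names(df)) {
    abort_tm(sprintf("missing name column '%s' (file has: %s)", name_field,
                     paste(names(df), collapse = ", ")),
             "taxonmatch_schema_error")
  }
  if (!is.null(authority_field) && nzchar(authority_field) &&
      !authority_field %in% names(df)) {
    abort_tm(sprintf("missing authority column '%s'", authority_field),
             "taxonmatch_schema_error")
  }
  keep <- setdiff(names(df), c(name_field, authority_field))
  if (!identical(data_fields, "keep_all")) keep <- intersect(keep, data_fields)

  lapply(seq_len(nrow(df)), function(i) {
    raw_name <- df[[name_field]][i]
    res <- tryCatch({
      n <- parse_name(raw_name, style)
      if (!is.null(authority_field) && nzchar(authority_field %||% "")) {
        auth_raw <- df[[authority_field]][i]
        if (nzchar(str_norm(auth_raw)) && authority_is_empty(n$authority)) {
          n$authority <- parse_authority(auth_raw)
        }
      }
      n
    }, taxonmatch_parse_error = function(e) e)
    if (inherits(res, "taxon_name")) {
      list(name = res, data = as.list(df[i, keep, drop = FALSE]), row = i)
    } else {
      list(name = NULL, raw = raw_name, reason = conditionMessage(res),
           row = i)
    }
  })
}

#' Write a match log to CSV
#'
#' One row per query in input order, with the columns `original_name`,
#' `original_authority`, `matched_accepted_name`, `matched_authority`,
#' `step`, `score`, `outcome`, `alternatives` (semicolon-joined) and
#' `notes` — the full audit trail of a matching run.
#'
#' @param results List of `match_result` objects (see [match_name()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_match_log_csv <- function(results, path) {
  df <- match_log_df(results)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}

#' Read a match log back from CSV
#'
#' @param path A file written by [write_match_log_csv()].
#' @return A data frame with the match-log columns.
#' @export
read_match_log_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = c(score = "numeric"), na.strings = "NA")
}

# ---- JSON taxon store ------------------------------------------------------
# Schema (version 1):
# {
#   "format": "taxonmatch-store", "version": 1,
#   "taxa": [
#     { "accepted_name": <name>, "synonyms": [<name>...],
#       "data": {...}, "distribution": ["code", ...] }
#   ]
# }
# where <name> is
#   { "genus", "epithet", "rank", "infraspecific_epithet", "hybrid",
#     "authority": <string as formatted> }

name_to_json <- function(n) {
  list(
    genus = n$genus, epithet = n$epithet, rank = n$rank,
    infraspecific_epithet = n$infraspecific_epithet, hybrid = n$hybrid,
    authority = format_authority(n$authority)
  )
}

name_from_json <- function(x) {
  taxon_name(
    genus = x$genus, epithet = x$epithet %||% "", rank = x$rank,
    infraspecific_epithet = x$infraspecific_epithet %||% "",
    hybrid = isTRUE(x$hybrid),
    authority = parse_authority(x$authority %||% "")
  )
}

#' Save and load taxon sets as JSON
#'
#' Unlike flat CSV, JSON can hold the nested structure of a taxon —
#' synonym lists, list-valued traits, distributions — losslessly:
#' `load_taxa_json(save_taxa_json(ts))` reproduces the set exactly. The
#' document carries a `format` tag and a `version` field; a version this
#' package does not know is refused with an explicit error rather than
#' misread.
#'
#' @param ts A [taxon_set()].
#' @param path File path.
#' @return `save_taxa_json()` returns the path invisibly;
#'   `load_taxa_json()` returns a [taxon_set()].
#' @export
save_taxa_json <- function(ts, path) {
  stopifnot(inherits(ts, "taxon_set"))
  doc <- list(
    format = "taxonmatch-store",
    version = 1L,
    taxa = lapply(ts$taxa, function(t) {
      list(
        accepted_name = name_to_json(t$accepted_name),
        synonyms = lapply(t$synonyms, name_to_json),
        data = t$data,
        distribution = as.list(t$distribution)
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_taxa_json
#' @export
load_taxa_json <- function(path) {
  if (!file.exists(path)) {
    abort_tm(sprintf("no such file: %s", path), "taxonmatch_io_error")
  }
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      abort_tm(sprintf("malformed JSON in %s: %s", path, conditionMessage(e)),
               "taxonmatch_parse_error")
    }
  )
  if (!identical(doc$format, "taxonmatch-store")) {
    abort_tm(sprintf("%s is not a taxonmatch store", path),
             "taxonmatch_schema_error")
  }
  if (!identical(as.integer(doc$version), 1L)) {
    abort_tm(sprintf("unsupported store version %s (this build reads version 1)",
                     doc$version), "taxonmatch_version_error")
  }
  taxa <- lapply(doc$taxa, function(x) {
    taxon(
      accepted_name = name_from_json(x$accepted_name),
      synonyms = lapply(x$synonyms, name_from_json),
      data = x$data %||% list(),
      distribution = unlist(x$distribution) %||% character()
    )
  })
  taxon_set(taxa)
}

#' Structural equality of two taxon sets
#'
#' Order-insensitive comparison of two [taxon_set()] objects: same
#' accepted names, same synonyms, identical data mappings and
#' distributions.
#'
#' @param a,b [taxon_set()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
taxon_set_equal <- function(a, b) {
  if (length(a$taxa) != length(b$taxa)) return(FALSE)
  key <- function(t) accepted_identity(t$accepted_name)
  ta <- a$taxa[order(vapply(a$taxa, key, character(1)))]
  tb <- b$taxa[order(vapply(b$taxa, key, character(1)))]
  for (i in seq_along(ta)) {
    x <- ta[[i]]; y <- tb[[i]]
    if (!name_equal(x$accepted_name, y$accepted_name)) return(FALSE)
    sx <- sort(vapply(x$synonyms, format_name, character(1)))
    sy <- sort(vapply(y$synonyms, format_name, character(1)))
    if (!identical(sx, sy)) return(FALSE)
    reord <- function(d) if (length(d)) d[order(names(d))] else list()
    if (!identical(reord(x$data), reord(y$data))) return(FALSE)
    if (!setequal(x$distribution, y$distribution)) return(FALSE)
  }
  TRUE
}
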