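#' Structured scientific names and author citations
#'
#' A `taxon_name` is the structured form of a Linnaean name: the genus, the
#' specific epithet, an optional infraspecific rank and epithet, a hybrid
#' flag, and a parsed author citation ([authority()]). `parse_name()` builds
#' one from free text; [format_name()] renders it back to a canonical string,
#' and the two are inverse to each other for every valid name.
#'
#' @param genus Capitalized genus word.
#' @param epithet Lowercase specific epithet; empty for genus-rank names.
#' @param rank One of `"species"`, `"subspecies"`, `"variety"`, `"form"`,
#'   `"genus"`.
#' @param infraspecific_epithet Lowercase infraspecific epithet; required for
#'   ranks below species, empty otherwise.
#' @param hybrid Logical; `TRUE` when the name carries a hybrid sign
#'   (multiplication sign or a free-standing "x").
#' @param authority An [authority()] object (possibly empty).
#' @param raw The original string the name was parsed from, kept for logs.
#' @return An object of class `taxon_name`.
#' @seealso [parse_name()], [format_name()], [parse_authority()]
#' @export
taxon_name <- function(genus, epithet = "", rank = "species",
                       infraspecific_epithet = "", hybrid = FALSE,
                       authority = new_authority(), raw = "") {
  rank <- match.arg(rank, name_ranks())
  n <- structure(
    list(
      genus = as.character(genus),
      epithet = as.character(epithet),
      rank = rank,
      infraspecific_epithet = as.character(infraspecific_epithet),
      hybrid = isTRUE(hybrid),
      authority = authority,
      raw = as.character(raw)
    ),
    class = "taxon_name"
  )
  validate_taxon_name(n)
}

name_ranks <- function() c("species", "subspecies", "variety", "form", "genus")

rank_markers <- function() {
  c(subspecies = "subsp.", variety = "var.", form = "f.")
}

validate_taxon_name <- function(n) {
  if (!grepl("^[A-Z\u00c0-\u00de][a-zA-Z\u00df-\u00ff-]*$", n$genus)) {
    abort_tm(sprintf("invalid genus %s", dQuote(n$genus)), "taxonmatch_parse_error",
             raw = n$raw)
  }
  ok_epithet <- function(e) e == "" || grepl("^[a-z\u00df-\u00ff][a-z\u00df-\u00ff-]*$", e)
  if (!ok_epithet(n$epithet) || !ok_epithet(n$infraspecific_epithet)) {
    abort_tm("epithets must be lowercase words (letters and hyphens)",
             "taxonmatch_parse_error", raw = n$raw)
  }
  if (n$rank %in% c("subspecies", "variety", "form") &&
      !nzchar(n$infraspecific_epithet)) {
    abort_tm("infraspecific rank requires an infraspecific epithet",
             "taxonmatch_parse_error", raw = n$raw)
  }
  if (n$rank %in% c("species", "genus") && nzchar(n$infraspecific_epithet)) {
    abort_tm("rank 'species'/'genus' must not carry an infraspecific epithet",
             "taxonmatch_parse_error", raw = n$raw)
  }
  if (n$rank == "genus" && nzchar(n$epithet)) {
    abort_tm("genus-rank names have no epithet", "taxonmatch_parse_error",
             raw = n$raw)
  }
  if (!inherits(n$authority, "tm_authority")) {
    abort_tm("authority must be an authority object", "taxonmatch_parse_error")
  }
  n
}

#' Parse a scientific name
#'
#' Splits a free-text name such as `"Zea mays subsp. mays"` or
#' `"Glycyrrhiza glandulifera Ledeb"` into a structured [taxon_name()].
#' Recognized infraspecific markers are `subsp.`, `ssp.`, `var.` and `f.`
#' (with or without the period); under `style = "zoological"` a bare
#' lowercase third word is read as a subspecific epithet. Anything after the
#' name parts is treated as the author citation and handed to
#' [parse_authority()]. A leading multiplication sign or free-standing
#' "x"/"\u00d7" before the genus or the epithet sets the hybrid flag and is
#' stripped from the stored words.
#'
#' @param raw The name string; must contain at least a recognizable genus
#'   word.
#' @param style `"botanical"` (default) or `"zoological"`; the two codes
#'   format trinomials differently.
#' @return A [taxon_name()]. On input with no recognizable genus a
#'   condition of class `taxonmatch_parse_error` is signalled, carrying the
#'   offending string in its `raw` field.
#' @examples
#' parse_name("Zea mays subsp. mays")
#' parse_name("Glycyrrhiza glandulifera Ledeb")
#' parse_name("Panthera leo persica", style = "zoological")
#' @export
parse_name <- function(raw, style = c("botanical", "zoological")) {
  style <- match.arg(style)
  if (!is_scalar_chr(raw) || !nzchar(str_norm(raw))) {
    abort_tm("empty name string", "taxonmatch_parse_error", raw = raw)
  }
  s <- str_norm(raw)
  toks <- strsplit(s, " ", fixed = TRUE)[[1]]

  hybrid <- FALSE
  is_hybrid_tok <- function(t) t %in% c("x", "X", "\u00d7") ||
    identical(t, "\u00d7")
  # leading hybrid sign (possibly glued to the genus, e.g. "×Festuca")
  if (length(toks) && is_hybrid_tok(toks[1])) {
    hybrid <- TRUE
    toks <- toks[-1]
  } else if (length(toks) && startsWith(toks[1], "\u00d7")) {
    hybrid <- TRUE
    toks[1] <- sub("^\u00d7", "", toks[1])
  }
  if (!length(toks) || !grepl("^[A-Za-z][A-Za-z-]*$", toks[1]) ||
      !grepl("^[A-Za-z]", toks[1])) {
    abort_tm(sprintf("no recognizable genus in %s", dQuote(s)),
             "taxonmatch_parse_error", raw = raw)
  }
  genus <- title_case_word(toks[1])
  if (!grepl("^[A-Z]", genus)) {
    abort_tm(sprintf("no recognizable genus in %s", dQuote(s)),
             "taxonmatch_parse_error", raw = raw)
  }
  toks <- toks[-1]

  # hybrid sign between genus and epithet
  if (length(toks) && is_hybrid_tok(toks[1])) {
    hybrid <- TRUE
    toks <- toks[-1]
  } else if (length(toks) && startsWith(toks[1], "\u00d7")) {
    hybrid <- TRUE
    toks[1] <- sub("^\u00d7", "", toks[1])
  }

  epithet <- ""
  rank <- "genus"
  infra <- ""
  if (length(toks) && is_epithet_token(toks[1])) {
    epithet <- casefold_lower(toks[1])
    rank <- "species"
    toks <- toks[-1]

    marker <- if (length(toks)) match_rank_marker(toks[1]) else NA_character_
    if (!is.na(marker)) {
      if (length(toks) < 2L || !is_epithet_token(toks[2])) {
        abort_tm(sprintf("rank marker %s not followed by an epithet in %s",
                         dQuote(toks[1]), dQuote(s)),
                 "taxonmatch_parse_error", raw = raw)
      }
      rank <- marker
      infra <- casefold_lower(toks[2])
      toks <- toks[-(1:2)]
    } else if (style == "zoological" && length(toks) &&
               is_epithet_token(toks[1])) {
      # zoological trinomials carry no rank marker
      rank <- "subspecies"
      infra <- casefold_lower(toks[1])
      toks <- toks[-1]
    }
  }

  auth_raw <- paste(toks, collapse = " ")
  taxon_name(
    genus = genus, epithet = epithet, rank = rank,
    infraspecific_epithet = infra, hybrid = hybrid,
    authority = parse_authority(auth_raw), raw = raw
  )
}

# An epithet token is a lowercase word; an all-caps word (shouting data
# entry) is folded rather than read as an author surname.
is_epithet_token <- function(t) {
  grepl("^[a-z\u00df-\u00ff][a-z\u00df-\u00ff-]*$", t) ||
    grepl("^[A-Z\u00c0-\u00de-]{2,}$", t)
}

match_rank_marker <- function(t) {
  # "f." must stay case-sensitive: an uppercase "F." is an author initial
  if (t %in% c("f.", "f")) return("form")
  t <- casefold_lower(t)
  switch(t,
    "subsp." = , "subsp" = , "ssp." = , "ssp" = "subspecies",
    "var." = , "var" = "variety",
    "forma" = "form",
    NA_character_
  )
}

title_case_word <- function(w) {
  paste0(toupper(substr(w, 1, 1)), casefold_lower(substr(w, 2, nchar(w))))
}

#' Format a scientific name
#'
#' Renders a [taxon_name()] as its canonical string,
#' `"Genus epithet [marker infra] [authority]"`. Formatting then re-parsing
#' yields an equal name (the `raw` field aside).
#'
#' @param n A [taxon_name()].
#' @param with_authority Append the formatted author citation when one is
#'   present.
#' @return A single string.
#' @examples
#' format_name(parse_name("Zea   mays subsp.  mays"))
#' @export
format_name <- function(n, with_authority = TRUE) {
  stopifnot(inherits(n, "taxon_name"))
  parts <- n$genus
  if (nzchar(n$epithet)) {
    ep <- if (n$hybrid) paste("\u00d7", n$epithet) else n$epithet
    parts <- c(parts, ep)
  } else if (n$hybrid) {
    parts <- c("\u00d7", parts)
  }
  if (n$rank %in% names(rank_markers())) {
    parts <- c(parts, rank_markers()[[n$rank]], n$infraspecific_epithet)
  }
  out <- paste(parts, collapse = " ")
  if (with_authority && !authority_is_empty(n$authority)) {
    out <- paste(out, format_authority(n$authority))
  }
  out
}

#' @export
print.taxon_name <- function(x, ...) {
  cat("<taxon_name> ", format_name(x), "  [rank: ", x$rank, "]\n", sep = "")
  invisible(x)
}

#' Compare two names for structural equality
#'
#' Field-by-field equality of two [taxon_name()] objects, ignoring the `raw`
#' strings on both the names and their authorities.
#'
#' @param a,b [taxon_name()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
name_equal <- function(a, b) {
  identical(a$genus, b$genus) && identical(a$epithet, b$epithet) &&
    identical(a$rank, b$rank) &&
    identical(a$infraspecific_epithet, b$infraspecific_epithet) &&
    identical(a$hybrid, b$hybrid) &&
    authority_equal(a$authority, b$authority)
}

# Case-folded "genus epithet [marker infra]" without authority or hybrid
# sign; homonyms deliberately collide on this key.
binomial_key <- function(n) {
  stopifnot(inherits(n, "taxon_name"))
  parts <- c(n$genus, if (nzchar(n$epithet)) n$epithet)
  if (n$rank %in% names(rank_markers())) {
    parts <- c(parts, rank_markers()[[n$rank]], n$infraspecific_epithet)
  }
  casefold_lower(paste(parts, collapse = " "))
}
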