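#' Synthetic synonymies and corrupted query lists
#'
#' The matcher's behaviour is evaluated on generated data with known
#' ground truth. [generate_reference()] builds a reference synonymy of
#' pronounceable pseudo-Latin binomials (syllable-templated, so q-gram
#' statistics and bucket occupancy resemble real names) with author
#' citations and optional injected homonyms. [corrupt_queries()] then
#' derives one query per taxon, damaged by the failure modes real name
#' lists exhibit: transcription typos, Latin gender-ending swaps
#' (album/alba/albus), use of a synonym instead of the accepted name, and
#' dropped author citations. [score_matching()] closes the loop with
#' precision, recall and a histogram of the cascade steps used.
#'
#' @param typo_rate,gender_swap_rate,synonym_use_rate,authority_drop_rate
#'   Per-query probabilities in \[0, 1\] of each corruption.
#' @param homonym_count Number of taxon pairs given an identical synonym
#'   binomial (under different authorities) in the generated reference.
#' @param seed Integer seed fixing all randomness.
#' @return `corruption_config()` returns an object of class
#'   `corruption_config`.
#' @export
corruption_config <- function(typo_rate = 0, gender_swap_rate = 0,
                              synonym_use_rate = 0, authority_drop_rate = 0,
                              homonym_count = 0L, seed = 1L) {
  rates <- c(typo_rate, gender_swap_rate, synonym_use_rate,
             authority_drop_rate)
  stopifnot(all(rates >= 0 & rates <= 1), homonym_count >= 0)
  structure(
    list(typo_rate = typo_rate, gender_swap_rate = gender_swap_rate,
         synonym_use_rate = synonym_use_rate,
         authority_drop_rate = authority_drop_rate,
         homonym_count = as.integer(homonym_count), seed = as.integer(seed)),
    class = "corruption_config"
  )
}

syllables <- function() {
  cons <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v",
            "ch", "th", "br", "tr", "st")
  vow <- c("a", "e", "i", "o", "u")
  as.vector(outer(cons, vow, paste0))
}

gender_endings <- function() c("a", "um", "us")

random_word <- function(n_syll) {
  paste(sample(syllables(), n_syll, replace = TRUE), collapse = "")
}

random_epithet <- function() {
  paste0(random_word(sample(2:3, 1)), sample(gender_endings(), 1))
}

random_genus <- function() {
  title_case_word(paste0(random_word(sample(2:3, 1)),
                         sample(c("a", "um", "us", "ia", "ius"), 1)))
}

surname_pool <- function() {
  c("Aldrovandus", "Bellarminus", "Candidus", "Delacroix", "Eversmann",
    "Fabricius", "Gerardus", "Hartmann", "Ingenhousz", "Jacquemont",
    "Koenigius", "Lindgren", "Montanus", "Norrelius", "Oldenburg",
    "Petermann", "Quensel", "Rothmann", "Severinus", "Tournefort")
}

random_authority <- function() {
  sn <- sample(surname_pool(), 1)
  if (stats::runif(1) < 0.5) sn <- paste0(substr(sn, 1, sample(4:6, 1)), ".")
  initials <- if (stats::runif(1) < 0.4) {
    paste0(sample(LETTERS, 1), ".")
  } else {
    character()
  }
  year <- if (stats::runif(1) < 0.3) sample(1753:1990, 1) else NA_integer_
  authority(primary_authors = list(author_token(sn, initials)), year = year)
}

random_species_name <- function(genus = random_genus(),
                                with_authority = TRUE) {
  a <- if (with_authority) random_authority() else new_authority()
  taxon_name(genus = genus, epithet = random_epithet(), authority = a)
}

# A random structured name across ranks/hybrids; used by round-trip
# property tests.
random_name_any <- function() {
  rank <- sample(c("species", "subspecies", "variety", "form", "genus"), 1,
                 prob = c(0.55, 0.15, 0.1, 0.05, 0.15))
  genus <- random_genus()
  if (rank == "genus") {
    return(taxon_name(genus = genus, rank = "genus",
                      authority = if (stats::runif(1) < 0.5)
                        random_authority() else new_authority()))
  }
  taxon_name(
    genus = genus, epithet = random_epithet(), rank = rank,
    infraspecific_epithet = if (rank == "species") "" else random_epithet(),
    hybrid = stats::runif(1) < 0.1,
    authority = if (stats::runif(1) < 0.6) random_authority()
                else new_authority()
  )
}

#' Generate a synthetic reference synonymy
#'
#' Builds `n_taxa` taxa with distinct pseudo-Latin accepted binomials,
#' `synonyms_per_taxon` synonyms each, and `homonym_count` injected
#' homonym pairs: pairs of taxa sharing one synonym *binomial* under
#' different authorities, the classic trap the authority comparator is
#' there to resolve. Deterministic for a given seed.
#'
#' @param n_taxa Number of taxa (>= 1).
#' @param synonyms_per_taxon Synonyms attached to each taxon.
#' @param seed Integer seed.
#' @param homonym_count Number of homonymous synonym pairs to inject
#'   (requires `n_taxa >= 2 * homonym_count`).
#' @return A [taxon_set()].
#' @export
generate_reference <- function(n_taxa, synonyms_per_taxon = 2L, seed = 1L,
                               homonym_count = 0L) {
  stopifnot(n_taxa >= 1, synonyms_per_taxon >= 0,
            n_taxa >= 2L * homonym_count)
  withr::with_seed(as.integer(seed), {
    keys <- character()
    fresh_name <- function() {
      repeat {
        n <- random_species_name()
        k <- binomial_key(n)
        if (!k %in% keys) {
          keys <<- c(keys, k)
          return(n)
        }
      }
    }
    taxa <- lapply(seq_len(n_taxa), function(i) {
      acc <- fresh_name()
      syns <- lapply(seq_len(synonyms_per_taxon), function(j) fresh_name())
      taxon(acc, synonyms = syns,
            data = list(taxon_id = sprintf("T%04d", i)))
    })
    # homonym injection: taxa 2k-1 and 2k share a synonym binomial under
    # two different authorities
    if (homonym_count > 0L) {
      for (k in seq_len(homonym_count)) {
        i <- 2L * k - 1L
        j <- 2L * k
        shared <- random_species_name(with_authority = FALSE)
        a1 <- random_authority()
        repeat {
          a2 <- random_authority()
          if (compare_authorities(a1, a2) != "agree") break
        }
        n1 <- shared; n1$authority <- a1
        n2 <- shared; n2$authority <- a2
        taxa[[i]]$synonyms <- c(taxa[[i]]$synonyms, list(n1))
        taxa[[j]]$synonyms <- c(taxa[[j]]$synonyms, list(n2))
      }
    }
    taxon_set(taxa)
  })
}

apply_typo <- function(word) {
  letters_pool <- letters
  chars <- strsplit(word, "")[[1]]
  n <- length(chars)
  op <- sample(c("sub", "del", "ins"), 1)
  if (n <= 1 && op == "del") op <- "sub"
  if (op == "sub") {
    i <- sample(n, 1)
    repeat {
      r <- sample(letters_pool, 1)
      if (r != chars[i]) break
    }
    chars[i] <- r
  } else if (op == "del") {
    chars <- chars[-sample(n, 1)]
  } else {
    i <- sample(n + 1L, 1)
    chars <- append(chars, sample(letters_pool, 1), after = i - 1L)
  }
  paste(chars, collapse = "")
}

#' Corrupt the queries derived from a reference
#'
#' Emits one query per taxon, starting from the accepted name (or, with
#' probability `synonym_use_rate`, one of its synonyms) and applying each
#' corruption independently at its configured rate. The typo model makes
#' a single random substitution, deletion or insertion in the *epithet*,
#' never in the first three characters of the name — the blocking
#' prefix — so a typo'd query remains reachable by the fuzzy step by
#' construction. Ground truth (the accepted name) is carried alongside
#' every query.
#'
#' @param ts A [taxon_set()] from [generate_reference()].
#' @param cfg A [corruption_config()].
#' @return A list of `list(query = <taxon_name>, truth = <taxon_name>)`,
#'   one per taxon, in taxon order.
#' @export
corrupt_queries <- function(ts, cfg = corruption_config()) {
  stopifnot(inherits(ts, "taxon_set"), length(ts$taxa) > 0,
            inherits(cfg, "corruption_config"))
  withr::with_seed(cfg$seed + 1L, {
    lapply(ts$taxa, function(t) {
      q <- t$accepted_name
      if (length(t$synonyms) && stats::runif(1) < cfg$synonym_use_rate) {
        q <- t$synonyms[[sample(length(t$synonyms), 1)]]
      }
      if (stats::runif(1) < cfg$gender_swap_rate) {
        for (e in gender_endings()) {
          if (endsWith(q$epithet, e)) {
            stem <- substr(q$epithet, 1, nchar(q$epithet) - nchar(e))
            q$epithet <- paste0(stem, sample(setdiff(gender_endings(), e), 1))
            break
          }
        }
      }
      if (stats::runif(1) < cfg$typo_rate) {
        q$epithet <- apply_typo(q$epithet)
        if (!nzchar(q$epithet)) q$epithet <- "a"
      }
      if (stats::runif(1) < cfg$authority_drop_rate) {
        q$authority <- new_authority()
      }
      q$raw <- format_name(q)
      list(query = q, truth = t$accepted_name)
    })
  })
}

#' Score a matching run against ground truth
#'
#' A match is correct when its accepted name equals the truth (binomial
#' and authority). Precision is correct matches over all matches made;
#' recall is correct matches over all queries; the step histogram counts
#' which cascade step produced each match.
#'
#' @param results List of `match_result` objects, aligned with `truth`
#'   by position.
#' @param truth List of [taxon_name()] objects (or of
#'   `list(query, truth)` pairs as returned by [corrupt_queries()]).
#' @return `list(precision, recall, step_histogram, n_queries, n_matched,
#'   n_correct)`; precision is `NA` when no matches were made.
#' @export
score_matching <- function(results, truth) {
  if (length(truth) && is.list(truth[[1]]) && !inherits(truth[[1]], "taxon_name")) {
    truth <- lapply(truth, `[[`, "truth")
  }
  if (length(results) != length(truth)) {
    abort_tm(sprintf("results (%d) and truth (%d) are not aligned",
                     length(results), length(truth)),
             "taxonmatch_alignment_error")
  }
  matched <- vapply(results, function(r) r$outcome == "matched", logical(1))
  correct <- vapply(seq_along(results), function(i) {
    matched[i] && name_equal(results[[i]]$accepted_name, truth[[i]])
  }, logical(1))
  steps <- vapply(results[matched], function(r) r$step, character(1))
  list(
    precision = if (any(matched)) sum(correct) / sum(matched) else NA_real_,
    recall = sum(correct) / length(results),
    step_histogram = if (length(steps)) table(steps) else table(character()),
    n_queries = length(results),
    n_matched = sum(matched),
    n_correct = sum(correct)
  )
}

#' Run the synthetic benchmark end to end
#'
#' Generates a reference, corrupts its queries, matches them back and
#' scores the result — the one-call version of the pipeline the `bench`
#' CLI subcommand drives.
#'
#' @param n_taxa Reference size.
#' @param synonyms_per_taxon Synonyms per taxon.
#' @param cfg A [corruption_config()].
#' @param match_cfg A [match_config()].
#' @return `list(metrics, results, queries, reference)`.
#' @export
run_benchmark <- function(n_taxa = 100L, synonyms_per_taxon = 2L,
                          cfg = corruption_config(),
                          match_cfg = match_config()) {
  ref <- generate_reference(n_taxa, synonyms_per_taxon, seed = cfg$seed,
                            homonym_count = cfg$homonym_count)
  pairs <- corrupt_queries(ref, cfg)
  queries <- lapply(pairs, function(p) list(name = p$query, data = list()))
  md <- match_dataset(queries, ref, match_cfg)
  metrics <- score_matching(md$log, pairs)
  list(metrics = metrics, results = md$log, queries = pairs, reference = ref)
}
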