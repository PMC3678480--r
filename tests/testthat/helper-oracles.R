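# Independent brute-force oracles, deliberately naive and kept separate
# from the implementation under test.

oracle_qgrams <- function(s, q = 3L, pad = "\u2227") {
  if (!nzchar(s)) return(character())
  p <- paste0(strrep(pad, q - 1L), s)
  out <- character()
  for (i in seq_len(nchar(p) - q + 1L)) {
    out <- c(out, substr(p, i, i + q - 1L))
  }
  unique(out)
}

oracle_similarity <- function(a, b, q = 3L) {
  ga <- oracle_qgrams(tolower(a), q)
  gb <- oracle_qgrams(tolower(b), q)
  if (!length(ga) || !length(gb)) return(0)
  length(intersect(ga, gb)) / length(union(ga, gb))
}

# Unblocked scan restricted to names sharing the query's first-q prefix.
oracle_prefix_scan <- function(names, query, q = 3L, threshold = 0.70) {
  key <- tolower(substr(query, 1L, q))
  hits <- data.frame(name = character(), score = numeric(),
                     stringsAsFactors = FALSE)
  for (nm in names) {
    if (tolower(substr(nm, 1L, q)) != key) next
    sc <- oracle_similarity(nm, query, q)
    if (sc >= threshold) {
      hits <- rbind(hits, data.frame(name = nm, score = sc,
                                     stringsAsFactors = FALSE))
    }
  }
  hits[order(-hits$score, hits$name, method = "radix"), , drop = FALSE]
}

# Random name strings drawn from a small genus pool so blocking buckets
# actually share prefixes.
random_name_strings <- function(n, seed) {
  withr::with_seed(seed, {
    genera <- replicate(8, taxonmatch:::random_genus())
    vapply(seq_len(n), function(i) {
      paste(sample(genera, 1), taxonmatch:::random_epithet())
    }, character(1))
  })
}

# The three worked-example taxa plus the homonym pair, used across the
# resolver tests.
paper_fixture_reference <- function() {
  taxon_set(list(
    taxon(parse_name("Glycyrrhiza glabra L."),
          synonyms = list(parse_name("Glycyrrhiza glandulifera Ledeb.")),
          data = list(habit = "herb")),
    taxon(parse_name("Glycyrrhiza uralensis Fisch."),
          synonyms = list(parse_name("Glycyrrhiza glandulifera Waldst. & Kit."))),
    taxon(parse_name("Zea mays L.")),
    taxon(parse_name("Mucuna holtonii (Kuntze) Moldenke"))
  ))
}

region_fixture_path <- function() {
  system.file("extdata", "regions_synthetic.csv", package = "taxonmatch",
              mustWork = TRUE)
}
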