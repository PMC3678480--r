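tmpfile <- function(ext) withr::local_tempfile(fileext = ext,
                                               .local_envir = parent.frame())

test_that("record CSVs read with combined or separate name/authority fields", {
  p <- tmpfile(".csv")
  writeLines(c("Name,Author,height",
               '"Glycyrrhiza glandulifera","Ledeb",0.8',
               '"Zea mays subsp. mays","",2.1'), p)
  recs <- read_records_csv(p, "Name", "Author")
  expect_length(recs, 2)
  expect_equal(recs[[1]]$name$authority$primary_authors[[1]]$surname, "Ledeb")
  expect_equal(recs[[1]]$data$height, "0.8")
  expect_equal(recs[[2]]$name$rank, "subspecies")

  # one combined column
  p2 <- tmpfile(".csv")
  writeLines(c("species", "Viscum album L."), p2)
  recs2 <- read_records_csv(p2, "species")
  expect_equal(recs2[[1]]$name$authority$primary_authors[[1]]$surname, "L.")
})

test_that("row counts are conserved: bad rows become explicit skips", {
  p <- tmpfile(".csv")
  writeLines(c("Name", "Zea mays", "123 456", "Homo sapiens"), p)
  recs <- read_records_csv(p, "Name")
  expect_length(recs, 3)
  expect_null(recs[[2]]$name)
  expect_equal(recs[[2]]$raw, "123 456")
  expect_match(recs[[2]]$reason, "genus")

  # header-only file
  p2 <- tmpfile(".csv")
  writeLines("Name", p2)
  expect_length(read_records_csv(p2, "Name"), 0)
})

test_that("a missing name column is a schema error naming the column", {
  p <- tmpfile(".csv")
  writeLines(c("species,author", "Zea mays,L."), p)
  err <- tryCatch(read_records_csv(p, "Name"),
                  taxonmatch_schema_error = identity)
  expect_s3_class(err, "taxonmatch_schema_error")
  expect_match(conditionMessage(err), "Name")
})

test_that("match logs round-trip through CSV with the documented columns", {
  ref <- paper_fixture_reference()
  results <- lapply(list("Mucuna holtoni", "Zea mays L.", "Nonexistens impossibilis"),
                    function(q) match_name(q, ref))
  p <- tmpfile(".csv")
  write_match_log_csv(results, p)
  back <- read_match_log_csv(p)
  expect_equal(names(back),
               c("original_name", "original_authority",
                 "matched_accepted_name", "matched_authority", "step",
                 "score", "outcome", "alternatives", "notes"))
  expect_equal(back$step[1], "fuzzy")
  expect_equal(back$score[1], 14 / 15, tolerance = 1e-9)
  expect_equal(back$outcome[3], "unmatched")
  expect_identical(back[c("original_name", "step", "outcome")],
                   match_log_df(results)[c("original_name", "step", "outcome")])

  # zero results: header-only log
  p0 <- tmpfile(".csv")
  write_match_log_csv(list(), p0)
  expect_equal(nrow(read_match_log_csv(p0)), 0)
})

test_that("the JSON store round-trips taxon sets losslessly", {
  ref <- paper_fixture_reference()
  p <- tmpfile(".json")
  save_taxa_json(ref, p)
  expect_true(taxon_set_equal(load_taxa_json(p), ref))

  # empty set
  p0 <- tmpfile(".json")
  save_taxa_json(taxon_set(), p0)
  expect_length(load_taxa_json(p0), 0)

  # nested, list-valued data survive
  t <- taxon(parse_name("Zea mays L."),
             data = list(uses = list("grain", "fodder"),
                         yield = list(irrigated = 9.5, rainfed = 4.2)),
             distribution = c("NOR", "MER"))
  p1 <- tmpfile(".json")
  save_taxa_json(taxon_set(t), p1)
  back <- load_taxa_json(p1)
  expect_equal(back$taxa[[1]]$data$uses, list("grain", "fodder"))
  expect_equal(back$taxa[[1]]$data$yield$irrigated, 9.5)
  expect_true(setequal(back$taxa[[1]]$distribution, c("NOR", "MER")))
})

test_that("the store refuses foreign documents and future versions", {
  p <- tmpfile(".json")
  writeLines('{"format": "something-else", "version": 1, "taxa": []}', p)
  expect_error(load_taxa_json(p), class = "taxonmatch_schema_error")

  p2 <- tmpfile(".json")
  writeLines('{"format": "taxonmatch-store", "version": 99, "taxa": []}', p2)
  expect_error(load_taxa_json(p2), class = "taxonmatch_version_error")

  p3 <- tmpfile(".json")
  writeLines('{"format": "taxonmatch-store", ', p3)
  expect_error(load_taxa_json(p3), class = "taxonmatch_parse_error")
})

test_that("generated stores round-trip (property)", {
  for (seed in c(2, 9)) {
    ref <- generate_reference(12, synonyms_per_taxon = 2, seed = seed,
                              homonym_count = 2)
    p <- tmpfile(".json")
    save_taxa_json(ref, p)
    expect_true(taxon_set_equal(load_taxa_json(p), ref))
  }
})
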