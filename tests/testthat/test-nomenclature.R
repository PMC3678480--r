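test_that("binomials, trinomials and authorities parse into structured names", {
  n <- parse_name("Zea mays subsp. mays")
  expect_equal(n$genus, "Zea")
  expect_equal(n$epithet, "mays")
  expect_equal(n$rank, "subspecies")
  expect_equal(n$infraspecific_epithet, "mays")
  expect_true(authority_is_empty(n$authority))

  n <- parse_name("Homo sapiens")
  expect_equal(n$rank, "species")
  expect_equal(n$infraspecific_epithet, "")
  expect_true(authority_is_empty(n$authority))

  n <- parse_name("Glycyrrhiza glandulifera Ledeb")
  expect_equal(n$epithet, "glandulifera")
  expect_equal(n$authority$primary_authors[[1]]$surname, "Ledeb")
  expect_false(n$authority$primary_authors[[1]]$is_abbreviation)

  n <- parse_name("Viscum album L.")
  expect_equal(n$authority$primary_authors[[1]]$surname, "L.")
  expect_true(n$authority$primary_authors[[1]]$is_abbreviation)
})

test_that("rank-marker synonyms and zoological trinomials are recognized", {
  expect_equal(parse_name("Zea mays ssp. mays")$rank, "subspecies")
  expect_equal(parse_name("Mentha aquatica var. crispa")$rank, "variety")
  expect_equal(parse_name("Betula pendula f. dalecarlica")$rank, "form")

  z <- parse_name("Panthera leo persica", style = "zoological")
  expect_equal(z$rank, "subspecies")
  expect_equal(z$infraspecific_epithet, "persica")
  # botanical style reads the bare third word as an authority fragment
  b <- parse_name("Panthera leo persica", style = "botanical")
  expect_equal(b$rank, "species")
})

test_that("hybrid signs and case anomalies are normalized, raw preserved", {
  h <- parse_name("Festuca × brinkmannii")
  expect_true(h$hybrid)
  expect_equal(h$epithet, "brinkmannii")
  expect_equal(h$raw, "Festuca × brinkmannii")
  expect_true(parse_name("x Festulolium")$hybrid)
  expect_equal(parse_name("ZEA MAYS")$epithet, "mays")
  expect_equal(parse_name("zea mays")$genus, "Zea")
})

test_that("unparseable input signals a parse error carrying the raw string", {
  expect_error(parse_name("   "), class = "taxonmatch_parse_error")
  err <- tryCatch(parse_name("123 456"), taxonmatch_parse_error = identity)
  expect_s3_class(err, "taxonmatch_parse_error")
  expect_equal(err$raw, "123 456")
})

test_that("authority grammar separates basionym, ex, primary, year and non groups", {
  a <- parse_authority("non Vahl")
  expect_length(a$excluded_authors, 1)
  expect_equal(a$excluded_authors[[1]]$surname, "Vahl")
  expect_length(a$primary_authors, 0)

  a <- parse_authority("")
  expect_true(authority_is_empty(a))

  a <- parse_authority("(L.) Merr.")
  expect_equal(a$basionym_authors[[1]]$surname, "L.")
  expect_equal(a$primary_authors[[1]]$surname, "Merr.")

  a <- parse_authority("Hook. & Arn. 1832")
  expect_equal(vapply(a$primary_authors, `[[`, "", "surname"),
               c("Hook.", "Arn."))
  expect_equal(a$year, 1832L)

  a <- parse_authority("Benth. ex Hook.")
  expect_equal(a$ex_authors[[1]]$surname, "Benth.")
  expect_equal(a$primary_authors[[1]]$surname, "Hook.")

  a <- parse_authority("A. Gray")
  expect_equal(a$primary_authors[[1]]$initials, "A.")
  expect_equal(a$primary_authors[[1]]$surname, "Gray")
})

test_that("authority parsing is total and 'non' is always detected", {
  junk <- c("L..", "???", "ined.", "sensu auct. 17", "(=) [sic]", "Vahl,,&",
            "1749 1832 2101", "de la Torre y Gomez")
  for (s in junk) expect_s3_class(parse_authority(s), "tm_authority")
  withr::with_seed(11, {
    for (i in 1:50) {
      s <- paste(sample(c(LETTERS, letters, ".", "&", "(", ")", "1", "8"),
                        sample(1:12, 1), replace = TRUE), collapse = "")
      expect_s3_class(parse_authority(s), "tm_authority")
      expect_gt(length(parse_authority(paste("non", s))$excluded_authors) +
                  (!nzchar(trimws(s))), 0)
    }
  })
})

test_that("years outside the Linnaean window are not swallowed", {
  expect_true(is.na(parse_authority("Smith 174")$year))
  expect_true(is.na(parse_authority("Smith 2101")$year))
  expect_equal(parse_authority("Smith 1753")$year, 1753L)
  expect_equal(parse_authority("Smith, 1900")$year, 1900L)
})

test_that("format_name is the inverse of parse_name on canonical strings", {
  expect_equal(format_name(parse_name("Zea   mays  subsp.   mays")),
               "Zea mays subsp. mays")
  expect_equal(format_name(parse_name("Homo sapiens")), "Homo sapiens")
  expect_equal(format_name(parse_name("Glycyrrhiza glandulifera Ledeb"),
                           with_authority = FALSE),
               "Glycyrrhiza glandulifera")
})

test_that("parse/format round-trips over generated names", {
  withr::with_seed(1234, {
    for (i in seq_len(300)) {
      n <- taxonmatch:::random_name_any()
      m <- parse_name(format_name(n))
      expect_true(name_equal(n, m),
                  info = paste("failed on", format_name(n)))
    }
  })
})
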