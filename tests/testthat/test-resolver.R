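test_that("authority comparison follows the bespoke component rules", {
  cmp <- function(a, b) compare_authorities(parse_authority(a),
                                            parse_authority(b))
  expect_equal(cmp("Vahl", "non Vahl"), "incompatible")
  expect_equal(cmp("non Vahl", "Vahl"), "incompatible")
  expect_equal(cmp("Ledeb", "Ledeb."), "agree")
  expect_equal(cmp("Ledeb.", "Ledebour"), "agree")
  expect_equal(cmp("", "L."), "neutral")
  expect_equal(cmp("L.", ""), "neutral")
  expect_equal(cmp("Hook.", "Arn."), "disagree")
  expect_equal(cmp("Hook. 1832", "Hook. 1840"), "disagree")
  expect_equal(cmp("Hook. 1832", "Hook."), "agree")
  expect_equal(cmp("A. Gray", "S. Gray"), "disagree")
  expect_equal(cmp("A. Gray", "Gray"), "agree")
  expect_equal(cmp("(L.) Merr.", "(Vahl) Merr."), "disagree")
})

test_that("homonyms are resolved by authority at the name_only step", {
  ref <- paper_fixture_reference()
  r <- match_name("Glycyrrhiza glandulifera Ledeb", ref)
  expect_equal(r$outcome, "matched")
  expect_equal(r$step, "name_only")
  expect_equal(format_name(r$accepted_name, FALSE), "Glycyrrhiza glabra")
})

test_that("nominal subspecies promote to the parent species", {
  ref <- paper_fixture_reference()
  r <- match_name("Zea mays subsp. mays", ref)
  expect_equal(r$step, "infraspecific_promotion")
  expect_equal(format_name(r$accepted_name, FALSE), "Zea mays")

  # a non-nominal subspecies does not promote under nominal_only
  r2 <- match_name("Zea mays subsp. parviglumis", ref,
                   match_config(infraspecific_promotion = "nominal_only"))
  expect_false(identical(r2$step, "infraspecific_promotion"))
  r3 <- match_name("Zea mays subsp. parviglumis", ref,
                   match_config(infraspecific_promotion = "all"))
  expect_equal(r3$step, "infraspecific_promotion")
  r4 <- match_name("Zea mays subsp. mays", ref,
                   match_config(infraspecific_promotion = "off"))
  expect_false(identical(r4$step, "infraspecific_promotion"))
})

test_that("misspellings match fuzzily with the worked-example score", {
  ref <- paper_fixture_reference()
  r <- match_name("Mucuna holtoni", ref)
  expect_equal(r$outcome, "matched")
  expect_equal(r$step, "fuzzy")
  expect_equal(r$score, 14 / 15, tolerance = 1e-12)

  v <- match_name("Viscum alba",
                  taxon_set(taxon(parse_name("Viscum album L."))))
  expect_equal(v$step, "fuzzy")
  expect_equal(v$score, oracle_similarity("viscum alba", "viscum album"))
})

test_that("an exact binomial+authority match always wins (cascade order)", {
  ref <- paper_fixture_reference()
  for (cfg in list(match_config(),
                   match_config(allow_authority_mismatch = FALSE),
                   match_config(infraspecific_promotion = "off"))) {
    r <- match_name("Zea mays L.", ref, cfg)
    expect_equal(r$step, "exact_with_authority")
  }
})

test_that("an incompatible authority vetoes the candidate at every step", {
  vref <- taxon_set(taxon(parse_name("Ficus indica non Vahl")))
  r <- match_name("Ficus indica Vahl", vref,
                  match_config(allow_authority_mismatch = TRUE))
  expect_equal(r$outcome, "unmatched")
  expect_match(paste(r$notes, collapse = " "), "incompatible")
  # and through the fuzzy step too
  r2 <- match_name("Ficus indicaa Vahl", vref)
  expect_equal(r2$outcome, "unmatched")
})

test_that("authority disagreement is configurable", {
  ref <- taxon_set(taxon(parse_name("Aus bus Hook.")))
  ok <- match_name("Aus bus Arn.", ref,
                   match_config(allow_authority_mismatch = TRUE))
  expect_equal(ok$outcome, "matched")
  expect_match(paste(ok$notes, collapse = " "), "disagree")
  no <- match_name("Aus bus Arn.", ref,
                   match_config(allow_authority_mismatch = FALSE))
  expect_equal(no$outcome, "unmatched")
})

test_that("homonym policies: prefer_accepted, ambiguity, interactive, reject", {
  two_accepted <- taxon_set(list(
    taxon(parse_name("Aus bus L.")),
    taxon(parse_name("Aus bus Sm."))
  ))
  one_accepted <- taxon_set(list(
    taxon(parse_name("Aus bus L.")),
    taxon(parse_name("Xus yus Sm."),
          synonyms = list(parse_name("Aus bus Jones")))
  ))
  q <- parse_name("Aus bus")  # no authority

  r <- match_name(q, one_accepted)
  expect_equal(r$outcome, "matched")
  expect_equal(format_name(r$accepted_name, FALSE), "Aus bus")

  r <- match_name(q, two_accepted)
  expect_equal(r$outcome, "ambiguous")
  expect_length(r$alternatives, 2)

  r <- match_name(q, one_accepted,
                  match_config(homonym_policy = "reject"))
  expect_equal(r$outcome, "ambiguous")

  picks <- match_name(q, two_accepted,
                      match_config(homonym_policy = "interactive"),
                      decider = function(query, candidates)
                        list(action = "pick", index = 2L))
  expect_equal(picks$outcome, "matched")
  expect_equal(format_authority(picks$accepted_name$authority), "Sm.")

  rejects <- match_name(q, two_accepted,
                        match_config(homonym_policy = "interactive"),
                        decider = function(query, candidates)
                          list(action = "reject"))
  expect_equal(rejects$outcome, "rejected_by_user")

  expect_error(match_name(q, two_accepted,
                          match_config(homonym_policy = "interactive")),
               class = "taxonmatch_config_error")
})

test_that("match_dataset reassigns data to accepted names and logs in order", {
  ref <- paper_fixture_reference()
  queries <- list(
    list(name = parse_name("Mucuna holtoni"), data = list(seed_mass = 0.1)),
    list(name = parse_name("Zea mays subsp. mays"), data = list(crop = TRUE)),
    list(name = parse_name("Glycyrrhiza glandulifera Ledeb"),
         data = list(root = "sweet"))
  )
  md <- match_dataset(queries, ref)
  expect_length(md$log, 3)
  expect_equal(vapply(md$log, `[[`, "", "step"),
               c("fuzzy", "infraspecific_promotion", "name_only"))
  out_names <- sort(vapply(md$taxa$taxa, function(t)
    format_name(t$accepted_name, FALSE), character(1)))
  expect_equal(out_names,
               c("Glycyrrhiza glabra", "Mucuna holtonii", "Zea mays"))

  # two synonyms of one accepted name land on one taxon with both mappings
  ref2 <- taxon_set(taxon(parse_name("Aus bus L."),
                          synonyms = list(parse_name("Aus cus Sm."),
                                          parse_name("Aus dus Jones"))))
  md2 <- match_dataset(list(
    list(name = parse_name("Aus cus Sm."), data = list(k1 = 1)),
    list(name = parse_name("Aus dus Jones"), data = list(k2 = 2))
  ), ref2)
  expect_length(md2$taxa, 1)
  expect_equal(md2$taxa$taxa[[1]]$data$k1, 1)
  expect_equal(md2$taxa$taxa[[1]]$data$k2, 2)
})

test_that("match_dataset is deterministic under prefer_accepted", {
  ref <- generate_reference(30, 2, seed = 8, homonym_count = 3)
  pairs <- corrupt_queries(ref, corruption_config(
    typo_rate = 0.3, synonym_use_rate = 0.5, authority_drop_rate = 0.5,
    seed = 8))
  queries <- lapply(pairs, function(p) list(name = p$query, data = list()))
  cfg <- match_config(homonym_policy = "prefer_accepted")
  log1 <- match_log_df(match_dataset(queries, ref, cfg)$log)
  log2 <- match_log_df(match_dataset(queries, ref, cfg)$log)
  expect_identical(log1, log2)
})
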