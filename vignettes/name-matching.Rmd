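---
title: "Matching species names against a reference synonymy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching species names against a reference synonymy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxonmatch)
```

## The problem and the model

Species-level data scattered across sources can only be combined through
scientific names, and names are unreliable join keys: taxa carry synonyms,
name strings are reused across taxa (homonyms), spellings drift, and
author citations — the one disambiguator — are themselves abbreviated
inconsistently. `taxonmatch` treats the reference source as a *synonymy*:
each taxon has exactly one accepted name and any number of synonyms, all
indexed by their case-folded binomial **without** the authority. That
indexing choice is deliberate: homonyms are *supposed* to collide in the
index, so that the authority comparison — not string luck — decides
between them.

Matching a query runs a fixed cascade, and the step that succeeds is
recorded in the result:

1. `exact_with_authority`: binomial hit plus a literally identical
   (whitespace/case-normalized) author citation. Literal is the operative
   word — a citation that merely *agrees* under the component comparator
   ("Ledeb" vs "Ledeb.") is deferred to step 2, so the log distinguishes
   a byte-exact record from an inferred one.
2. `name_only`: binomial hit with compatible authorities. The comparator
   returns `agree` / `neutral` / `disagree` / `incompatible`; candidates
   with the best available class win (agreement beats silence beats
   disagreement), `incompatible` candidates are removed unconditionally,
   and plain disagreement is accepted with a warning note unless
   `allow_authority_mismatch = FALSE`.
3. `infraspecific_promotion`: a below-species query with no hit retries
   as its parent binomial — for all infraspecific names, only nominal
   ones, or never (`nominal_only` is the default; the same switch governs
   subspecies, varieties and forms).
4. `fuzzy`: blocked q-gram lookup, then the same authority filtering.

An unmatched or ambiguous query is never silently dropped: it appears in
the match log with its alternatives and the notes explaining what was
tried.

## Author citations: a bespoke comparator

Citations are too short for string similarity to be safe — "Vahl" and
"non Vahl" are nearly identical as strings and opposite in meaning ("non"
marks the name as *not* the one that author defined). The parser is a
tolerant tokenizer: a leading parenthesized group is the basionym
authors, "ex" separates the proposer from the validating publisher,
"non" switches to the excluded group, and a four-digit token in 1750–2100
is a year (the window keeps page numbers and typos out of the year slot
while covering the Linnaean era). Unknown fragments attach to the nearest
group and never abort a parse; tolerance here is a design requirement,
since real citations are full of annotations no grammar anticipates.

Comparison is then component-wise. Surnames match abbreviation-aware
("Ledeb." matches "Ledebour" by marked prefix); initials and years are
compared only when both sides record them — absence is treated as missing
information (`neutral`), never as disagreement. The `incompatible`
verdict is reserved for positive evidence: one side's author appearing in
the other's excluded group. An incompatible candidate is vetoed at every
cascade step, regardless of configuration.

## The fuzzy score and its parameters

A name is broken into overlapping grams of `q = 3` characters after
prefixing `q − 1 = 2` pad characters; **no trailing pads** are added.
Front-only padding weights the start of the name (where the genus sits
and errors are rare) and de-emphasizes the ending, where Latin gender
endings and doubled letters cause most variation. Similarity is the
Jaccard ratio of the two gram *sets*:

```{r}
similarity("Mucuna holtoni", "Mucuna holtonii")
similarity("Mucuna restonii", "Mucuna holtonii")
```

The intersection-over-union denominator was chosen over Dice or
shorter-string-proportion because it is a true set metric, symmetric and
1 only on identical gram sets; on the canonical misspelling pair above it
gives 14 shared grams out of 15 in the union, ≈ 93%. Set (not multiset)
semantics keep repeated grams from double counting. The default
acceptance threshold is 0.70, inclusive (`score ≥ threshold`), and ties
between equal-scoring candidates break lexicographically so batch runs
are deterministic.

Lookups are *blocked*: only reference names sharing the query's first
`q` characters (case-folded) are scored. Blocking makes lookup cost
proportional to one bucket rather than the whole reference, at a known
price — an error inside the first three characters is unrecoverable by
construction. The pad character is a non-letter sentinel (the logical-and
sign) that cannot occur in normalized names.

## Names, normalization and degenerate inputs

Parsing normalizes to Unicode NFC, collapses whitespace, title-cases the
genus and lower-cases epithets, preserving the raw string for logs. The
multiplication sign or a free-standing "x" sets a hybrid flag and is
stripped from the stored words. Recognized infraspecific markers are
`subsp.`/`ssp.`, `var.` and `f.` — the last case-sensitively, because an
uppercase "F." is an author initial, not a form marker. Under the
zoological style a bare lowercase third word is a subspecific epithet;
under the botanical style it is left to the authority parser. This
bare-trinomial rule is this package's own convention for zoological
input. A string with no recognizable genus raises a typed parse error
carrying the offending input; in batch CSV reading such rows become
explicit skip records so row counts are conserved.

Formatting is the inverse of parsing: `parse_name(format_name(n))`
reproduces `n` exactly (ignoring the raw field), a property the suite
exercises over 1000 generated names spanning ranks, hybrids and
authority shapes.

## Homonym policy

When several candidates survive filtering, the policy decides:
`prefer_accepted` takes the candidate hit via an accepted name when
exactly *one* such candidate exists — with two accepted-name candidates
there is no "most likely option" and the query is ambiguous.
`interactive` hands the candidate list to a caller-supplied callback
(the CLI maps this to the ambiguous outcome under `--non-interactive`);
`reject` marks the query ambiguous outright. The default (`auto`)
prefers the accepted name when the query has no authority — the case
where nothing better is available — and asks otherwise.

## What the synthetic benchmark emulates — and what it does not

`generate_reference()` builds pseudo-Latin binomials from syllable
templates (consonant–vowel pairs plus Latin endings), so gram statistics
and blocking-bucket occupancy resemble real binomials rather than random
strings. Each taxon gets an author citation drawn from an invented
surname pool with realistic abbreviation and initial rates, and homonym
pairs can be injected: two taxa sharing a synonym binomial under
different authorities.

`corrupt_queries()` damages one query per taxon with the documented
failure modes, each at an independent probability: a single-character
typo (substitution, deletion or insertion) in the epithet, a Latin
gender-ending swap among -a/-um/-us, substitution of a synonym for the
accepted name, and dropping the authority. Typos avoid the first three
characters of the name so that a typo'd query stays reachable by the
blocked fuzzy step; errors in the blocking prefix are a known,
deliberate blind spot of the method and would only measure that design
choice again. All randomness is scoped to the supplied seed, so
identical seeds give identical references, queries and metrics.

Benchmark defaults are modest deliberately — references of tens to a few
hundred taxa with two synonyms each; the suite uses 20–60 taxa per run
and averages degradation curves over five seeds. Passing these tests
shows the cascade recovers *modelled* corruption (it does: zero
corruption yields precision = recall = 1 with every match at the exact
step, and recall falls monotonically as the typo rate rises). It does
not show robustness to what the generator leaves out: OCR-specific error
distributions, vernacular contamination, multi-word epithets, or
citation conventions beyond the Latin-alphabet codes.

## Region standardization

Distribution lists name countries and informal "major regions"
inconsistently across sources. A region index maps normalized names
(case-folded, diacritics stripped) to canonical codes at one level of a
scheme such as TDWG's four-level hierarchy; aliases map alternative
spellings to codes and groups expand to member sets. The full TDWG
tables are not bundled — the loader takes any CSV with the documented
schema, and the package ships a small invented 12-region table
(`regions_synthetic.csv`) for its tests. Standardization is a union over
resolutions, idempotent on already-canonical codes, monotone in its
input, and reports unresolved names as values rather than errors.

## Known limitations

* Authority comparison requires equal author counts to agree; "Hook."
  vs "Hook. & Arn." is a disagreement, not partial agreement.
* The JSON store schema is this package's own (versioned, refused on
  mismatch); no compatibility with other tools' serializations is
  attempted.
* No nomenclatural-code legality checking and no validation against the
  standard author-abbreviation registries; the parser is tolerant by
  design, not normative.
* Fuzzy matching operates on the whole binomial string, not per word; a
  genus misspelling past the third character is recoverable, but genus
  and epithet errors are not scored separately.
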