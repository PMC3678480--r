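# taxonmatch

Linking species datasets by scientific name.

Combining trait, distribution or occurrence data from different sources
means joining on Linnaean names — and that join fails constantly, for four
well-known reasons:

* **Synonymy** — one taxon has collected several names over 250 years of
  revision;
* **Homonymy** — one name string has been applied to more than one taxon
  (*Glycyrrhiza glandulifera* has served for both *G. glabra* and
  *G. uralensis*; only the author citation, "Ledeb.", separates them);
* **Spelling variation** — transcription errors, long-standing variant
  spellings, and Latin gender confusions (*Viscum alba* for
  *Viscum album*);
* **Format anarchy** — real data live in CSV files that put the name and
  its author citation in one field, or two, next to arbitrary trait
  columns.

`taxonmatch` is for ecologists and evolutionary biologists who need that
join to be automatic, reproducible and auditable. It parses names and
author citations into structured objects, resolves query lists against a
reference synonymy, merges matched datasets under accepted names, and
standardizes free-text distribution regions to a canonical scheme such as
the TDWG World Geographical Scheme.

## The matching cascade

For each query name, candidate resolutions are tried strictly in order:

1. **Exact** — binomial plus a literally identical author citation.
2. **Name-only** — the binomial matches; authorities are compared
   component-wise (surnames abbreviation-aware, so "Ledeb." ≡ "Ledebour";
   initials and years only when both sides have them). A candidate whose
   citation is *incompatible* with the query — its author appears after a
   "non" qualifier on the other side — is vetoed outright, never matched.
3. **Infraspecific promotion** — an unmatched name below species rank is
   retried as its parent species (for all infraspecific names, only
   nominal ones like *Zea mays* subsp. *mays*, or never).
4. **Fuzzy** — names are broken into overlapping 3-letter q-grams with two
   padding characters prepended and *none* appended (so the ending, where
   spellings most often differ, carries less weight). The similarity of
   two names is the Jaccard ratio of their gram sets

   $$s(a,b) = \frac{|Q(a) \cap Q(b)|}{|Q(a) \cup Q(b)|}$$

   and candidates with `s ≥ 0.70` (configurable) are accepted, best score
   first. Lookups are blocked: only names sharing the query's first three
   characters are compared.

Homonyms surviving these filters are resolved by policy: prefer the single
accepted-name candidate, hand the choice to a callback, or flag the query
ambiguous. Every decision lands in a match log.

## Worked example

```r
library(taxonmatch)

ref <- taxon_set(list(
  taxon(parse_name("Glycyrrhiza glabra L."),
        synonyms = list(parse_name("Glycyrrhiza glandulifera Ledeb."))),
  taxon(parse_name("Glycyrrhiza uralensis Fisch."),
        synonyms = list(parse_name("Glycyrrhiza glandulifera Waldst. & Kit."))),
  taxon(parse_name("Zea mays L.")),
  taxon(parse_name("Mucuna holtonii (Kuntze) Moldenke"))
))

queries <- list(
  list(name = parse_name("Mucuna holtoni"),                 data = list(seed_mass = 0.12)),
  list(name = parse_name("Zea mays subsp. mays"),           data = list(crop = TRUE)),
  list(name = parse_name("Glycyrrhiza glandulifera Ledeb"), data = list())
)

md <- match_dataset(queries, ref)
match_log_df(md$log)[, c("original_name", "matched_accepted_name", "step", "score", "outcome")]
#>              original_name matched_accepted_name                    step     score outcome
#> 1           Mucuna holtoni       Mucuna holtonii                   fuzzy 0.9333333 matched
#> 2     Zea mays subsp. mays              Zea mays infraspecific_promotion        NA matched
#> 3 Glycyrrhiza glandulifera    Glycyrrhiza glabra               name_only        NA matched
```

Each row is one query. The misspelt *Mucuna holtoni* reaches its target
through the fuzzy step: its 14 q-grams are all shared with the 15 of
*Mucuna holtonii*, a similarity of 14/15 ≈ 0.933 — comfortably above the
0.70 threshold (while *Mucuna restonii*, at 0.50, would be rejected). The
nominal subspecies promotes to its parent species, and the homonymous
synonym *G. glandulifera* "Ledeb" resolves to *G. glabra* because the
recorded synonym's authority "Ledeb." agrees, while the *G. uralensis*
homonym's "Waldst. & Kit." does not. `md$taxa` now holds the queries'
data keyed by the reference's accepted names.

The same pipeline runs from a shell via the installed script
(`inst/scripts/taxonmatch`), with subcommands `match`, `combine`,
`regions` and `bench`.

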