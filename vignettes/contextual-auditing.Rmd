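---
title: "Contextual lexical auditing of SNOMED CT: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual lexical auditing of SNOMED CT: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simaudit)
```

## The method

SNOMED CT concepts are modeled structurally: each concept has parent
concepts (is-a relationships), attribute relationships (e.g. *Method*,
*Procedure site*), and role groups that bundle attributes which jointly
qualify one aspect of the definition. Auditing this modeling concept by
concept is hard because a single concept offers no point of reference.

Contextual lexical auditing supplies that reference: concepts whose
descriptions are nearly identical — differing by exactly **one word** — are
expected to be modeled nearly identically. `simaudit` therefore

1. reduces every active fully specified name (FSN) and synonym of every
   concept in a chosen hierarchy to a **bag of words** (lowercased,
   semantic tag stripped, stop words removed, duplicates kept);
2. groups concepts any two of whose bags differ by exactly one word into
   **similarity sets**;
3. computes per concept a **structural profile**: number of parents, number
   of attributes, number of role groups;
4. classifies each set as a *Same set* (all members agree on all three
   counts) or a *Diff set* (some count differs), with non-exclusive subtype
   flags Diff-Par / Diff-Rel / Diff-Grp for parent, attribute and role-group
   count disagreement;
5. draws a seeded uniform sample of Diff sets of two to four concepts and
   writes an auditor-ready report. The tool flags *candidates*; the
   inconsistency verdict is left to the human auditor, and the report
   carries an empty verdict column for exactly that reason.

The working assumption — lexical twins should be structural twins — is a
heuristic, not a theorem. Same sets can still be wrong (both members
missing the same parent) and Diff sets can be legitimate (a genuinely more
complex sibling). The method concentrates auditor attention; it does not
replace the auditor.

## Normalization parameters

All knobs live in `normalization_config()` and can be loaded from a YAML or
JSON file with `read_normalization_config()`; the effective values are
echoed in the run log.

* `stop_words` (default `default_stop_words()`: *a, an, the, of, with, as,
  for, using, to, from, by, in, on, and, or*). The list is deliberately
  minimal: just the function words that appear in common procedure
  phrasings ("drainage **of** lesion", "arthrodesis **with** osteotomy
  **as for** flatfoot correction", "referral **to** … service"). A larger
  list would merge genuinely different names; a smaller one would split
  equivalent ones on connective words.
* `min_words` (default 5). Only concepts whose FSN still has at least five
  tokens after stop-word removal enter the analysis. Short names are
  lexically unspecific — one-word differences between four-word names pair
  up largely unrelated procedures — so the threshold trades recall for
  precision of the candidate sets.
* `strip_semantic_tag` (default `TRUE`). The trailing parenthesized tag
  (e.g. `"(procedure)"`) is removed from comparison bags so that FSNs can
  match synonyms, which carry no tag.
* `count_tag_for_threshold` (default `TRUE`). The tag token still counts
  toward `min_words`: an FSN with four content words plus its tag is
  eligible. The two switches are independent because they serve different
  purposes (comparability vs. specificity).

Tokenization keeps hyphenated words as single tokens (`non-surgical` is one
word, and differs from `surgical`), trims punctuation only at token edges,
and applies no stemming, lemmatization or spelling normalization —
`computed` and `computer` are different words, and collapsing them would
manufacture false matches. Word *position* is ignored throughout: bags are
multisets, so "Surgical biopsy of gastrointestinal tract" and
"Non-surgical gastrointestinal tract biopsy" differ only in
surgical/non-surgical.

"One word apart" is read as a symmetric single substitution: each bag must
have exactly one exclusive word after multiset cancellation, which forces
equal bag sizes. A strict subset (one name being the other plus one extra
word) does **not** qualify: those are parent/child-like name pairs, not
lexical siblings.

## Set semantics

Pairwise one-word similarity is not transitive (A–B and B–C one word apart
do not make A–C one word apart), so "group similar concepts into sets" is
underdetermined. `simaudit` resolves it with a **shared-template** rule:
each bag of *n* words is indexed *n* times under the (n−1)-word templates
obtained by deleting one occurrence of each distinct word; all concepts
meeting at one template key form one set. Members of such a set share the
same n−1 words and each contributes a distinct substituted word, so the
pairwise one-word property holds *within every set by construction*. The
alternative — merging overlapping pairs into cliques or components — was
rejected: it can emit sets containing pairs that are not one word apart,
and its output depends on merge order.

Consequences worth knowing:

* A concept may belong to several sets (via different descriptions or
  different substitution slots); the summary reports how many concepts do.
* The same concept pair matching via both FSNs and synonyms yields one set,
  not two: sets with identical member lists are deduplicated, keeping the
  canonically first template.
* Evidence is deterministic: per concept, the FSN-derived bag is preferred
  over synonyms, then the smallest description id, then the alphabetically
  first differing word. If two concepts at a key carry *identical* bags
  (zero words apart — duplicated descriptions), the later concept in
  canonical order falls back to another of its candidate words or is
  dropped from that set, preserving the pairwise contract.
* Eligibility gates the concept, not the description: an ineligible FSN
  excludes the concept's synonyms too, since the length threshold is
  defined on fully specified names.

## Structural comparison

Profiles count only **outgoing active** relationships of each member:
parents = active is-a rows, attributes = active non-is-a rows, role groups
= distinct nonzero `relationshipGroup` values among the attribute rows
(group 0 is the RF2 "ungrouped" convention and counts as no group; each
attribute row counts individually, so a group of two attributes contributes
two to the attribute count). Classification compares *counts only*. Two
members can have the same counts but different attribute types or target
values — such value-level discrepancies are visible to the auditor in the
report rows but do not make a set Diff; count-based classification is the
definition of the Same/Diff distinction, and value comparison is left to
the human judgment the sample is drawn for. Whether the relationship file
fed in is the stated or the inferred view is the caller's choice; the run
log records the file path.

## Sampling and determinism

`sample_sets()` draws uniformly without replacement from the pool of Diff
sets with at most four members (defaults: 50 sets, two-to-four concepts),
using a single integer seed. Everything downstream is deterministic:
canonical C-locale (radix) ordering is used for bags, keys, member lists
and output rows, set ids are the sorted member ids joined with `"|"`, the
report files contain no timestamps, and the RNG state of the calling
session is restored after sampling. Identical inputs, configuration and
seed therefore produce byte-identical reports — a property the test suite
asserts file by file.

Percentages in summaries are rounded to whole numbers, matching the usual
reporting style for these tables; raw counts are always printed alongside.

## The synthetic release generator

Real SNOMED CT releases are license-restricted, so `generate_release()`
fabricates structurally valid RF2 snapshot triples with a ground-truth
manifest:

* **Planted families**: each family shares an (n−1)-word template (n
  between 5 and 7 content words) and gives every member one globally unique
  substituted word; member word order is shuffled to exercise position
  independence. Each member also gets a preferred-term synonym.
* **Synonym-only families** emulate pairs whose FSNs diverge (three words
  apart) while their synonyms are one word apart.
* **Structural planting**: the base shape is two parents and two role
  groups of two attributes. Diff families perturb exactly one member: an
  extra parent (Diff-Par), an extra ungrouped attribute (Diff-Rel, leaving
  the group count untouched), or a regrouping that adds a third group
  without changing the attribute count (Diff-Grp). Flags are drawn
  independently per family with defaults 0.55 / 0.35 / 0.15, which makes
  roughly three quarters of the planted sets Diff sets with parent-count
  discrepancies the most common subtype — the kind of composition a large
  procedure hierarchy exhibits; 5% of families are synonym-only.
* **Decoys**: pairs one word apart but below the eligibility threshold, and
  eligible pairs two words apart. Neither may ever surface in a set.
* **Inactive rows**: one retired concept, one inactive description and one
  inactive relationship are planted to verify that inactive content is
  invisible to the pipeline.
* Identifiers come from a reserved numeric range and are *not* valid SCTIDs
  (no check digit); no licensed content is reproduced.

Default scale is 40 families (about 180 active concepts); the
oracle-equivalence tests use 20 independent 10-family releases, small
enough that the quadratic brute-force comparison of every bag pair is an
affordable independent oracle.

What the generator does **not** emulate: realistic word-frequency
distributions (real hierarchies share words heavily across unrelated
concepts, which mainly stresses index size, not correctness), description
inactivation history, multiple FSNs over time, cross-hierarchy attribute
targets with meaningful semantics, or concepts participating in many
overlapping similarity sets. Passing the planted-truth tests therefore
shows that the algorithms implement their definitions exactly; it does not
by itself validate the auditing heuristic on real terminology content,
which requires the licensed release and human review.

A separate hand-written fixture, `published_examples_fixture()`, pins the
tokenizer and set builder to real SNOMED wording: five documented concept
pairs (one-word FSN substitution; synonym-mediated match with three-word
FSN divergence; word-order permutation; staged-operation and
referral/discharge pairs) with structural rows reconstructed from their
published descriptions. The structural rows are synthetic reconstructions,
not release content.

## Degenerate inputs and edge rules

* A term that normalizes to an empty bag is dropped, not an error.
* A single concept whose own descriptions are one word apart never forms a
  set (sets need two distinct concepts).
* Two concepts with identical bags are zero words apart and never pair.
* Zero sets summarize to an all-zero table without division errors; an
  empty sampling pool yields an empty sample with a warning.
* A cycle among active is-a rows is fatal and names the concepts involved;
  a missing root, malformed line, wrong header or non-integer group number
  is fatal with the offending line number.

## Scale and the licensed release

All bundled tests run on generated fixtures and the published example
pairs. Release-level statistics — hierarchy size, number of sets, concept
coverage, the Diff/Same split, synonym-only set counts — are computed and
logged by `run_audit()` on whatever release it is given, so holders of a
SNOMED CT license can benchmark against a real Snapshot directly; those
numbers are a property of the release fed in and are not asserted by the
test suite. The in-memory pipeline holds all bags and index entries at
once; the January-release Procedure hierarchy (tens of thousands of
concepts) is well within reach of a laptop, but the quadratic
`pairwise_oracle()` is a test oracle only and should not be pointed at a
full hierarchy.

## Known limitations

* The stop-word list is a configuration choice; there is no canonical list,
  and results do change with it (the effective list is logged for that
  reason).
* Count-based classification cannot flag sets whose members differ only in
  attribute types or target values.
* The one-word criterion finds lexical *siblings*; parent/child name pairs
  (subset relations) and two-word variants are out of scope by design.
* Whether a synonym-rich concept with a short FSN should be eligible is
  debatable; eligibility is keyed to the FSN alone here.
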