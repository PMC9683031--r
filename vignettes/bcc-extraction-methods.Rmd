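---
title: "Rule-based extraction from BCC histopathology reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based extraction from BCC histopathology reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bccner)
```

`bccner` implements the classic architecture for clinical information
extraction from semi-structured reports: deterministic preprocessing, lexicon
(gazetteer) lookup, a cascade of declarative pattern rules, trigger-based
polarity detection, and structured record assembly.  This vignette is the
package's account of that machinery: the model and its assumptions, the
parameters that matter, the numerical conventions, and the places where a
design choice was genuinely open and we made one.

## The document model

A report is immutable text; everything else is *standoff annotation*: a
category, a character span, and a flat map of scalar features.  Offsets are
0-based and half-open (`[start, end)`), the convention of most standoff
formats, so adjacent spans share a boundary offset and never a character.
Annotation tables are tibbles ordered by start ascending then end
descending, which makes "longest annotation first" the natural iteration
order everywhere downstream.  Feature values are scalars only; anything
structured (a measurement with a value, unit and clock position) is
flattened into several features.  This keeps the CSV output, the feature
compatibility rules in scoring, and the standoff JSON all trivially
isomorphic.

## Preprocessing

**Tokenisation** has two policies because the package serves two different
consumers.  The `general` policy (pipeline default) emits words, numbers
(with one internal decimal point) and individual punctuation marks, each
with a `kind` feature — measurement extraction needs numbers and slashes.
The `capture` policy keeps only maximal alphanumeric runs that begin with a
letter; it exists solely for capture-probability corpus sizing, where the
token universe is deliberately restricted to letter-initial tokens and
numbers are excluded by definition.  In `"1.2 mm"` the capture policy sees
only `mm`.

**Sentence splitting** is rule-based: boundaries after `.`, `?`, `!`
followed by whitespace, and at newlines.  A short exception list protects
decimals, `e.g.`/`Dr.`-style abbreviations, and unit abbreviations
(`cm.`, `mm.`) followed by a lowercase continuation — measurement prose
dominates these reports and a split inside a measurement sentence would
truncate every ConText scope in it.  No learned segmentation: reports are
short, regular, and the failure modes of a statistical splitter are harder
to audit than an exception list.

**Section segmentation** matches configurable header synonyms
(case-insensitive, at line start, optional colon) and extends each section
to the next header.  Text before the first header is `ReportDetails`, and a
headerless report is a single `ReportDetails` section, so every character
is always inside exactly one section.  Synonym lists are config
(`sections.headers`) because header wording varies by report writer; the
shipped defaults cover the common variants of the nine canonical sections.

## Gazetteer lookup

Lexicons are tab-separated files (`term`, `majorType`, `minorType`,
`conceptCode`) grouped by an index file.  Compilation folds case for
case-insensitive entries, rejects duplicate `(term, majorType, minorType)`
triples, and indexes entries by first token.  Matching is anchored on token
boundaries (never regex word boundaries, so the Token layer is the single
source of truth about word edges), multi-word terms must be separated by
exactly one space, and at each start offset only the longest match is
emitted while overlapping matches with different starts are all kept.
`carcinoma` never fires inside `carcinomatous`.  Concept codes are opaque
strings carried through to output; no terminology service is consulted.

The shipped lexicons cover BCC subtypes (nodular, superficial,
infiltrative, micronodular, morphoeic, basosquamous), margin and
completeness vocabulary, prognostic factors, invasion levels, anatomical
sites, laterality, and measurement axes, one file per major type.

## The rule cascade

Rules are YAML documents: a phase header (`name`, `control`, `input`
categories) and an ordered rule list, each rule a sequence of pattern
elements (category, feature equality / set-membership / covered-text regex
predicates, a quantifier, an optional binding label) plus create/remove
actions.  The dialect deliberately has no embedded code and no quantifiers
over sub-patterns — element quantifiers with greedy, backtracking matching
are enough for this grammar and keep rule files declarative and portable.

Phase control follows the usual transducer conventions:

* `appelt` — at each position the longest match wins; ties break by higher
  rule priority, then declaration order.  A match consumes its region, so
  within a phase an appelt rule's outputs never overlap.
* `first` — first declared rule that matches.
* `all` — every rule's match is applied, nothing is consumed.

Sequence adjacency is defined over the phase's *input* annotations: the next
element must match at the next occupied start offset at or after the current
match end.  Text covered by no input annotation is skipped, which is what
lets `Lookup(subtype) Lookup(diagnosis)` match across the space between two
lookups.  All structural errors — unknown quantifiers, actions referencing
unbound labels, duplicate rule names, a phase consuming a category first
produced by a later phase — are load-time errors carrying the file and rule
name; a rule set that loads cannot fail at run time.

Feature values copied from bindings are normalised (lower-cased, whitespace
collapsed) unless the action requests raw text; raw is used where the
surface form is the value (accession numbers, dates, measurement phrases).

The shipped cascade has three phases: token-level rules for fixed-format
fields (accession numbers, numeric and month-name dates, requestor names;
`all` control, since date patterns intentionally produce both an
excision-date and a report-date candidate), lookup-anchored entity rules
(`appelt`), and a cleanup phase removing raw lookups from the output.
Section attribution then removes any entity whose category disagrees with
its enclosing section — this is how the date ambiguity resolves, and it is
the package's version of the cascade's remove-from-output behaviour for
out-of-place matches.

## ConText polarity

Negation and affirmation use the trigger-and-scope model: a non-pseudo
trigger opens a scope in its direction; the scope closes at the first
termination term, the sentence boundary, or an optional token-window cap
(`context.window_tokens`, default unlimited — the published default for
this algorithm family is sentence-bounded scoping, and these sentences are
short).  Targets wholly inside a negation scope get `negated = TRUE`,
affirmation scopes set `affirmed = TRUE`, and a pseudo trigger (e.g. "no
increase") suppresses any trigger starting at its position.  Only these two
axes are modelled; temporality and experiencer detection are out of scope
for pathology reports, which describe one specimen in the present.

Where an annotation falls in both a negation and an affirmation scope,
negation wins and `affirmed` is not set: the two flags are mutually
exclusive by construction, and a false "affirmed" on a negated finding is
the more harmful error in this domain.  Trigger matching reuses the
gazetteer scanner, so trigger and lexicon semantics (case folding,
longest-match-per-start, token anchoring) can never drift apart.

## Records and CSV output

Entity annotations are grouped into per-specimen, per-lesion records.
Line-initial specimen labels (`A.`, `B)`, `1.`) in the macroscopic and
microscopic sections open a specimen context inherited by following
entities; a report without labels gets one implicit specimen.  Report-level
fields (accession, dates, requestor, clinical site) replicate onto every
lesion row.  Measurements are normalised to millimetres (`cm` × 10),
dimension triplets distribute their unit, clock positions must be 1–12, and
dates are emitted ISO-8601 from numeric or month-name forms.  The CSV is
RFC-4180 with a stable column order (id triplet, then schema declaration
order), absent values empty, negated booleans rendered as the explicit
string `negated`; files are written to a temporary name and atomically
renamed, and a sidecar JSON lists MD5 checksums of every resource file used.

## Evaluation

Alignment pairs key (gold) and response (system) annotations of one
category: a pair must overlap and be *feature-compatible*, meaning every
key feature appears in the response with an equal normalised value (extra
response features are fine — the inclusion runs from key into response).
Coextensive compatible pairs count `correct`, other overlapping compatible
pairs `partial`, leftovers `missing`/`spurious`.

**Design choice — optimal assignment rather than greedy pairing.**  The
obvious implementation pairs greedily by longest overlap.  Greedy is not
optimal: a single long-overlap pairing can block two shorter pairings that
together score better, and randomised testing finds such cases readily at
realistic sizes.  Because the package's own invariant is that alignment
tallies agree with exhaustive enumeration, `align_annotations()` solves the
exact maximum-weight assignment (Hungarian algorithm, O(n³) in the per-
category annotation count, negligible at per-document scales), with
coextensive pairs weighted above any attainable number of partial pairs so
the optimum is lexicographic: most correct pairs first, then most partial.
The tallies (though not necessarily the pairing itself) are unique, hence
deterministic.

Scoring uses the partial weight *w* = 0 / ½ / 1 for strict / average /
lenient.  Zero denominators follow the empty-vs-empty convention: a score
with an empty denominator is 1 if the other side is also empty, else 0 —
correctly extracting nothing from a document that contains nothing is
perfect performance, not undefined.

Corpus evaluation reports both aggregations: *macro* (mean of per-document
scores; a document contributes to a category when either set mentions it)
with normal-approximation 95% confidence intervals over the per-document
score distribution, and *micro* (scores of the summed tallies).  The normal
approximation is the pragmatic default for a mean of bounded scores at
n ≈ 200; with one document the half-width is defined as 0.

Token-level agreement labels each token with the covering entity (longest
annotation wins, then schema order — one label per token), builds a
confusion matrix over categories ∪ NONE, and derives Cohen's kappa
(`p_e = 1` degenerates to 1 if `p_o = 1`, else 0) and positive specific
agreement (`2·both/(first+second)`, 0/0 ≡ 1).  Pairwise F1 between two
annotators is reported in both role directions; under the symmetric partial
weights, swapping roles exchanges precision and recall and leaves F1
unchanged, which the suite verifies on random pairs.

The package ships the published per-entity tallies of a rule-based BCC
extraction study as a fixture.  Several printed cells are internally
inconsistent with the count identities (key total = correct + missing +
partial; response total = correct + spurious + partial);
`tally_identity_check()` flags exactly those cells, and the tallies are
shipped as printed rather than "fixed".

## Corpus sizing by capture probability

The estimator answers: how many documents must a validation set contain so
that the tokens of the concept vocabulary are represented?  For a token in
*d* of *D* corpus documents, the probability a uniform without-replacement
sample of *N* documents contains it is `1 − C(D−d, N)/C(D, N)`, computed
with log binomial coefficients.  Hypergeometric, not binomial: documents
are sampled, not re-drawn.  The corpus-level aggregate is the mean
per-token capture probability by default, with a threshold-fraction
alternative (`aggregation = "fraction"`) behind a flag; both are
reconstructions of the same idea and the choice is logged in the output.
The vocabulary is taken from a supplied concept list under the `capture`
token policy, not from all corpus tokens — coverage of the concepts is what
the validation set must guarantee.  Since capture is non-decreasing in *N*,
`min_sample_size()` binary-searches; the suite checks it against a linear
scan and the analytic form against full enumeration (all *d*, *N* for
D ≤ 12) and Monte Carlo resampling.

## The synthetic corpus

Real health-board corpora cannot be shared, so the generator is a
first-class module, not a test shim.  Its defaults are the study conditions
the package targets: about 1.5 lesions per report (lesion-count
distribution 0.55/0.40/0.05 over 1/2/3), 7% of reports on a structured
proforma, a bank of 20 report-writer styles (header synonyms, date formats,
sentence variants), and a negation rate of 0.8 for prognostic-factor
mentions — pathologists overwhelmingly record these factors as absent.
Physiologic ranges (thickness 0.5–8 mm, clearances up to 10 mm, clock 1–12)
are plausible for BCC excisions.  Generation is deterministic: each
document draws from its own seed-derived stream, so corpora are reproducible
regardless of generation order, and a manifest records realized lesion
counts and template fraction.

The generator emits gold standoff annotations and records tracked exactly
as the text is composed, with phrasing drawn from the same lexicons the
cascade matches on.  That is deliberate and defines what the end-to-end
closure test (200 reports, P = R = F1 = 1 under strict and lenient
matching) does and does not show: it proves the machinery — tokeniser,
scanner, cascade, ConText, section attribution, record assembly, scorer —
is internally consistent and lossless on in-grammar text.  It says nothing
about recall on out-of-grammar phrasing, misspellings, OCR noise, or the
error profile of real annotators, which is precisely where real systems
lose performance.  Simulated annotator pairs (span jitter, drops, feature
flips at a configurable disagreement rate) exercise the agreement stack the
same way: shape, not realism.

## Problem sizes and numerical conventions

The checked configurations are: closure on 200 synthetic reports; scope
boundedness over 10,000 generated sentences; 500 random alignment problems
of up to 6×6 annotations against exhaustive enumeration; 1,000 random
tallies for the strict ≤ average ≤ lenient ordering; capture enumeration up
to D = 12 and a D = 1,000 Zipf-like sizing table; 10,000 Monte Carlo draws
at three standard errors.  These sizes give the property checks real
statistical teeth while keeping a full run comfortable on one core.
Tolerances on closed forms are 10⁻¹²; stochastic checks use explicit
standard-error bounds; scores are proportions in [0, 1] and rendered ×100
only at presentation edges.

## Known limitations

Only English-language, BCC-shaped reports are in scope; the schema is
user-extensible but no SCC/melanoma resources ship.  The rule dialect has
no sub-pattern closures and no computed actions.  ConText covers
negation/affirmation only.  Specimen segmentation assumes line-initial
labels; interleaved multi-lesion narratives without labels collapse into
one specimen.  The shipped cascade is a reconstruction built from the
concepts named in the public record of such systems, not a port of any
production rule set, and its perfect closure scores are a property of the
synthetic grammar, not a performance claim about clinical text.
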