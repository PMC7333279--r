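---
title: "Composite common data elements: model, constraint language, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite common data elements: model, constraint language, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdemdr)
```

## The problem

Clinical forms are built from data elements: named items with a precise
meaning (an object class plus a property, the *data element concept*) and a
representation (datatype, unit, format, permissible values, the *value
domain*).  Metadata registries in the ISO/IEC 11179 tradition standardize
these elements so that studies and institutions can share data, but the
classical registry treats every element as independent: it cannot say that
a form's fields belong together, that one field's admissibility depends on
another's value, that a derived field has a formula, or that a free-text
field secretly accepts two datatypes.  In practice those relationships are
exactly what distinguishes a well-specified case report form from a bag of
labels, and leaving them out forces registries to mint thousands of
near-duplicate elements.

`cdemdr` implements an extended model that keeps the 11179 core and adds:

* **atomic CDE subtypes** — *plain*; *variable* (the value is a code from a
  controlled vocabulary, realized as the key column of a dictionary
  table); *hybrid* (one concept, several alternative value domains with
  distinct datatypes, e.g. a dialysis-session `Time` that accepts either
  `08:00` or the enumerated strings `Start`/`Finish`);
* **composite CDEs** (cCDEs) — identified, reusable groups of two or more
  atomic CDEs, of kind *general*, *repeated* (the member set is entered
  many times as rows of a table) or *dictionary* (a variable member is the
  foreign key into a reference table that supplies units and normal
  ranges);
* **four constraint kinds** — *Operated* (formulas and assertions between
  members), *Required* (non-null), *Dependent* (one element's permitted
  nullness governed by a predicate over others), *Ordered* (relative field
  order inside a composite; ordering never applies to a lone atomic
  element).

Composites hold atomics and hybrids hold plain atomics; nesting stops
there.  Two levels are what clinical forms actually exhibit, and the flat
structure keeps identity, reuse counting and validation decidable at a
glance.

## The constraint language

Rules are written operator-first in parentheses:

```
(Required CDE40 CDE41)
(IF (or (!= CDE20 'Yes') (!= CDE21 'Yes')) CDE22 NULL)
(< DE:47618 DE:47619)
(IF (= CDE31.unit_of_measure 'm') (/ CDE30 CDE31 CDE31)
    (* (/ CDE30 CDE31 CDE31) 10000))
```

Lexical choices follow the printed conventions of the source material the
examples come from: commas are whitespace, string literals use single
quotes, `NULL` is uppercase, `!=` may be typeset with an internal space,
and identifiers are opaque tokens so both `CDE30` and `DE:47616` are ids
(the colon belongs to the token).  The only attribute path is
`.unit_of_measure`, which reads the entered (or declared) unit of the
referenced element — that is what lets one BMI rule serve both metre- and
centimetre-entered heights.

Semantics:

* arithmetic (`+ - * /`) folds left over two or more numeric arguments, so
  `(/ a b c)` is `(a/b)/c`; division by zero is an error, and a null
  operand makes the whole arithmetic result null;
* relational operators chain pairwise (`(= a b c)` means all equal,
  `(< a b c)` strictly increasing); `!=` is binary only, because an n-ary
  "not equal" is ambiguous between pairwise-distinct and not-all-equal;
* any comparison with a null operand is **indeterminate**, and
  indeterminacy propagates through `and`/`or`/`not` as Kleene three-valued
  logic (`false and x` is false, `true or x` is true, everything else
  involving indeterminate stays indeterminate).  Nullness itself is the
  Required constraint's business; comparisons never silently treat null as
  a value;
* `IF` evaluates its condition and then exactly one branch.

One widely-circulated rendering of the BMI rule scales by a token printed
as `100,100`.  Under comma-as-whitespace that reads as two literals and no
left-fold over them yields kg/m² from kilograms and centimetres, so the
registry built by `demo_registry()` carries the mathematically explicit
form `(* (/ CDE30 CDE31 CDE31) 10000)`; the garbled token remains
parseable (as two number literals) but is not used as a formula.

There is no assignment operator.  The model's "assignment" class is
realized implicitly: an Operated derivation writes its target, a Dependent
rule forces its target to null.  The language deliberately has no
variables, user functions, loops or infix syntax — rules must stay
statically analyzable (see `collect_refs()`, which the linter uses to
reject rules referencing non-members).

`classify_rule()` recovers the constraint kind structurally: `Required` and
`Ordered` by head symbol, `(IF <boolean-expr> <ref> NULL)` is Dependent,
anything else is Operated.  A declared kind that disagrees with the
structural classification is not an error at registration time — the file
may be hand-written — but `lint_registry()` reports it.

## Validation

`validate_record()` runs value checks first (numeric syntax, enumerated
membership, ISO 8601 dates, `HH:MM` times; hybrids try their members in
declared order and the first successful parse wins), then rules in the
fixed kind order Required → Dependent → Operated → Ordered → Dictionary,
by id within a kind.  The order is a determinism device, not a semantic
claim: the kinds are independent, but reports must be reproducible and
diffable.

Severities: a violated constraint is an `error`; a condition or assertion
that cannot be decided because something is null is an `info` finding of
kind `indeterminate` (the missing value, if it matters, is flagged by
Required); a significance value present on a result flagged normal is a
`warning`, because only the abnormal direction of that dependency is
normative and the reverse is a courtesy check.

Operated derivations compare an entered target against the computed value
with relative tolerance `1e-6` and absolute `1e-9` — derived clinical
values such as BMI are reported to at most two decimals, so these
tolerances are far below clinical resolution while still absorbing decimal
round-tripping.  When the target is absent the derived value is reported
instead (fill mode; the `derive` CLI subcommand prints it).

Repeated composites validate row by row (`validate_table()`); rows are
independent by design.  Cross-row constraints (e.g. monotone session
times) are out of scope: nothing in the model as specified states them.
The Ordered check compares the rule's references against the record's
field order as a subsequence, so interleaved non-members are harmless; a
record without a field order yields a single unverifiable-info finding.

Dictionary composites check, in order: the foreign key is a table key
(exact match after trimming — reference tables are controlled content, so
case differences are treated as real mismatches); the entered unit is
offered for that key; the numeric result against that unit's inclusive
normal range, with the implied Normal/Abnormal expectation compared to the
entered flag; and the abnormal→significance dependency.  Bounds are
inclusive because `lo ~ hi` reference intervals are conventionally closed
in clinical use.  Unit conversion is deliberately absent — the tables
store parallel ranges per unit instead, which is both simpler and closer
to how laboratory dictionaries are actually published.

## Integration metrics

Given an extraction corpus (per group, per document, the list of extracted
element occurrences, plus the composite groupings assigned in each group),
`metrics_report()` computes for every group and for the pooled corpus:
occurrence and unique counts, composites, captured and free elements, and
four percentages — reuse rate `(n_total − n_unique)/n_total`, capture
share, representation efficiency `(n_ccde + n_free)/n_total`, and the
integration reuse ratio `(n_total − n_ccde − n_unique)/n_total`.  Two
capture denominators (unique vs total extracted) are both in legitimate
use, so `capture_share()` takes its denominator explicitly.  Percentages
round half-up to one decimal; banker's rounding would disagree on ties
with every printed convention the formulas mirror.

The package does not group elements into composites itself: grouping is a
clinical-judgment input, supplied in the corpus.  A counts-only corpus
form exists so printed summary tables can be checked without
reconstructing occurrence lists.  Element identity across documents is the
registry id when both sides have one, otherwise the canonical
`cde_signature()` (case-folded, whitespace-collapsed name + datatype +
unit) — a reproducible proxy for what is, in reality, a manual mapping
step.

## The fixture generator

`generate_fixture()` writes a registry, an extraction corpus, a table of
medical-history rows and an answer key, all deterministic under the seed.
Its defaults emulate the evaluated study layout: **5 groups × 5
documents** drawing from a shared pool of **60** elements with a per-slot
reuse probability of **0.35** (which lands group-level reuse rates in the
20–40% band typical of real hospital document sets), about **30%** of each
group's unique elements gathered into composites of three, and **12**
medical-history rows carrying a planted violation plan of two `required`,
two `dependent`, one `operated` and one `datatype` fault, each injected
into its own row so fault localization is testable.  The answer key
records the generator's own draws (counts per group, composite
assignments, planted fault counts); tests then require the engine and the
metrics to recover it exactly.

What the generator does *not* emulate: real corpora have skewed element
frequencies, semantically near-duplicate names that a human integrator
merges, and composites chosen by clinical meaning rather than first-seen
order.  Passing the recovery tests therefore demonstrates that the
counting and validation machinery is exact on known ground truth — not
that the package reproduces human integration judgment, which is an input
here, not an output.

## Numerical and design choices

* Ids match `[A-Za-z_][A-Za-z0-9_:.-]*`; a symbol ending in
  `.unit_of_measure` is attribute access, otherwise the whole token
  (dots included) is the id.
* Hybrid member order is significant and first-match-wins: deterministic
  resolution beats any attempt at "best" matching.
* A hybrid may not itself be variable; the combination is undefined in
  the source model and is rejected rather than guessed at.
* Dates/times are ISO 8601 (`YYYY-MM-DD`, `HH:MM`); entered units compare
  case-sensitively after trimming.
* Strict mode (default) errors on unknown record keys and unknown JSON
  keys; lenient mode downgrades both to warnings and treats unbound rule
  references as null, for partially filled forms.
* The medical-history end-date dependency follows its printed expression
  — `(IF (!= DE:44078 'Yes') DE:47619 NULL)`, i.e. an end date may only
  be present while the condition "ongoing = Yes" holds — even though one
  could argue the clinical polarity reads the other way; the expression,
  not the prose around it, is normative here.
* One worked example in the specification this package was built against
  expects an indeterminate outcome for a dependent condition in which the
  other disjunct is decidedly true; under the Kleene semantics adopted
  throughout (`true or indeterminate = true`) that condition is true and
  the dependent error fires.  The package follows the logic, not the
  example.

## Problem sizes used in the checks

The shipped test-and-acceptance workload was sized to stay small while
exercising every path: 1,000 random arithmetic expressions against a
brute-force oracle, 100-expression parse/unparse round-trip batches,
20-seed fixture answer-key recovery (each fixture: 25 documents, ~300
occurrences, 12 record rows), and exhaustive boundary grids over every
dictionary range.  All statistics recomputed from published document
counts are exact integer arithmetic and independent of any seed.

## Limitations

The registry covers neither the full 11179 administered-item lifecycle
(versioning, stewardship, registration status) nor terminology-service
resolution; dictionary versioning with time-stamped ranges is explicitly
out of scope.  Composite membership is flat; corpora are counted, not
semantically matched; and the validation engine checks records against
declared structure — it cannot tell a well-structured wrong answer from a
right one.
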