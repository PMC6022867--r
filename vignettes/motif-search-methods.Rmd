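---
title: "Catalytic-centre motif search: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catalytic-centre motif search: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acscan)
```

## The model

A search motif is an ordered list of elements, each either a *residue
class* (one residue drawn from an explicit set, e.g. `[RKS]`) or a
*bounded wildcard gap* `X{m,n}` (between m and n arbitrary residues).
Matching is exact set membership — there is no scoring, no mismatch
tolerance, and no position weighting. This is deliberate: the motif family
encodes hard biochemical requirements (a hydrogen-bonding residue at
position 1, substrate specificity at position 3 — `[DE]` for ATP, `[CTGH]`
for GTP — a transition-state stabilizing `[KR]` at position 14, and a
metal-binding `[DE]` one to three residues downstream), and the screening
question is "which proteins satisfy all of them", not "which score
highest". Candidate centres found this way are *moonlighting* sites: short
catalytic centres embedded in proteins whose primary annotated function —
ion transport, receptor kinase signalling, clathrin assembly — is
something else, which is why whole-proteome pattern screens rather than
domain-homology searches are the appropriate tool.

Two position numberings coexist and are both exposed. The *element index*
addresses the element list (the `[DE]` of the core AC motif is element 3).
The *expanded motif position* counts residues over the minimal
instantiation (gaps at their minimum length), which is the numbering used
when one says the transition-state residue sits "at position 14" of a
14-residue motif; `expanded_position()` and `role_position()` convert.
Derivation operators use whichever the operation naturally needs:
`substitute_position()` takes an element index, `constrain_wildcard()` an
expanded position.

### The preset family and its derivations

All presets derive from the GC parent by three operators, and the package
tests assert these identities structurally:

* `ac_core = substitute_position(gc_core, 3, "[DE]")` — a single
  substitution at the substrate-specificity position converts a GC search
  motif into an AC one.
* `ac_fv5 = constrain_wildcard(ac_core, 5, "[FV]")` — fixing a gap
  position can only shrink the hit set (tested as a set inclusion).
* `ac_anchored = add_upstream_anchor(ac_core, "R", 5, 20)` — an upstream
  arginine filter, implicated in pyrophosphate binding.

`ac_kr15` (`[R]X{5,20}[RKS][YFW][DE][VIL]X{8}[KR][KR]X{0,2}[DE]`) is
stored verbatim rather than derived: its printed form shortens the core
gap to `X{8}` and doubles the `[KR]`, which is not the result of any
single well-defined insertion into `ac_core`, so deriving it would invent
structure the published pattern does not have. Two related printing
quirks are worth knowing: the anchored pattern `[R]X{5,20}` places the
arginine 6–21 residues upstream of position 1 even though the
accompanying prose says "between the 5th and 20th aa upstream", and the
`ac_kr15` gap shift puts its doubled `[KR]` at expanded positions 13–14
of the core rather than 14–15. In both cases the printed pattern is
implemented, because that is what a reader would paste into a scanner.

### Canonical serialization

`motif_to_string()` sorts residues inside brackets alphabetically, writes
single-residue classes bare, emits `X{n}` only for n > 1, and merges
adjacent fixed wildcard gaps on construction (`XX{3}X` becomes `X{5}`).
Canonicalization makes round-trip identity (`parse(serialize(m)) = m`)
and structural equality well defined; both are property-tested on random
motifs.

## The scanner

`find_matches()` reports **every** distinct (start, end) span admitting an
element assignment — overlapping spans, and several spans per start when
the variable gaps allow different total lengths. Per-protein *presence*
(not match count) drives proteome hit counts, since a screening list
counts candidate proteins, not sites. Implementation: each motif expands
into its finite set of fixed gap-length layouts (the published motifs
expand to at most 48), and each layout is tested with vectorized
cumulative-sum masks, so scanning is linear in sequence length per layout.
A hard cap of 1e5 layouts guards against pathological patterns. For each
span a single witness assignment is kept: the lexicographically smallest
gap-length vector, a deterministic tie-break.

Conservative matching rules: named classes match only their own residues;
ambiguity codes (B, J, Z, U, O, X) never satisfy a named class; wildcard
positions accept any letter but never `*`; sequences are upper-cased and
one trailing stop is stripped at load. These choices can only deflate, not
inflate, proteome counts. Coordinates are 1-based inclusive everywhere a
user sees them. Isoform handling is explicit: default counts are per FASTA
record, and `collapse_isoforms = TRUE` truncates ids at the first `.`
(`AT1G68110.1` → `AT1G68110`) to count distinct loci, since published
counts rarely state which convention a proteome release used.

The test suite validates the scanner against an *independent* oracle: a
recursive backtracking matcher that shares no code or strategy with the
layout-enumeration implementation. The acceptance suite runs the
equivalence on 1,000 random sequences (length 50–500) for all six presets;
exact span-set agreement is required.

## The background model

`start_probability()` is the union bound: the sum over gap layouts of the
product of class frequencies (wildcards contribute 1). Summing over
layouts over-counts sequences matched by more than one layout, so the
value is an upper bound; exact inclusion–exclusion across up to 48
partially overlapping layouts would add complexity for a correction that
is O(p²) at the p ≈ 1e-5 probabilities involved. The tests therefore
check the bound two ways: exact equality of the closed form on
hand-derived cases, and Monte-Carlo agreement with an inclusion–exclusion
value computed independently in the test. `expected_hits()` applies the
edge correction (a record of length L offers L − max_span + 1 starts) and
treats starts as independent for the per-record hit probability — a good
approximation because p · max_span ≪ 1 in any realistic proteome screen.

## What the simulator emulates — and what it does not

`generate_proteome()` draws i.i.d. residues (default uniform; any
composition, including degenerate ones, is accepted) with record lengths
from a geometric distribution shifted to a 50-aa floor around the
requested mean (default 400 aa, a typical plant proteome scale; the
specific length law is immaterial to every property tested and was chosen
for simplicity). `plant_motifs()` inserts sampled instantiations by
*substitution* — overwriting background residues — so record lengths and
all downstream coordinates stay fixed, which keeps the truth table exact.
Real proteomes are not i.i.d.: they have compositional bias, repeats, and
homologous families. A green planted-recovery test therefore establishes
scanner correctness (recall 1 by construction, zero false-positive
records in backgrounds lacking the position-1 residues R/K/S, chance hits
within binomial error of the closed form in uniform backgrounds) — it
does not establish that a real proteome count has any particular split
between true and chance hits.

`generate_expression()` builds a latent standard-normal signal (the query
gene) and mixes each target gene as `r·signal + sqrt(1−r²)·noise`. The
noise vector is orthogonalized against the realized signal before mixing
(the empirical-covariance construction familiar from
`MASS::mvrnorm(empirical = TRUE)`), so the designed correlation is the
*sample* correlation, exact at any sample size — without this, the
sampling cross-term makes a ±0.1 recovery band at n = 200 only a ~1.4 σ
statement, and a validation test would measure the generator's luck
rather than the ranker's correctness. Latents map affinely to intensities
(`base_mean + noise_sd · value`, defaults 100 ± 10, a microarray-like
scale); affine maps preserve Pearson correlations exactly, and the 10 σ
positivity guard effectively never triggers. Fold inductions multiply one
gene's intensities in one condition's samples, matching the
group-mean-ratio definition used by `log2_fold_change()`. The generator
does not emulate mean–variance dependence, batch effects, or
condition-correlated structure.

## Co-expression choices

Correlation is computed across **all** samples with no condition
stratification, the query gene is excluded from its own list
(self-correlation is uninformative), zero-variance genes are dropped with
a warning, and ties break by gene id for a deterministic ranking. The
default list size k = 200 mirrors the ECG200 convention. Fold change uses
group means of positive intensities and refuses non-positive means by
naming the offending gene — silent pseudocounting hides exactly the
degenerate inputs a user needs to see. The published ECG lists were
produced by an unstated compendium and tool; this module implements the
generic Pearson definition only, so numeric agreement with any specific
published list is out of scope.

## Numerical and interface choices

* Union bound rather than inclusion–exclusion (above); documented upper
  bound.
* Degenerate inputs: empty sequences and empty FASTA files are valid and
  yield zero counts; duplicate FASTA ids are suffix-deduplicated with a
  warning; zero-length records are skipped with a warning; unreadable
  files are errors.
* The preset catalogue and CLI configuration use JSON (jsonlite) rather
  than YAML: no YAML parser is available in the supported dependency set,
  and the catalogue structure (name, pattern, role map, provenance) is
  format-agnostic. Config-file keys are strictly validated; flags win
  over config values. Exit codes: 0 ok, 1 usage error, 2 data error.
* All generators take explicit seeds and restore the caller's RNG state;
  every simulation in the package is bit-reproducible given its seed.

## Known limitations

* Proteome count reproduction against the TAIR10 representative protein
  set requires that FASTA locally (`data-local/
  TAIR10_pep_representative.fasta`); it cannot be bundled, so the
  corresponding acceptance test fails in offline environments by design.
  Counts are release- and isoform-set-sensitive, hence the dual
  record/locus counting modes and a ±10% band rather than exact equality
  for differing releases.
* Exact class matching cannot find centres with conservative
  substitutions outside the written classes; that is a property of the
  motif family, not of the implementation.
* No nucleotide scanning, six-frame translation, PWM scoring, motif
  discovery, or GO enrichment.
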