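---
title: "Evaluating prokaryotic gene calls with peptide evidence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating prokaryotic gene calls with peptide evidence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progeval)
```

# Overview

`progeval` evaluates prokaryotic structural annotation — the placement of
protein-coding gene boundaries — against mass-spectrometry peptide
identifications. Peptides are direct evidence of translation: where a
peptide maps on the genome, in which reading frame, and how it sits
relative to a gene call either supports the call or witnesses a specific
kind of annotation error. The package implements the complete evaluation:
exact unique six-frame peptide mapping, support/conflict accounting,
wrong/short/missed error classification with an evidence threshold,
pseudogene re-scoring, multi-caller consensus statistics, and a seeded
synthetic-data generator that makes the whole pipeline testable end to end.

This vignette explains the model, its assumptions, the tunable parameters,
the numerical conventions, and the design decisions taken where the
procedure was genuinely open.

# Peptide mapping

Peptides are matched **exactly** (character equality; isoleucine and
leucine are distinct) against the six translated frames of every replicon,
under genetic code 11 with plain codon lookup (no initiator special-casing,
so GTG codons inside a frame read V, not M). A peptide is kept only when
its sequence occurs **exactly once** across all frames of *all* replicons;
several occurrences discard it as ambiguous, none as unmatched. The
mapping report partitions the input: `n_input = n_mapped + n_ambiguous +
n_unmatched`.

Choices worth stating:

* **Uniqueness scope is the whole input genome**, not per replicon —
  "unique" is otherwise ill-defined for multi-replicon organisms.
* **I/L are not equivalenced.** Isobaric merging would only create more
  ambiguity; exact matching is the stricter, more conservative choice.
* Codons containing `N` translate to `X`, and `X` never matches a peptide
  residue, so no peptide maps across undetermined sequence.
* Peptides shorter than 6 aa are processed normally but counted in the
  report as high ambiguity risk.
* Peptides that arrive with precomputed coordinates are validated by
  re-translating the claimed interval; failures are demoted to unmatched
  rather than trusted.

Coordinates are 0-based half-open internally and converted to GFF3's
1-based inclusive convention only at file boundaries. Reading frames are
intrinsic to the strand-oriented reading: on `+` the frame of an interval
is `start mod 3`; on `-` it is `(L - end) mod 3` for replicon length `L`.
Two same-strand features are co-framed exactly when their labels agree,
which makes peptide-versus-call frame comparison well defined on both
strands.

# Support, conflicts, and error categories

A mapped peptide **supports** a call when it falls wholly inside one of the
call's CDS fragments *and* matches that fragment's strand and frame. Frame
agreement matters: a peptide wholly inside a call's span but translated in
a different frame is evidence against the call, not for it — spatial
containment alone would make the "wrong" category undetectable. Gene
coverage is the percentage of calls with at least one supporting peptide.

Every non-supporting mapped peptide is a **conflict**, labelled
`extends_upstream` (in frame with an overlapped call, starting 5' of its
start), `spans_boundary` (in frame but running past the 3' end, or lying
in the gap between a disrupted call's fragments), `overlaps_out_of_frame`,
or `outside_all`. Classification then applies three rules, each requiring
at least `min_support = 2` **non-redundant** peptides — peptides count
once per distinct genomic interval, because re-observations of the same
spectrum are not independent evidence while overlapping distinct tryptic
peptides are:

* **wrong** — a call overlapped by peptides that share a strand and frame
  different from the call's. If several peptide frame groups conflict with
  one call, the largest group is scored (one error per call).
* **short** — in-frame peptides whose start lies 5' of the call's start,
  each within the call's *maximal in-frame upstream ORF extension*: a
  peptide separated from the annotated start by an in-frame stop cannot
  belong to the same protein and is excluded. The implied interval extends
  the call to the 5'-most supporting peptide. A peptide may satisfy this
  for a call it does not overlap (a truncation deeper than the peptide
  itself); such `outside_all` peptides are assigned to the nearest
  qualifying call as short evidence rather than treated as a separate
  gene.
* **missed** — remaining `outside_all` peptides grouped by the maximal
  stop-to-stop ORF that contains them, provided that ORF contains no
  in-frame call. The implied gene is reported as the whole ORF, since the
  true start is unknowable from peptides alone.

These rules make the categories mutually exclusive per caller: a conflict
peptide feeds at most one error call. `spans_boundary` conflicts are
recorded but feed no category — 3' extensions have no error type in this
framework, and gap-spanning peptides of disrupted genes must not generate
spurious errors.

**Pseudogene re-scoring.** Post-processors retain the coordinates of all
CDS fragments of genes they disrupt. A pseudogene-tagged call whose
fragments contain at least `min_support` confirming in-frame peptides is
re-scored as a **missed** gene — the peptides show the locus produces a
real protein, so calling it a pseudogene removed a real gene from the
annotation. An *untagged* multi-fragment (frameshifted) call with
confirming peptides is a good call, and any error previously recorded
against it is withdrawn. Peptides confirming pseudogene fragments are
never double-counted in other categories.

**Evidence arithmetic.** With per-peptide false identification rate `q`,
the probability that `k` independent supporting peptides are all false is
`q^k` (`joint_false_rate()`). At the defaults `q = 0.003`, `k = 2` this is
9e-06 — comfortably below the 0.09 % working bound often quoted for the
two-peptide rule, which the package treats as an upper bound rather than
an identity (the product rule gives a much smaller number).

# Caller comparison

Two calls are **identical** only when replicon, strand, start and stop all
coincide. **Stop-consensus** pairs share the 3'-terminal coordinate on the
coding strand — the `end` boundary of a `+` call, the `start` boundary of
a `-` call — but differ in start; this set is disjoint from the identical
set. The strand-aware definition matters: "varies only in the start codon"
is ill-defined without it. Because caller output dialects differ on
whether the stop codon is inside the reported interval, comparisons assume
stop-inclusive intervals; inputs in the stop-exclusive dialect should be
normalized at read time. `consensus_summary()` reports pairwise and
all-way identical and stop-consensus counts, per-caller unique calls, and
percentages under each caller's own total (the natural dual-denominator
presentation for asymmetric call counts).

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not any particular organism:

* **Replicons** (`sim_params()`): genes of Normal-distributed length
  (default mean 900 nt, sd 200, floored at 150 nt and rounded to codons)
  are placed non-overlapping on random strands with Normal intergenic gaps
  (default mean 150 nt, sd 50, floored at 30). Defaults build a 100 kb,
  80-gene replicon at GC 57.7 % — the mean GC of the kind of
  high-GC-biased genome panels these evaluations are typically run on; the
  generator accepts 25–75 %. Each gene is an ATG start, a stop-free run of
  sense codons, and a stop. Codon composition is tuned by per-base GC
  sampling with stop-codon rejection, compensated for the fixed AT-rich
  elements so realized GC lands within about 2 points of target at 100 kb.
* **Frame closure:** every intergenic gap carries a 12 nt cassette
  (`TTAATTAATTAA`) containing a stop codon in all six frames regardless of
  phase (it is its own reverse complement). This guarantees that maximal
  ORFs never bridge two genes, so planted missed genes are separable by
  construction instead of by luck.
* **Peptide evidence** (`sample_peptides()`): per gene, expression is
  Bernoulli(`p_gene_expressed`, default 0.4 — matching the roughly 40 %
  gene coverage observed in large proteogenomic compilations); each
  tryptic peptide (cleave after K/R, not before P) within the length
  window (default 6–50 aa) is detected with `p_peptide_detected` (default
  0.5, a middling instrument). False identifications are planted at
  `false_match_rate` (default 0.003) as out-of-frame or intergenic genomic
  substrings, rejection-sampled to map uniquely and to not sit in-frame
  inside a real gene — so they exercise the false-discovery pathway, not
  the ambiguity discard, and the two failure modes stay separated in
  tests.
* **Caller perturbation** (`perturb_calls()`): at most one event per gene —
  deletion (expected **missed**), start truncation in frame by at least
  9 nt (expected **short**), replacement by a frame-shifted call over the
  same locus (expected **wrong**; a spurious wrong-frame call *added*
  next to a retained true call would be undetectable, because the true
  call's peptides would support it and conflicts are defined as the
  non-supporting peptides), or splitting into retained fragments with an
  optional pseudogene tag (tagged: expected **missed** after re-scoring;
  untagged: expected good call). Every deviation is recorded in a ledger
  with its expected category. Exact event counts can be requested, in
  which case genes are drawn from those whose tryptic peptide complement
  guarantees detectability at the two-peptide threshold; the anchoring
  evidence peptides are required to be at least 7–8 aa, since shorter
  peptides have an appreciable chance of a second six-frame occurrence
  (which would discard them as ambiguous and starve the planted error).
  Truncation points sit just past the second upstream peptide start plus a
  small random codon offset, so two distinct peptides always extend
  upstream of a planted short call under saturating detection.

Everything is deterministic given the seed; `make_benchmark()` writes a
self-contained bundle (FASTA, per-caller GFF3, peptide TSV, ledgers) that
reproduces byte-for-byte under the same seed.

**What the generator does not emulate:** ribosome binding sites, promoter
structure, codon usage bias beyond GC, operon structure, signal-peptide
cleavage, hydrophobicity-dependent detectability, spectrum-level effects,
or the per-genome peptide-count bias of heterogeneous data compilations
(expression enters only through `p_gene_expressed`). Passing tests
therefore demonstrate the correctness of the *evaluation logic* under the
stated statistical assumptions, not gene-caller performance on real
genomes; on real data the short-call rate in particular is biased by
unobservable "too long" errors and alternative initiation sites.

# Numerical and degenerate-input conventions

* ORFs are the maximal stop-free codon runs themselves (stops excluded,
  sequence edges count as boundaries); `find_orfs()` defaults to the 39 nt
  biological floor (the shortest experimentally validated CDS), with the
  common caller defaults (90/81/120 nt) available by argument.
  `has_start_codon` reports an in-frame ATG/GTG/TTG anywhere in the run.
* An empty call set yields zero coverage and makes every mapped peptide a
  conflict; an empty peptide file is a warning plus an empty result, and
  an all-zero mapping report.
* Ties: a conflict peptide overlapping several calls takes the relation of
  highest specificity (`extends_upstream` over `spans_boundary` over
  `overlaps_out_of_frame`); an upstream peptide qualifying for several
  calls is assigned to the nearest; several duplicate-stop calls within
  one caller pair off at most once, in coordinate order.
* `gene_call_set()` rejects duplicate (replicon, strand, start, end)
  calls, overlapping fragments, and empty intervals at construction, so
  downstream code never re-validates.
* Spearman correlations in `bias_report()` are defined as 0 when either
  margin is constant (ranks carry no information), rather than `NA`.

# Problem sizes in the test suite

The suite verifies the mapper against a naive all-positions six-frame scan
on 20 random replicons of 10–25 kb; recovers 33 planted errors exactly on
a 100 kb, 80-gene noiseless benchmark; checks consensus fractions against
the closed form `(1 - p)^2` and coverage against its 99 % binomial band on
200-gene replicons (~220 kb); and exercises translation and ORF
enumeration against independent oracles (seqinr translation, exhaustive
frame scans) on smaller sequences. These sizes give the statistical checks
3-sigma headroom while keeping the default run brisk.

# Limitations

Peptide evidence is one-sided: it can confirm translation but never deny
it, so false-positive calls and "too long" starts are undetectable by
construction and are deliberately out of scope. Homology verification of
error calls (BLASTp, conserved-domain checks) is likewise out of scope;
error tables carry the supporting peptides so such verification can be
layered on. The evaluation trusts the per-peptide FDR it is given — it
performs no decoy-based FDR estimation of its own.
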