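---
title: "Mining sequence patterns around cis non-proline peptide bonds"
author: "cisPatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining sequence patterns around cis non-proline peptide bonds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisPatterns)
```

## The problem

The backbone amide bond adopts two conformations distinguished by the
omega dihedral: *trans* (omega near 180°) and *cis* (omega near 0°).
Cis bonds preceding proline are uncommon; cis bonds at any *other*
residue are rare enough (on the order of 0.03% of amide bonds) that a
dataset of them is drowned by five to six orders of magnitude more trans
examples. Yet they matter: the strained cis geometry is repeatedly found
at active sites and binding interfaces. `cisPatterns` asks a deliberately
interpretable question: *which short, possibly degenerate sequence
patterns describe the neighbourhoods of cis non-proline bonds and almost
never occur around trans bonds?*

The package consumes sequences plus per-bond omega angles; it never
computes dihedrals from coordinates. Any structure-annotation tool that
emits omega angles can feed it.

## Window construction

A bond linking residues $i-1$ and $i$ is attributed to residue $i$; its
window is the 11-mer $[i-5, i+5]$. Classification uses omega normalised
to $(-180, 180]$: CIS iff $|\omega| \le 30°$, TRANS iff
$|\omega| \ge 150°$, with inclusive boundaries; anything else (distorted
bonds) is ignored. Four exclusion rules apply, each counted separately:

* windows that would cross a chain terminus (centre closer than 6
  positions to either end);
* bonds whose bond-bearing residue is proline — "non-proline" is a
  property of residue $i$, the C-terminal partner of the bond;
* windows containing a non-standard letter (X, B, Z, U, O): the window
  is invalidated, not the chain;
* trans windows whose centre lies within 5 positions of *any*
  cis-classified bond centre in the same chain, so the trans set never
  contains sequence shared with a cis neighbourhood. We use all
  cis-classified centres (including cis-prolines) as the guard — the
  stricter reading; with typical cis rarity the difference is a handful
  of windows.

Chains are treated independently; we make no attempt to bridge chain
breaks or reconcile multi-chain structures, since the omega table is the
caller's responsibility.

## Maximal pattern discovery

Patterns are sequences of elements — a residue literal, an equivalency
class such as `[DE]`, or the wildcard `.` — that never start or end with
a wildcard. Discovery enumerates every pattern with

* length $\le W$ (default 11, the window width),
* at least $L$ literals (default 3; classes count as literals),
* support $\ge K$ (default 2), where support is the number of *distinct*
  windows matched — a window with two occurrences counts once, because
  all downstream scoring operates on sets of matched regions, not
  occurrence counts,

and then keeps only the *maximal* ones: a pattern is discarded iff some
strictly more specific pattern — a wildcard specialised to a class or
literal, a class specialised to a member literal, or the pattern extended
at either end within the length bound — matches exactly the same set of
windows. Since specialisation can only shrink a support set, maximality
reduces to a subsumption check within groups of equal support set, which
is how both the production implementation (depth-first rightward
extension of occurrence lists with support pruning) and the independent
exhaustive oracle (`bruteForceDiscover()`, candidate generation from the
windows themselves) implement it. The two implementations share nothing
but the element definitions, and the test suite requires them to agree
exactly on hundreds of random tiny instances.

Two equivalency alphabets ship with the package: a chemical grouping
(`[AG] [DE] [FY] [KR] [ILMV] [QN] [ST]`) and a structural grouping
(`[CS] [DLN] [EQ] [FHWY] [ITV] [KMR]`). When an alphabet is active its
class symbols simply compete with the literals during enumeration;
letters outside every group (P and W in the chemical alphabet) can only
appear as literals. Output order is descending support, then
lexicographic — discovery is fully deterministic.

## Propensity scoring

With $c$ cis matches, $t$ trans matches, and dataset sizes
$|CNP|, |TNP|$:

$$ sc(P) = \frac{c}{c + norm \cdot t}, \qquad norm = \frac{|CNP|}{|TNP|}. $$

The normalising factor makes the score comparable under extreme class
imbalance without subsampling the trans set: $sc = 1$ iff $t = 0$,
$sc = 0.5$ when the pattern's representation is exactly proportional to
the dataset sizes, and the score is strictly monotone in both counts.
This algebraic form is the simplest ratio with those three properties;
it is isolated in `scScore()` so an alternative could be swapped in
without touching anything else. Filtering keeps patterns with
$sc > 0.90$ — strictly greater, so a pattern sitting exactly at the
threshold is discarded.

Each pattern also receives a base-10 log-likelihood: the probability
that a random string of the pattern's length, drawn from a Markov
background model of order 0–2, matches it at a fixed offset. The dynamic
programme sums over class members and all 20 residues at wildcards and
equals exhaustive enumeration to within $10^{-9}$ (tested). Background
models are fitted from any user corpus with add-one smoothing, so unseen
contexts still carry proper distributions; lower-order tables serve the
first positions of a string. Absolute log-likelihood values depend
entirely on the corpus supplied, so only comparisons within one
background are meaningful.

## Non-redundant selection

Discovery output is heavily overlapping. Selection sorts patterns by
descending score — ties broken by larger cis count, then more literals,
then lexicographic pattern, making the greedy pass deterministic (ties
at $sc = 1$ are common) — and lets each pattern claim the not-yet-claimed
cis *and* trans windows it matches. A pattern claiming no new cis window
is dropped. The pass stops at 100% cis coverage or list exhaustion. The
result is a 1-N pattern-to-window relationship: each window belongs to at
most one pattern. Coverage is the percentage of cis windows claimed; the
false discovery rate is the percentage of *distinct* trans windows
claimed (trans windows are claimed uniquely too, so FDR counts windows,
not raw match events).

## Pattern-based classification

The classifier protocol: split the cis set into training
(round-half-up of $2/3 \cdot n$) and test; draw an equal-size trans
control for training, sampled without replacement; run
discovery → scoring → filtering → selection on the training data only;
call a test window *cis* iff any retained pattern matches it. Trans test
sets of the cis-test size are resampled 5 times from the trans windows
*excluding* the training control (a strict no-leakage choice; resamples
are drawn independently, so they may overlap each other but never the
control). Sensitivity is computed once on the cis test set; specificity
and accuracy are computed per resample and averaged — the averaged values
equal the mean of the per-resample values by construction, and this
per-resample-then-average convention is asserted in the tests. All
randomness flows from a single integer seed.

## Motif-library comparison

Retained patterns are compared against a user-supplied library of
functional motifs (TSV: id, pattern, class among TRG/MOD/LIG/CLV, GO
terms). The supported pattern dialect is literals, `.`, classes and
negated classes; library entries using quantifiers, anchors or
alternation are skipped with a warning rather than half-interpreted.

The comparison slides one pattern over the other and scores each overlap
by shared information content: an element allowing $s$ of the 20
residues has $IC = 1 - \log(s)/\log(20)$ (1 for a literal, 0 for the
wildcard); an aligned non-wildcard pair contributes
$\min(IC_q, IC_m)$ if the two allowed sets intersect, and vetoes the
offset entirely if they do not. A hit requires at least `min_shared`
(default 3) compatible non-wildcard pairs; `CM_score` is the best
qualifying offset's sum. The score is symmetric and self-maximal, both
property-tested. This is a deliberately simple information-content
formulation; it is not calibrated against any external tool's scale.

For the class profile, a query pattern counts at most once per
functional class however many same-class motifs it hits (one pattern may
still feed several classes). The profile is tested against the library's
class composition by a chi-square goodness-of-fit test with
$df = 3$ at $\alpha = 0.01$. Class compositions are usually quoted as
rounded percentages — the default TRG 13 / MOD 25 / LIG 54 / CLV 7 sums
to 99% — so `motifEnrichment()` accepts fraction vectors within 0.05 of
a unit sum and renormalises; observed counts exactly proportional to the
quoted fractions still yield $\chi^2 = 0$ exactly, because the
proportionality constant cancels.

## The synthetic generator

`synthSpec()`/`generateSynthetic()` emulate the structure of the real
mining problem: a large trans set drawn i.i.d. from a residue background
(uniform by default, or any fitted Markov model) and a small cis set in
which each planted degenerate motif is instantiated — class positions to
a uniform member, wildcards to a background draw — at a uniform random
offset in its share of windows, with optional per-position corruption
noise. At most one motif is planted per window. In the default *clean*
mode the trans windows are rejection-sampled until no planted pattern
matches any of them, giving a known-zero false positive floor; the
*natural* mode skips rejection to exercise nonzero-FDR paths.

What the generator does **not** emulate: positional composition biases
of real bond neighbourhoods (e.g. glycine enrichment at the bond
position), homology between windows, correlated flanks, or realistic
omega distributions. Passing tests on synthetic data therefore
demonstrate the machinery — recovery of planted signal, exact
bookkeeping, determinism — not biological performance; on real data,
patterns are weaker and classifier metrics are far from the clean-mode
100%.

Test and verification problem sizes were chosen to make every check
exact and fast: discovery-vs-oracle equivalence uses hundreds of random
instances of up to 6 windows of length up to 7 over reduced alphabets
(the oracle is exponential by design); the end-to-end recovery study
uses 20 cis / 2000 trans windows with two planted motifs covering all
cis windows; the log-likelihood oracle sweep covers every pattern of
length up to 4 over a 6-letter alphabet.

## Numerical and edge-case choices

* Omega normalisation maps any finite angle into $(-180, 180]$ before
  classification; classification is periodic with period 360° (tested).
* `round(2/3 · n)` uses round-half-up, so a 3-window cis set splits 2/1.
* Degenerate inputs fail loudly: empty region sets for frequency tables,
  out-of-bounds bond indices (named protein and index), non-finite
  omegas, malformed TSV rows (reported with line numbers), pattern
  residues absent from a background model's alphabet.
* An empty pattern list is a valid classifier: it predicts everything
  trans (sensitivity 0, specificity 100 on balanced sets).
* Pattern matching compiles to PCRE substring search; results equal the
  naive positional scan by construction of the element tokens, and
  matching a retained list against $10^5$–$10^6$ windows is a vectorised
  `grepl` per pattern.

## Known limitations

* Discovery enumerates all maximal patterns; its cost grows with window
  count and alphabet richness. It is comfortable at the few-hundred-cis
  scale the method targets; it is not a general-purpose motif miner for
  thousands of long sequences.
* The propensity score's algebraic form is a reconstruction from its
  stated properties (range, neutral point, normalisation); `scScore()`
  isolates it for that reason.
* CM_score values are on this package's own scale and not comparable to
  other motif-comparison tools.
* The FDR here is a claimed-window rate under a specific greedy
  selection, not a multiple-testing-corrected error rate.
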