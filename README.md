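# cisPatterns

Most peptide bonds in folded proteins are *trans* (omega dihedral near
180°); *cis* bonds at non-proline residues are exceedingly rare (roughly
0.03% of amide bonds) and tend to sit at functionally strained spots —
active sites, ligand-binding pockets. `cisPatterns` is an R package for
mining regular-expression-type sequence patterns that describe the
neighbourhoods of such *cis* non-proline bonds, for structural
bioinformaticians who have per-bond omega annotations (from any dihedral
annotation tool) and want interpretable sequence descriptors rather than a
black-box predictor.

## What it computes

Starting from protein chains and a table of omega dihedrals, the package:

1. **Builds labelled windows.** A bond between residues *i−1* and *i* is
   attributed to residue *i* and classified CIS (|omega| ≤ 30°) or TRANS
   (omega within 30° of 180°). Each usable bond yields the 11-mer
   `chain[i−5 .. i+5]`; windows crossing a terminus, centred on proline,
   containing non-standard letters, or (for trans) overlapping a cis bond
   centre are excluded. The two sets are called CNP (cis-nonPro) and TNP
   (trans-nonPro).
2. **Discovers maximal patterns** in the CNP windows: every pattern built
   from residue literals, the `.` wildcard and — optionally — chemical
   (`[AG] [DE] [FY] [KR] [ILMV] [QN] [ST]`) or structural
   (`[CS] [DLN] [EQ] [FHWY] [ITV] [KMR]`) equivalency classes, with length
   ≤ W (11), at least L (3) literals and support ≥ K (2) distinct windows,
   keeping only patterns that cannot be specialised or extended without
   losing support (TEIRESIAS-style maximality).
3. **Scores cis propensity.** For a pattern with *c* cis and *t* trans
   matches,

   ```
   sc(P) = c / (c + norm · t),    norm = |CNP| / |TNP|
   ```

   so 1 means "never seen in trans", 0.5 means representation exactly
   proportional to the dataset sizes. Patterns with `sc > 0.90` are kept.
   A base-10 log-likelihood under an order-0/1/2 Markov background model
   quantifies how generic each pattern is.
4. **Selects a non-redundant set** greedily by descending score: each
   pattern claims the still-unclaimed windows it matches, so every window
   is assigned to at most one pattern. Reported are the coverage (% of
   CNP claimed) and the false discovery rate (% of TNP claimed).
5. **Classifies held-out windows**: a window is called *cis* iff any
   retained pattern matches it, evaluated under a 2/3 train / 1/3 test
   split with an equal-size trans control and 5 resampled trans test
   sets (sensitivity / specificity / accuracy, averaged over resamples).
6. **Compares retained patterns to a motif library** (ELM-like TSV with
   TRG/MOD/LIG/CLV classes): a sliding-window alignment scores each
   overlap by shared information content (`CM_score`), and a chi-square
   goodness-of-fit test checks the recovered class profile against the
   library's class composition (default TRG 13%, MOD 25%, LIG 54%,
   CLV 7%, α = 0.01).

A synthetic-data generator (`synthSpec()` / `generateSynthetic()`) plants
degenerate motifs into cis windows over a Markov background with known
ground truth, so the whole pipeline is testable without any structural
data.

## Worked example

```r
library(cisPatterns)

spec <- synthSpec(20, 2000,
                  planted = list(list(pattern = "AD[DE]AT", fraction = 0.5),
                                 list(pattern = "W.HKY", fraction = 0.5)),
                  noise = 0, clean = TRUE, seed = 42)
d <- generateSynthetic(spec)

ps <- discoverPatterns(d$cnp, W = 11, L = 3, K = 2)
ps
#> PatternSet: 30 pattern(s), alphabet 'none'
#>   AD.AT                support 10
#>   W.HKY                support 10
#>   ADDAT                support 5
#>   ADEAT                support 5
#>   ...

scored <- scorePatterns(ps, d$cnp, d$tnp)
sel <- selectNonredundant(filterPatterns(scored, 0.90), d$cnp, d$tnp)
retainedPatterns(sel)
#>   pattern  c t sc_score claimed_cis claimed_trans
#> 1   AD.AT 10 0        1          10             0
#> 2   W.HKY 10 0        1          10             0

cls <- runClassification(d$cnp, d$tnp, seed = 42)
#> sensitivity 100.0%  specificity 100.0%  accuracy 100.0%
```

Both planted motifs are recovered (without an equivalency alphabet the
degenerate `[DE]` position surfaces as the wildcard in `AD.AT`, the
maximal pattern shared by all ten carriers; running with
`alphabet = "chemical"` recovers `AD[DE]AT` itself). Both score 1 —
never matching any of the 2000 background trans windows — and together
they claim all 20 cis windows: coverage 100%, FDR 0%. On held-out data
the pattern matcher separates the classes perfectly under these clean,
noise-free conditions.

A command-line front-end for every stage ships in
`inst/cli/cispattern` (subcommands `extract`, `discover`, `evaluate`,
`select`, `classify`, `compare`, `simulate`, `pipeline`).

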