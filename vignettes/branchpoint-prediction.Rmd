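---
title: "Heuristic branch-point prediction: model, regions and scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heuristic branch-point prediction: model, regions and scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(bpsfinder)
```

## The problem

During pre-mRNA splicing the U2 snRNP base-pairs its GUAGUA motif with the
branch point sequence (BPS), a roughly seven-nucleotide intronic element
whose sixth position — usually an adenosine — forms the lariat bond with the
5' splice site. In yeast the BPS is the nearly invariant UACUAAC, perfectly
complementary to GUAGUA; in human introns the motif is highly degenerate and
experimentally verified branch points are scarce, so sequence conservation
alone pins the branch site poorly.

`bpsfinder` implements a heuristic predictor built on two ideas:

1. **Constrain the search space** using intron architecture. The branch
   point lies upstream of the polypyrimidine tract (PPT) and inside the AG
   exclusion zone (AGEZ), the AG-free region abutting the 3' splice site.
   Searching only this *shortened AGEZ* removes most decoys before any
   scoring happens.
2. **Score what biology scores.** Candidate heptamers are ranked by a
   position-specific log-frequency score plus the thermodynamic stability of
   the duplex that the candidate (minus the branch site) can form with
   GUAGUA, weighted by the branch-site nucleotide preference.

Throughout the package, coordinates are 3'ss-relative and negative:
position -1 is the last intron base (the G of the terminal AG). All the
field's distance conventions ("branch points concentrate at -18 to -32")
read off directly.

## Regions

**PPT.** A tract is a valid PPT when (i) both ends are pyrimidines; (ii) no
purine run exceeds two; (iii) every purine segment of length *l* is flanked
on each side by at least *l* pyrimidines totalling at least 4*l*; (iv)
T(GT)n stretches are allowed, i.e. their lone G's are exempt from rule
(iii); and (v) the tract is at least 9 nt long *or* contains at least five
T's (a disjunction, read literally). Among valid tracts the search keeps the
*maximal* ones — not extendable by one base into a still-valid tract — and
returns the one whose 3' end is closest to the 3'ss (ties: 3'-most start).

Two implementation notes. First, extending a valid tract by one pyrimidine
never invalidates it (every rule is monotone under pyrimidine extension), so
maximal candidates begin and end on complete pyrimidine runs; `find_ppt()`
therefore enumerates spans of whole pyrimidine segments rather than all
substrings. The test suite checks this reasoning against a literal
brute-force scan of every substring on thousands of random short sequences.
Second, flank counts in rule (iii) are the literal adjacent pyrimidine runs;
a neighbouring exempt T(GT)n stretch does not count toward a flank.

**AGEZ.** Scanning 5'-ward from position -13 (AGs wholly inside the last 12
nt are ignored — an AG with its A at -13 straddles the boundary and *does*
count), the first AG found defines the zone; the AGEZ runs from *L*
nucleotides upstream of that AG to the 3'ss, clamped at the intron start,
and covers the whole intron when no internal AG exists. *L* defaults to 9,
the operating point at which the scoring family peaks, and is restricted to
7–12.

**Shortened AGEZ.** Branch points avoid the pyrimidine-rich 3' end of the
PPT, so the search region ends immediately 5' of the PPT's maximal
all-pyrimidine suffix (just 5' of the whole PPT when the tract is purely
pyrimidine). No published formula defines this boundary precisely; the
suffix-run rule is one consistent reading, deliberately isolated in
`shorten_agez()` so it can be swapped. The PPT itself is sought within the
AGEZ core (defining AG to the 3'ss, without the L extension) — the search
window is likewise not pinned down by the literature, and the core is the
natural 3'-end context.

```{r regions}
introns <- simulate_introns(3, seed = 7)
locate_regions(introns)
```

## Scoring

For a heptamer $X$ with per-position relative frequencies $f_{i,x}$,

$$S = \sum_{i=1}^{7} \log_2 f_{i,X_i},$$

with $S = -\infty$ whenever some $f_{i,X_i} = 0$: zero frequencies are kept
as hard exclusions rather than smoothed with pseudocounts, because a
TNA-fixed matrix (T invariant at position 4, A at position 6) is *meant* to
restrict the search to TNA heptamers.

The full family adds the U2 duplex term:

$$S^{*} = S \;-\; \frac{\sum_{j=1}^{3} P_j \, BE(X/X_{k(j)}) \,
f_{k(j),X_{k(j)}}^{\,Q_j}}{\sum_{j=1}^{3} P_j}, \qquad k(j) = j + 4,$$

where $BE(X/X_k)$ is the co-fold minimum free energy (kcal/mol) of the
hexamer obtained by deleting position $k$ from $X$, duplexed with GUAGUA.
Stable duplexes have negative energies, so subtracting the term rewards
candidates that pair well with U2. With all $P_j = 0$ the term is dropped
and $S^{*} \equiv S$. The $j \to k$ mapping assigns one deleted position per
term; this is the only reading under which "score8 minus score0 equals
$BE(X/X_6)$" holds with a single active weight.

Fifteen named configurations ship in `inst/extdata/score_configs.tsv`. Two
are canonical: `score0` ($P = 0$, the pure PSSM) and `score8` ($P = (0,1,0)$,
$Q_2 = 1$ — the branch-site term only, the configuration that performs best
and is the default). The remaining thirteen are a systematic placeholder
family (the seven non-empty $P$ subsets at $Q = 0$ and at $Q = 1$): their
published assignments are not available in the main text we implement from,
so they are data, not code, and trivially editable. Note $Q_2$ is
unidentifiable on TNA-restricted data since $f_{6,A} = 1$ there.

**Candidate enumeration and selection.** One candidate per position $p$ in
the shortened AGEZ whose heptamer $[p-5, p+1]$ lies wholly inside the intron
(the *branch site* must be in-zone; the heptamer's tail may extend 3' of
it); heptamers containing N are never scored. The highest score wins; ties
break toward the 3'ss, where observed branch points concentrate. If every
candidate is excluded by zero frequencies, the candidate with the most
negative $BE(X/X_6)$ is returned with an `all_excluded` flag rather than no
answer.

## Binding energies

`build_energy_table()` computes all $4^6 = 4096$ hexamer/GUAGUA energies
once and scoring does table lookups; genome-scale runs never shell out per
candidate. Two backends:

* **cofold** (reference, default): one batch call to `RNAcofold` (ViennaRNA)
  with default parameters (37&nbsp;°C, Turner 2004).
* **nn** (built-in): a register-scan nearest-neighbor evaluator — the
  hexamer is slid along GUAGUA in all antiparallel registers, and the best
  contiguous helix of Watson–Crick/wobble pairs is summed from the Turner
  2004 stacking parameters plus duplex initiation (+4.10 kcal/mol) and
  terminal AU/GU penalties (+0.50). No bulges, internal loops or
  dangling-end terms.

A hexamer with no stable duplex is assigned 0 kcal/mol in either backend, so
the energy term vanishes gracefully. Under the register-scan model the
perfect complement UACUAC is provably minimal (a shifted register has at
most five pairs). Under full co-folding it is *not*: GCUACA reaches
-5.9 kcal/mol through a shifted five-pair helix with two C–G pairs, a G–U
wobble and dangling ends, below UACUAC's -4.5. The weaker property that does
hold for co-folding — no single-mismatch neighbor of UACUAC beats it — is
what the tests pin for that backend. This divergence is a fact about the
thermodynamic model, worth knowing if you swap parameter sets: predictions
can shift near score ties across ViennaRNA versions, which is why evaluation
reports record the backend label.

```{r energy}
tab <- build_energy_table("nn")
binding_energy("TACTAAC", 6, tab) # consensus minus branch site = UACUAC
```

## Evaluation and baselines

`evaluate_predictions()` scores a prediction correct when its position
matches *any* annotated branch site of that intron (annotations from
lariat-mapping experiments are often multiple), and reports
`100 * n_correct / n_introns` rounded to two decimals. Two literature-style
baselines are included: a Hamming-distance scan against the strict consensus
TACTAAC over a fixed 3'-terminal window (100 or 200 nt, terminal AG
included), and a PSSM argmax over the full, un-shortened AGEZ. Baseline ties
break toward the 3'ss, consistent with the main predictor — the original
methods' tie rules are not documented, which can move a comparison by about
one intron.

## Synthetic data: what it shows and what it cannot

`simulate_introns()` builds introns from the 3' end inward: terminal AG; a
T-rich pure-pyrimidine PPT (default 15 nt) ending one base before it; a
pyrimidine gap; the planted heptamer with its branch site at a chosen
position (default -25, inside the observed -18..-32 concentration); the
AGEZ-defining AG immediately upstream; decoy AGs in the background (default
two) at least 18 nt upstream of the defining AG; background at 40% GC,
intron-like. Two scrubbing passes make the architecture exact rather than
probable: any AG arising by chance in the AGEZ core is broken, and any
T-at-4/A-at-6 pattern at an in-zone position other than the planted branch
site is broken for every L up to 12. Identical seeds give identical FASTA
bytes.

Consequently, with the TNA-fixed matrix the planted heptamer is the *only*
finite-score candidate, and recovery on consensus fixtures is 100% by
construction — that property tests the region/enumeration/selection
machinery, not predictive power. The harder regime plants heptamers sampled
from the degenerate matrix; recovery there is partial (around 35–40% against
~10% for the Hamming baselines under the default conditions), and the energy
term does not help, because sampled heptamers — unlike real branch points —
are not selected for complementarity to U2. Synthetic fixtures also lack
real 5'ss context, nucleotide composition gradients and alternative 3'ss:
passing on them validates the mechanics and the contracts, not accuracy on
real introns. Accuracy claims belong to the benchmark protocol
(`benchmark_accuracy()`), which runs only when the published evaluation
datasets are dropped into `inst/extdata/supplementary/` (they are journal
supplementary material and not redistributed here; see
`?supplementary_status`).

The two bundled matrices are synthetic fixtures, labelled as such in their
filenames: `tna_synthetic` mirrors the *structure* of a TNA-restricted
verified set (two invariant positions contribute 4 of its ~5.1 total bits),
`degenerate_synthetic` the weak preferences of a large sequencing-derived
set (~1.1 bits). Neither is a transcription of a published table.

## Numerical and degenerate-input choices

* Matrix columns must sum to 1 within 1e-3 (then renormalized exactly);
  anything further off is rejected, as are negative entries.
* Information content is $2 + \sum_x f \log_2 f$ with $0 \log 0 = 0$ —
  uniform background, no small-sample correction.
* NN energies are rounded to two decimals (stack sums are exact 2-decimal
  quantities; rounding removes float accumulation noise so tables
  round-trip byte-identically through TSV).
* Introns shorter than `ignore_zone + 2` have no AGEZ (error); an empty
  shortened AGEZ or an empty candidate list yields a typed no-prediction
  row (`status` column), not a crash.
* Region/oracle problem sizes used by the test suite (random-string lengths
  up to 20 for the PPT oracle with 10^4 samples, 100–200 fixtures for
  pipeline-level properties) keep the whole suite to a few minutes on one
  CPU while exercising every rule branch.

## Worked example

```{r example}
m <- bundled_matrix("tna_synthetic")
introns <- simulate_introns(20, seed = 42)
preds <- predict_branch_points(introns, m, tab) # tab: nn backend from above
head(preds[, c("intron_id", "heptamer", "branch_pos", "score", "short_agez_start",
               "short_agez_end")], 3)
ev <- evaluate_predictions(preds, introns)
glance(ev)
```

```{r plots, fig.width = 6, fig.height = 3.5}
plot_info_content(m)
autoplot(ev)
```

## Known limitations

* The shortened-AGEZ 3' boundary and the PPT search window are reasoned
  interpretations (flagged above), each isolated behind a single function.
* Thirteen of the fifteen score configurations are placeholders pending
  their published parameter values.
* "Uridine content ≥ 5" is read as a count, not a fraction.
* The SVM-based and exact-PWM reference methods are not re-implemented; the
  bundled PWM-over-AGEZ baseline is an approximate stand-in for comparison
  plumbing only.
* Co-fold energies, and therefore predictions near score ties, can shift
  slightly across ViennaRNA versions and parameter sets.
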