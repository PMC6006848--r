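---
title: "Sample sequence selection for quorum planted motif search: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample sequence selection for quorum planted motif search: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samselect)
```

## The problem

Quorum planted motif search (qPMS) asks: given $t$ DNA sequences of length
$n$, a motif length $l$, a mismatch allowance $d$ ($0 \le d < l < n$) and a
quorum $q \in (0, 1]$, find every $l$-mer $m$ that occurs in at least $qt$
sequences with at most $d$ mismatches. It is the standard formulation for
locating transcription-factor binding sites, and it is NP-complete. Exact
solvers handle the classical benchmark scale ($t = 20$, $n = 600$) well, but
ChIP-seq experiments yield thousands of sequences, of which often only half
or fewer carry the motif. Both suffix-tree pattern-driven and
sample-pattern-driven solvers degrade badly in exactly that regime: running
time grows quadratically with $t$, and a small $q$ both weakens pattern-tree
pruning (the probability that a random pattern spans $qt$ sequences,
computable with `p_span()`, grows as $q$ shrinks) and inflates the number of
reference-sequence combinations `n_com()` an $h$-tuple solver must examine.

The remedy implemented here is *sample sequence selection*: choose a small
subset $D'$ of the input ($t' \ll t$) whose proportion $q'$ of motif-bearing
sequences is much higher than $q$, then run any qPMS solver on $D'$. The
package provides the three-stage selection algorithm, a planted-motif
simulator for validation, and a small exact qPMS solver so the entire claim
— "the implanted motif is recoverable at rank 1 from the selected sample" —
can be verified end to end on synthetic data.

## Stage 1: word counting with mismatches

Motif instances are mutually similar, so windows overlapping an instance
occur (up to a few mismatches) more often than background windows. For
every $w$-mer $x$ in the input the pipeline computes
$$\mathrm{count}_k(x) = \sum_{y \in B_k(x)} \mathrm{count}(y),$$
where $B_k(x)$ is the Hamming ball of radius $k$ and $\mathrm{count}(y)$ is
the exact occurrence count of $y$.

Exact counts come from a dense table of size $4^w$ indexed by the `stn()`
encoding (reverse the string, map A, C, G, T to 2-bit codes, read as an
integer; the reversal makes the first character least significant, so
rolling window codes and backward extension agree). The reference
construction (`build_count_table()`) walks the complete quadtree of strings
of length up to $w$ grown by *prepending* characters over a backward-search
index (`build_index()`: suffix array by prefix doubling, BWT, cumulative
occurrence counts — sequences are joined with per-sequence sentinels so no
window spans two sequences). Each node inherits its parent's suffix-rank
interval, so the shared-suffix backward search runs once per node, and any
zero-count node prunes its subtree. Because the table contract is exact,
the pipeline itself uses a rolling-code tally (`scan_count_table()`) that
produces a bit-identical table in a fraction of the time; the test suite
asserts the identity on every fixture.

With the table in memory, `count_all_windows()` evaluates
$\mathrm{count}_k$ for every window by $|B_k(w\text{-mer})|$ table lookups,
vectorized over windows via digit arithmetic on the codes.

**Choice of $w$ and $k$.** Defaults are $w = 12$, $k = 1$: the table
($4^{12}$ entries) fits comfortably in memory, $|B_1|=37$ keeps the lookup
cost linear, and $k \ge 1$ is needed because instances are similar rather
than identical. $w > 15$ is refused (the table would exceed $4^{15}$
entries).

## Stage 2: high-frequency substrings

Windows with $\mathrm{count}_k$ *strictly above* a threshold $f$ are
selected. The initial $f$ is the rounded sum of two expectations from
`expected_counts()`: $N_r$, the expected $\mathrm{count}_k$ of a random
background $w$-mer, and $N_m$, the expected contribution of sibling motif
instances. $N_m$ models per-position disagreement between two windows
covering instances of one motif: the $\min(w, l)$ instance positions
disagree with probability $\beta = \min(1, 2d/l)$, and, when $w > l$, the
remaining $w - l$ flank positions disagree like background (probability
$3/4$). For $w \le l$ this reduces to a plain binomial; the $w > l$
extension is this package's own generalization, needed because the default
$w = 12$ exceeds the headline motif length $l = 9$. The pipeline is robust
to the exact value: whenever more than 5000 substrings survive, $f$ is
escalated by $\max(1, \lceil 0.05 f \rceil)$ and the pass repeats, so the
initial value only determines how many cheap passes run.

Selected windows in one sequence whose overlap is at least $w/2$ are
chained into substrings (a chain may join many windows); pieces shorter
than $l$ are dropped, giving the set $A$. Long members of $A$ may span two
adjacent motifs, so each substring $\varphi$ is segmented using its
*attract table*: with
$$\mathrm{dis}(\varphi, \varphi') = \min_{x \in_l \varphi,\, x' \in_l \varphi'} d_H(x, x'),$$
entry $i$ of the table counts the other substrings whose nearest $l$-mer in
$\varphi$ (all argmin ties included) sits at position $i$. The $l$-mer at
the table maximum (leftmost on ties) is cut out with up to 3 characters of
context on each side; remainders of length $\ge l$ — defined relative to
the *unextended* cut, so a piece may share up to 3 characters with its
neighbour — are segmented recursively, reusing the original table
restricted to the surviving window positions (recomputing the table against
the full set at every recursion level costs $O(|A|)$ per step and changed
no outcome on our fixtures; we keep the cheaper variant). Pieces of length
$\ge l$ form the set $A'$. All pairwise window distances for a set are
computed once as a blocked matrix computation shared by the distance
matrix, the attract tables and the later similarity matrix.

## Stage 3: grouping and sample-set emission

$A'$ mixes instances of possibly several motifs with surviving random
substrings. Affinity propagation clusters $A'$ under the similarity
$$\mathrm{sim}(\varphi, \varphi') =
  \begin{cases}-\mathrm{dis}(\varphi, \varphi') & \mathrm{dis} \le 2d\\
  -10\,\mathrm{dis}(\varphi, \varphi') & \text{otherwise,}\end{cases}$$
which keeps plausible same-motif pairs (two instances differ by at most
$2d$) on a gentle scale and pushes everything else far away. Affinity
propagation chooses the number of clusters itself; the implementation is
the standard dense message-passing scheme (damping 0.9, preference equal
to the median off-diagonal similarity, at most 1000 iterations, declared
converged when the exemplar set is stable for 100 consecutive iterations).
Two numerical details matter: a deterministic jitter of relative magnitude
$10^{-9}$ breaks the exact symmetry that otherwise pins exemplar scores at
zero, and a fully tied similarity matrix (e.g. all members identical)
short-circuits to a single cluster.

Clusters are then greedily merged: for a larger cluster's center $\varphi$
and a smaller cluster $c'$, if the number of $\varphi' \in c'$ with
$\mathrm{dis}(\varphi, \varphi') \le d$ exceeds the random-case expectation
$P_d\,|c'|$ by more than a 20% margin, $c'$ is absorbed (the larger
center is kept). $P_d$ is the probability that two random $l$-mers lie
within $d$, from `p_d()`. Only the larger-center-versus-smaller-members
direction is tested, matching the rule as stated.

Each surviving cluster is trimmed to the $t'$ members closest to its
center and then must pass three rules in order:

1. **Pairwise bounded:** every pair at $\mathrm{dis} \le 2d$; the worst
   violator is removed iteratively (ties: larger center distance, then the
   later member; the center itself is exempt, since a cluster without its
   exemplar is no longer the object the rules describe).
2. **Center bound:** every member within $\lfloor 3d/2 \rfloor$ of the
   center — instances close to the motif should be closer to a
   well-conserved center than the $2d$ worst case.
3. **Motif set:** the weight $w(c) = \sum_{\{\varphi,\varphi'\}} \mathrm{dis}$
   (unordered pairs) must not exceed $a_m = \mu + \sigma$, where $\mu$ and
   $\sigma$ summarize the weights of 1000 freshly drawn samples of $|c|$
   true motif instances. The calibration instance model mutates each of
   $d$ distinct positions with probability $1/2$ — the intermediate
   conservation point of the simulator's own model — because the
   calibration must not assume the (unknown) conservation of the data.
   Clusters over the threshold lose their 10 most eccentric members
   (largest total distance) and retry with a recalibrated $a_m$; clusters
   that shrink below 20 members are discarded, preventing degenerate
   near-singleton "motif sets".

Finally each accepted cluster becomes a sample set: the distinct source
sequences of its members (a sequence contributing several members is
represented by the one closest to the center), ranked by size descending
(ties: smaller mean center distance). The declared $q'$ (default 0.95 for
simulated data; 0.9 is a sensible choice for noisier real data) is the
quorum a downstream solver should use on the set.

## The simulator and the reference solver

`generate_planted()` implements the classical protocol: $t$ i.i.d. uniform
sequences, a uniform random $l$-mer motif, $\lceil qt \rceil$ distinct
sequences each receiving one instance at a uniform position. An instance
mutates each of $d$ distinct uniformly chosen positions with probability
$g$ (to a uniformly different base), so the mismatch count is
Binomial($d$, $g$) and conservation decreases as $g$ grows. Chance
near-occurrences of the motif in background sequences are left in place —
they are a property of real data too, and they matter for interpretation
(below).

`solve_qpms()` is deliberately simple and exact: every motif is a
$d$-neighbor of each of its instances, so the union of per-sequence
neighborhood codes, accumulated over a $4^l$ support table, yields the
exact support of every candidate; candidates at or above
$\lceil qt \rceil$ are reported, ranked by support (descending), then
total minimum distance over supporting sequences (ascending), then
lexicographically. The ranking key is this package's own convention — the
published suffix-tree solvers rank their output but do not document the
key — and it is only relied on for the "implanted motif at rank 1" check,
which holds whenever the implant has maximal coverage. A cost guard
refuses instances beyond roughly $t \sim 200$, $l \le 13$, $d \le 3$
unless forced.

## What the synthetic data does and does not show

The simulator emulates uniform background with a single planted motif. It
does not emulate genomic composition bias, repeats, multiple co-occurring
motifs, ragged read lengths, or reverse-strand instances (only the forward
strand is processed throughout). Passing the end-to-end checks therefore
demonstrates the algorithmic contract — high-count window selection,
segmentation, clustering and the rules behave as specified, and the
implanted motif survives to rank 1 on the first emitted set — but not
performance on real ChIP-seq data, where $q'$ = 0.9 profiles and
enrichment-based post-ranking are advisable.

One interpretation caveat is worth stating precisely. For the headline
parameters $(l, d) = (9, 2)$ and $n = 600$, a *background* sequence
contains a chance occurrence of a given motif within $d$ with probability
$1 - (1 - P_d)^{n - l + 1} \approx 0.55$. A selected sample therefore
legitimately contains sequences that carry excellent motif occurrences
without having been implanted; a truth-based "fraction implanted" measure
undercounts motif-bearing sequences, increasingly so at low conservation
(large $g$), where implanted instances are no better matched than chance
ones. `estimate_q()` quantifies this: its $Q/t$ upper-bounds the true
implant fraction for exactly this reason.

## Problem sizes and numerical choices

The package's own verification uses $t = 500$, $n = 600$ datasets with
$t' = 50$ — large enough that the frequency signal, the cap escalation and
the clustering all engage, while a five-seed end-to-end run completes in a
few minutes on one core. Other fixed choices, made once:

* Coordinates are 0-based half-open internally; printed positions are
  1-based inclusive.
* `stn()` accepts strings up to 26 characters (the longest length whose
  code is exactly representable in a double); every pipeline use has
  length $\le 15$.
* Selection uses the strict inequality $\mathrm{count}_k > f$; escalation
  steps are 5% (configurable) so the pass count stays logarithmic.
* Odd $w$ uses $\lceil w/2 \rceil$ as the merge overlap.
* Non-ACGT characters are rejected on input by default; an explicit option
  replaces them by seeded random bases.
* Calibration draws are memoised per (size, $l$, $d$, samples, seed), with
  per-size seeds derived as `seed + size` so results do not depend on call
  order.

## Known limitations

* Affinity propagation is dense: $O(|A'|^2)$ memory and per-iteration
  time. The 5000-substring cap exists precisely to bound this, but sets
  near the cap are slow in pure R.
* The solver is a verification tool, not a competitor to optimized qPMS
  implementations; its cost guard is deliberately conservative.
* The initial-threshold expectations are a modelling choice (the
  escalation loop makes the pipeline insensitive to it); the $w > l$ flank
  term assumes independent uniform background.
* Only one motif per dataset is simulated; multi-motif inputs are handled
  by the clustering stage but are not part of the generator's contract.
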