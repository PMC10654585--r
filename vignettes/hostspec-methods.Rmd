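---
title: "Transmission routes and cophylogeny of host-specific symbionts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission routes and cophylogeny of host-specific symbionts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostspec)
```

This vignette is the package's own account of the science it implements:
the transmission model and its estimator, the genetic-distance and
delimitation conventions, the reconciliation algorithm, the simulators,
and the numerical and design choices behind each.

## The four-route transmission model

A symbiont can move between host individuals along four routes:
vertical conspecific (`q_vc`, parent to own chick), horizontal
conspecific (`q_hc`, contact between adults of the same species),
vertical interspecific (`q_vi`, foster parent to chick), and horizontal
interspecific (`q_hi`, contact between species). On an obligate brood
parasite `q_vc = 0` by natural history: there is no parental care. That
is the crucial identification assumption — every record of a
host-specific symbiont on the focal host must trace back to `q_hc`,
while records of foster-parent symbionts trace to `q_vi + q_hi`.

The data unit is the **record**: a unique (host individual, taxon) pair,
i.e. presence/absence. Specimen counts are kept separately as abundance
and never enter the rate estimator; a record is interpreted as at least
one successful colonisation event, whatever the resulting population
size. Mite-free hosts live in the roster, not as zero-abundance records,
because prevalence denominators need them.

### Classification into host-specificity categories

Three rules, applied in fixed priority by `classify_taxon()`:

1. **Ecological rule** (highest priority): quill- and skin-dwelling taxa
   are always QSM, whatever their host range. Their contact transmission
   (and, for skin mites, possible phoresy on louse flies) is not
   comparable with that of vane-dwelling plumage mites, so they cannot be
   placed on either side of the conspecific/interspecific contrast.
2. **Exclusivity rule**: a vane taxon found only on the focal host is
   host-specific, provided its known sister taxon (if any) lives on a
   congeneric brood parasite and any genetic distance to the nearest
   foster-parent mite exceeds the gene-flow threshold.
3. **Proximity rule**: everything else is "alien" (foster-parent
   derived).

Molecular evidence is optional: the survey classified 29 taxa with
sequences for only a few, so occurrence exclusivity alone suffices for
the specific category. The gene-flow threshold defaults to 0.05
(a K2P proportion, i.e. 5%) and is inclusive ("at or below"); the same
threshold doubles as the shallow-branch criterion in rule 2 because no
separate numeric cutoff is defined for "shallow" — the package flags
this reuse rather than asserting it as established convention.

### The rate estimator and its bounds

With record counts S (specific), A (alien), Q (QSM) out of N = S + A + Q,
`estimate_transmission()` reports shares s = 100·S/N, a = 100·A/N,
q = 100·Q/N rounded **half-up to one decimal**, the unrounded point
ratio S/A, and the QSM-assignment bounds computed from the rounded
shares exactly as the tabulated arithmetic:

* lower bound: s / (100 − s) — all QSM records assigned to the
  interspecific side;
* upper bound: (s + q) / a — all QSM records assigned to the conspecific
  side.

On the packaged survey this gives 74.8 / 18.9 / 6.3, point ratio
273/69 ≈ 3.96, and bounds 3.0–4.3. `confint()` on the estimate returns
these bounds; they are **assignment bounds**, not a statistical
confidence interval — no sampling test is attached, deliberately,
because the inference is about bracketing an identification ambiguity,
not about sampling error.

Denominators are a recurring source of confusion in prevalence work, so
every derived percentage in `summary.cooccurrence_summary()` carries
explicit numerator and denominator columns. Two conventions coexist:
prevalence uses **all examined hosts** (here 144), "cases" percentages
use **hosts that carried any symbiont** (here 139). Both are reported
for the headline quantity (hosts with specific mites: 130/144 = 90.3%
vs 130/139 = 93.5%) rather than choosing silently.

### Rounding

All displayed percentages round half **away from zero**
(`round_half_up()`), not half-to-even as base `round()` does; this is
what reproduces tabulated values such as 56.25 → 56.3. A guard of 1e-9
absorbs binary floating-point error in `x/n*100` terms. Per-taxon
percentages keep two decimals, subtotals and shares one.

## Kimura two-parameter distances

`k2p_distance()` implements the two-parameter distance directly from
transition proportion P and transversion proportion Q over the compared
sites:

d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q).

Conventions and edge cases:

* **Pairwise deletion**: sites with a gap or N in either sequence of a
  pair are excluded for that pair only — the standard choice for
  barcoding distances, where sequences of unequal coverage are common.
  The number of compared sites is reported per pair.
* **Saturation** (1 − 2P − Q ≤ 0 or 1 − 2Q ≤ 0) is a classed error, not
  a silent `NaN`: a distance that does not exist should not propagate.
* Distances are proportions internally; percentages only at display.
* Zero overlap after deletion is its own error.

The implementation is cross-checked in the test suite against
`ape::dist.dna(model = "K80", pairwise.deletion = TRUE)` on simulated
pairs, and against the closed form at hand-counted P and Q.

### Gene flow and OTU delimitation

`gene_flow_call()` applies the inclusive 5% rule: populations at or
below the threshold are treated as connected by ongoing gene flow. The
call is mechanical; for borderline cases (e.g. a 3.6% distance that may
reflect either a past switch or ongoing low-rate flow) the distance is
returned alongside so users can annotate.

`delimit_otus()` is a deliberately simple **barcode-gap maximiser**: for
each threshold in a grid, labels are clustered by single linkage
(connected components of the "d ≤ t" graph), and the partition with the
widest gap — smallest between-cluster distance minus largest
within-cluster distance — wins; ties go to the smallest threshold. The
gap is undefined for all-singleton and single-cluster partitions, which
are returned only when nothing else exists. This replaces
probability-scored partitioning: the package makes no attempt to
reproduce partition scores from such tools, only the partition itself in
clear-gap situations, which is the regime in which the survey's
delimitation calls were unambiguous anyway.

## Event-based maximum-parsimony reconciliation

`mpr_cost()` runs the standard undated duplication–switch–loss dynamic
program over symbiont nodes (postorder) × host nodes. A symbiont leaf
costs 0 at its associated host leaf; an internal symbiont node at host
node h chooses the cheapest of cospeciation (children descend into the
two distinct child subtrees of h), duplication (both children at or
below h), or host switch (one child at or below h, the other lands on
any host node **not ancestrally comparable** with h). Each host edge
traversed on the way down charges one loss. The optimum is the minimum
over host placements of the symbiont root.

Choices that matter:

* **Undated** reconciliation: no timing constraints, so a switch may
  target any non-ancestral host lineage. Dated host trees are out of
  scope, and undated parsimony is the mode in which the event census of
  interest (codivergences vs switches) is defined here.
* **Default costs (0, 1, 1, 1)** — free cospeciation, unit everything
  else. Costs are an explicit, validated configuration object
  (`event_costs()`), and the packaged analyses sweep
  duplication/switch/loss over {1, 2} to show the census does not hinge
  on the default.
* **Deterministic tie-breaks** in `backtrace()`: at equal cost prefer
  cospeciation over duplication over switch, then the host placement
  with the lexicographically smallest canonical label (sorted leaf set).
  One reconciliation is returned; the number of co-optimal solutions of
  the dynamic program is reported alongside (`n_optimal`), so users know
  when the returned scenario is one among several.
* **Brute force as oracle**: `mpr_brute_force()` enumerates every
  assignment of internal symbiont nodes to host nodes and prices it
  directly from the event definitions. It is exponential and capped, but
  on trees of up to six leaves it provides an independent check that the
  dynamic program is exact; the test suite runs hundreds of random
  tanglegrams through both.

A caveat documented rather than hidden: parsimony **can infer switches
on switch-free histories**. When survivors sample a deep host tree
sparsely, one switch (cost 1) is cheaper than a chain of two or more
losses, and the optimum is genuinely the switch scenario. The simulator
tests therefore assert the true bound (parsimony cost ≤ true-history
cost) and absence recovery under a switch-penalising cost vector, not
the false claim that zero simulated switches always yield zero inferred
switches.

### The packaged lineage tanglegrams

`molothrus_tanglegrams()` encodes the three independent
cowbird-associated mite lineages at desk scale, 6–8 host tips each,
with intervening icterid, cardinalid, passerellid and thraupid taxa so
that the cowbird (Icteridae) and *Sicalis* (Thraupidae) clades are not
sisters — the property that makes a cospeciation-only explanation of
the mite topology expensive. Their pooled census under default costs is
2 codivergences + 3 switches, stable across the {1,2}³ cost grid. These
are schematic topologies, not the full published phylogenies: tip sets
are reduced to the lineages of interest plus the minimum context, which
is exactly why the census — but not, say, branch support or timing —
is the quantity the package reproduces.

## The simulators

The generators exist so that every estimator in the package can be
validated by recovery, with no downloads.

**Transmission** (`simulate_transmission()`): each focal host is reared
by one uniformly chosen foster species (each of its pool taxa acquired
with probability `q_vi`), then makes `n_contacts_conspecific` contacts
(each specific-pool taxon acquired per contact with `q_hc`) and
`n_contacts_interspecific` contacts with uniformly chosen foster species
(per-taxon per-contact `q_hi`). First acquisition creates the record;
repeats increment abundance — mirroring presence/absence counting. The
closed-form oracle (`expected_record_counts()`) gives the expected
per-host record counts, e.g. S_pool · (1 − (1 − q_hc)^contacts) for the
specific side. Defaults (10 foster species, pools of 3, q_vi = 0.1) are
illustrative: no empirical contact rates exist for this system, so
recovery tests pin the *estimator*, not field parameter values. Foster
choice is uniform because real usage weights are unknown; a weight
vector is accepted.

**Sequences** (`simulate_k2p_pair()`): sites mutate independently with
the transition/transversion probabilities that make the expected
distance exactly the target d at rate ratio kappa — substituting the
expectations back into the distance formula returns d identically, so
estimator recovery (mean within Monte-Carlo error of truth) is a clean
test. Near-saturation targets trigger a warning.

**Cophylogeny** (`simulate_cophylogeny()`): an event-level simulator, not
a continuous-time birth–death process — deliberately, because the
event census is what the reconciliation stage can verify. The host tree
grows by uniform random splits; symbiont lineages track splits with
`p_cospeciate` (otherwise following one daughter, a sorting loss),
speciate with `rate_switch` with one daughter jumping to a uniformly
chosen contemporary host (its own host included, which yields a
duplication), and die with `rate_loss`. Extinct subtrees are pruned,
unifurcations suppressed; replicates with fewer than two survivors are
redrawn up to a bounded retry count. The true event log counts all
events as simulated, including on lineages that later die — which is
why it upper-bounds, rather than equals, the parsimony cost.

All simulators take an integer seed and restore the RNG state on exit;
identical seeds give identical output.

## What the packaged data are — and are not

The survey fixture (`molothrus_dataset()` and the `_synthetic` files
under `inst/extdata/`) is a **deterministic reconstruction**, not the
original field data: per-taxon record and abundance counts, category
subtotals, host block structure (which categories co-occur on how many
hosts, and how many records each block holds) all match the published
marginals exactly, but the assignment of individual records to
individual host IDs inside those constraints is an arbitrary
deterministic allocation. Every statistic computed from published
marginals is therefore reproduced bit-for-bit; any statistic that would
depend on the unpublished per-host assignment (e.g. per-host abundance
variance) is not meaningful on this fixture. The same applies to the
demo alignment, which is simulated at the published distances.

Likewise, passing tests on simulated data show that the estimators
recover the parameters of the generating models; they cannot show that
real mite surveys satisfy those models (uniform contact structure,
independent acquisitions, no competitive exclusion among mites — the
last being an open hypothesis this package does not model).

## Problem sizes and tolerances used in the packaged checks

Chosen as comfortable desk-scale settings: exhaustive-vs-DP equivalence
on 200 random tanglegrams of up to 6 leaves; distance-estimator recovery
at d ∈ {0.02, 0.05, 0.10} with 100 replicates of 1000 sites (3 standard
errors of the replicate mean); transmission-ratio recovery at target
ratios {1, 3, 5} with 50 replicates of 2000 hosts (3 standard errors);
co-occurrence tabulation against a naive per-host scan on 60 simulated
datasets. Equality checks on tabulated values are exact at the printed
precision.

## Known limitations

* Undated parsimony only: no likelihood/Bayesian cophylogenetics, no
  global-fit tests, no time-consistency constraint on switch scenarios.
* One optimal reconciliation is reported; the co-optimum count warns
  about, but does not enumerate, the alternatives.
* The barcode-gap partitioner needs a clear gap; overlapping
  within/between distance distributions return whatever maximises the
  (small) gap and should be inspected.
* The classification rules encode the brood-parasite study design;
  applying them to a host with parental care would conflate q_vc with
  q_hc by construction.
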