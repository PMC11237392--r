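---
title: "Hybrid-aware genome-scale metabolic modeling with hybridgem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-aware genome-scale metabolic modeling with hybridgem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridgem)
```

## The problem

Interspecies hybrids such as the lager yeast *Saccharomyces pastorianus*
(*S. cerevisiae* x *S. eubayanus*) carry aneuploid genomes in which many
genes exist as a pair of orthologous parental alleles. Either allele's
product can usually catalyze the shared reaction, so the hybrid is
*functionally redundant* at those loci. Constraint-based models built for a
parent species encode none of this: their gene-protein-reaction (GPR) rules
name single genes, so a simulated deletion of one ortholog wrongly kills a
reaction the other ortholog still supports, and expression data cannot be
apportioned between sub-genomes. `hybridgem` builds hybrid-aware models from
a template model plus ortholog tables, simulates them, constrains them with
RNA-seq data, and quantifies which parental sub-genome does the work.

## The constraint-based core

A model is a stoichiometric matrix $S \in \mathbb{R}^{m \times n}$ over $m$
metabolites and $n$ reactions, flux bounds $v_l \le v \le v_u$ (in
mmol·gDCW$^{-1}$·h$^{-1}$; reversible reactions default to $[-1000, 1000]$,
irreversible to $[0, 1000]$) and an objective vector $c$, usually the
indicator of a biomass drain. Flux balance analysis (FBA) solves

$$\max_v\; c^T v \quad \text{s.t.}\quad S v = 0,\; v_l \le v \le v_u,$$

the steady-state assumption turning growth prediction into a linear
program. Flux variability analysis (FVA) then brackets each flux: for
reaction $i$ it minimizes and maximizes $v_i$ subject to the same
constraints plus $c^T v \ge \gamma Z_0$, where $Z_0$ is the FBA optimum and
$\gamma \in [0,1]$ selects optimal ($\gamma = 1$) or suboptimal network
states — two LPs per reaction.

The LP engine (`solve_lp()`) is a dense two-phase primal simplex with
bounded variables: nonbasic variables rest at either bound, entering steps
can terminate in a bound flip, and phase 1 minimizes artificial variables
introduced against the shifted right-hand side. It targets the small, dense,
well-scaled systems this package generates and manipulates; every optimal
solve is checked against $\|S v\|_\infty \le 10^{-6}$. Numerical choices:
reduced-cost and pivot tolerances of $10^{-9}$, Dantzig pricing with a
Bland's-rule fallback after a fixed iteration count to exclude cycling, and
a hard requirement that lower bounds be finite (flux bounds conventionally
are; FVA's slack variable has lower bound 0). Degenerate alternate optima
are inherent to FBA; all scalar outputs (objective values, FVA bounds) are
well defined, while flux vectors are one optimal vertex and documented as
non-unique.

Exchange reactions — boundary reactions with a single stoichiometric entry —
encode the medium: negative flux is uptake, so "an uptake of 20" is a lower
bound of $-20$. `apply_medium()` sets the listed exchange bounds and closes
uptake on every unlisted exchange, leaving secretion open; growth is then
whatever the declared nutrients support. The biomass objective is reported
unit-agnostically: its scale follows whatever the model's biomass reaction
encodes, and the package deliberately does not re-interpret it as a specific
growth rate.

## Building a hybrid model

`build_mapping()` consumes ortholog records (hybrid gene, template gene,
parent, percent identity, evidence level) and resolves one call per
(template gene, parent). Records at or below the identity threshold
(default 70 %, strict inequality) are discarded. Two evidence levels are
supported because nucleotide- and protein-level ortholog searches can
disagree — different isoforms can be attributed at the two levels, and
paralogs identical at the protein level cannot be discriminated at all.
Protein-level calls both *rescue* template genes the gene-level search
missed and *override* gene-level calls on conflict; every disagreement is
logged. The override direction is a design choice (the protein sequence is
closer to the catalytic function being modeled); both strata are kept in the
mapping so either accounting can be audited.

`rewrite_gprs()` rewrites every GPR leaf: both parents present becomes
`allele_A or allele_B` (either product suffices), one parent becomes that
single allele, and an unmapped gene is dropped from its Boolean context — an
`or` loses the operand, while an `and` containing it becomes unsatisfiable,
because a complex missing a subunit cannot assemble. Allele identifiers are
the template gene's common name plus `_Scer` / `_Seub` (parent A / parent
B; `_Spast` marks hybrid-specific genes), case-sensitive, and a suffix
collision is an error rather than a silent merge. `prune_model()` then
removes reactions whose rewritten rule is unsatisfiable even with every gene
present, and afterwards genes left in no rule — in that order, so genes
orphaned by reaction removal are also dropped; both removals are reported
with reasons. Reactions without a GPR (exchanges, spontaneous chemistry) are
never pruned.

Organellar genes absent from nuclear annotations, isoform rescues and
newly evidenced reactions are handled by explicit, auditable curation
actions (`apply_curation()`) rather than inference: each action has an id,
is applied at most once (idempotent lists), must pass elemental balance
(`check_balance()`) unless explicitly waived, and records a provenance note.

## Expression integration

`tpm_normalize()` implements transcripts-per-million: RPK = count /
length(kb), scaling factor = $\sum$RPK / $10^6$, TPM = RPK / factor. Every
library sums to exactly $10^6$, which is the property that makes
across-library comparison meaningful and is asserted in the tests.

`map_transcriptome_data()` converts expression into flux capacity through
the GPR tree, recursively: `or` sums its children (alternative catalysts add
capacity) and `and` takes the minimum (a complex is limited by its scarcest
subunit). A reaction is constrained only when *all* its genes are expressed
strictly above `threshold_abundance` (default 10, above typical RNA-seq
noise); the aggregate then caps the upper bound of an irreversible reaction
and both bounds ($\pm E$) of a reversible one. Three deliberate conventions,
all of them documented rather than hidden:

* TPM magnitudes are used directly as flux-bound magnitudes. There is no
  biochemical unit linking the two; the constraint is a relative-capacity
  heuristic, and its value lies in comparisons across conditions, not in
  absolute flux predictions.
* Bounds are clipped against the existing bounds and `max_bound` (default
  1000) — constraining never widens a bound and never relaxes
  irreversibility. Two equal alleles at level $x$ give an `or` capacity of
  $2x$: the sum rule is applied exactly, with no saturation.
* The all-genes gate is strict; a reaction with one silent isoform is left
  untouched even though the expressed isoform could carry it. An `"any"`
  gating mode exists for sensitivity analysis but is off by default.

Genes absent from the expression table count as level 0 (failing the gate)
and the affected reactions are flagged as incompletely measured.

## Parental attribution

`attribute_reaction()` asks, per reaction and condition: what fraction of
the expression supporting this reaction comes from each parent? For a flat
`or` over alleles the answer is the TPM-weighted share,
$\sum \mathrm{TPM}(\text{parent's leaves}) / \sum \mathrm{TPM}(\text{all leaves})$.
For an `and` of groups each subunit slot counts once: the shares of the
groups are averaged unweighted. The choice of an unweighted mean for
complexes is a genuine design decision — the alternative of weighting by
group capacity is defensible — so it is isolated in one function and the
recursion reduces exactly to the two stated rules on those shapes. The call
is `inconclusive` when total supporting TPM does not exceed the threshold
(default 10, reusing the expression-gating threshold): with no meaningful
signal there is nothing to apportion. This threshold-based definition of
inconclusiveness is one plausible reading; it is a package convention, not
an empirical claim. Hybrid-specific alleles carry no parental weight;
conclusive shares always sum to 1, swap exactly under relabeling the
parents, and are invariant under uniform scaling of all TPM values.
`detect_shift()` classifies a reaction as `shifted` when the parent-A share
differs by at least `delta` (default 0.10) between any two conclusive
conditions — e.g. growth temperatures — and `indeterminate` below two
conclusive conditions. Report output rounds shares to 5 % granularity;
machine output keeps full precision.

## Synthetic data: what it emulates and what it does not

`make_template()` builds toy networks whose optimum is known in closed form:
one substrate exchange, a two-subunit transport complex, `n_parallel_paths`
conversion paths whose entry steps are capacity-capped at `uptake_per_path`
(default 10, a conventional sugar-uptake scale), a biomass drain objective.
The FBA optimum is exactly `uptake_per_path * n_parallel_paths`, which is
what makes the LP acceptance check meaningful. GPR rules span all six census
categories (single gene, `or`-only, `and`-only, mixed, gene-less internal,
gene-less exchange). `make_ortholog_tables()` draws per-gene parental
coverage from the requested fractions (defaults 0.6 / 0.1 / 0.3
both / A-only / B-only, echoing the roughly 60/6/30 coverage pattern seen in
hybrid yeast gene mappings) with identities strictly above the threshold for
mapped genes and decoy records below it for unmapped ones.
`make_expression()` gives each allele family a log-normal base level
(meanlog $\log 100$, sdlog 1 — a realistic right-skewed transcript
distribution), splits pairs as `parentB_bias` : 1 − bias, applies optional
multiplicative noise (`noise_cv`) and per-condition log-normal effects, and
normalizes to TPM. All generators are driven by a single integer seed
through R's default RNG, with the caller's RNG state restored afterwards;
the same seed reproduces the same artifact exactly.

These toys exercise every code path but are *not* genome-scale biology:
they have tree-like topology without cycles or cofactor coupling, one
substrate, no compartmental transport chains, and expression without count
overdispersion, batch structure, or mapping ambiguity between near-identical
alleles. Passing the synthetic recovery tests shows the algorithms implement
their stated rules faithfully — not that those rules capture everything real
transcriptomes do; the attribution of multi-mapping short reads between
alleles, in particular, is upstream of this package.

## Problem sizes and verification

The test suite and the acceptance script run entirely on generated data:
50 seeded toy models of at most 12 reactions for the LP cross-check against
an independent solver (scipy's HiGHS via `python`, agreement to $10^{-6}$),
exhaustive truth tables on rules of up to 10 genes, 200 random trees for the
aggregation oracle (an independent postfix evaluator), 20 libraries for the
TPM sum invariant, and 100 seeded hybrids for the attribution-recovery check
(parent-B bias 0.8 recovered exactly on `or` pairs and within 0.02 on mixed
rules). These sizes were chosen so the whole verification runs in seconds on
one core while still covering every rule combination; the generators scale
to larger networks if heavier stress testing is wanted.

## Known limitations

* The simplex core is dense and unfactorized; it is sized for toy and
  mid-sized curated models, not for repeated scans over genome-scale
  matrices, where a sparse solver with basis updates would be appropriate.
* SBML support covers the L3V1 + fbc v2 constraint-based subset only (no
  kinetic laws, events, or annotations round-trip).
* Expression-derived bounds are heuristic capacities, not measured fluxes;
  absolute growth predictions from constrained models should be read
  comparatively across conditions.
* Attribution presumes the expression quantification already resolved
  reads to alleles; proportions inherit any upstream mis-assignment.
* Copy-number dosage (beyond allele presence/absence) and proteomics
  integration are out of scope.
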