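---
title: "Methods: constraint-based modelling of an aerobic diazotroph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based modelling of an aerobic diazotroph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diazogem)
```

## The modelling framework

A genome-scale metabolic model (M-model) is a stoichiometric network: a
metabolites-by-reactions matrix $S$, flux bounds $l \le v \le u$
(mmol/gDW/h), and gene-protein-reaction (GPR) boolean rules linking genes
to the reactions they catalyse. Flux balance analysis (FBA) predicts a
flux state by linear programming:

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; l \le v \le u,$$

where $c$ selects the biomass objective function (BOF); the optimum is the
growth rate $\mu$ (1/h). The framework carries the usual assumptions:
steady state (no metabolite accumulation except through explicit exchange,
sink and biomass pseudo-reactions), a fixed biomass recipe, and no
transcriptional or enzyme-level regulation — a growth prediction says the
network *can* sustain flux, not that the organism expresses it.

The package applies this machinery to the physiology of aerobic
nitrogen-fixing bacteria of the *Azotobacter* type: growth on molecular
nitrogen via the ATP-expensive Mo-nitrogenase
($N_2 + 8H^+ + 8e^- + 16\,\mathrm{ATP} \to 2\,NH_3 + H_2 + 16\,\mathrm{ADP} + 16\,P_i$)
versus ammonium assimilation, and the two storage/protection polymers
alginate (secreted, periplasmic route) and polyhydroxybutyrate (PHB,
intracellular sink).

## The linear-programming core

No LP package is assumed: `fba()` runs on a bounded-variable two-phase
primal simplex implemented in the package (`lp_solve`, internal). Nonbasic
variables rest at a bound, bound flips avoid basis changes, and Bland's
rule takes over after a Dantzig warm-up so the heavily degenerate FBA
polytopes (all right-hand sides are zero) cannot cycle. The solver is
deterministic, so every result in this package is reproducible
bit-for-bit on a given platform. Tolerances: feasibility/optimality
$10^{-9}$; reported steady-state residuals are checked at $10^{-6}$;
unbounded directions cannot occur in practice because "unconstrained"
fluxes are capped at $\pm 1000$ mmol/gDW/h, the community convention. The
test suite cross-checks optima against an independent brute-force
vertex-enumeration oracle on dozens of random networks.

FBA optima are degenerate, so any quantity that consumes a single flux
vector (subsystem partitioning, flux-map comparison, production analysis)
uses parsimonious FBA (`pfba()`): the objective is pinned at its optimum
and total absolute flux $\sum_j |v_j|$ is minimised via flux splitting.
This is a selection rule, not extra biology; it makes per-reaction flux
values well defined.

## Model representation and I/O

Metabolite identifiers are BiGG-style with a compartment suffix (`_c`
cytoplasm, `_p` periplasm, `_e` extracellular). Exchange and sink
reactions touch exactly one metabolite; negative flux is uptake, positive
is secretion, and a growth medium (`medium_spec()`) is a map from exchange
ids to bound pairs, with every unreferenced uptake closed by
`apply_medium()`. Models round-trip through two dialects: cobra-style JSON
(hand-editable, used for fixtures) and SBML Level 3 with the FBC v2
package (shared flux-bound parameters, `fbc:geneProductAssociation` trees,
charge/formula attributes). Subsystem labels and provenance tags ride in
the SBML notes body. Stoichiometries are serialised in sorted metabolite
order so write-read-write is byte-stable.

## Quality control

`element_balance()` audits every internal reaction: the signed atom count
of each element (Hill-notation formulas) and the net charge must be
exactly zero. Boundary and biomass pseudo-reactions are inherently
unbalanced and are skipped but listed; a missing formula flags the
reaction unauditable rather than silently passing it. Imbalances confined
to H/O/charge are additionally marked `minor`, because periplasmic
transport legitimately moves protons.

`energy_cycle_check()` hunts energy-generating cycles: with every
boundary reaction closed, a temporary dissipation reaction is added and
maximised. The dissipation forms are the community-standard ones —
$\mathrm{ATP} + H_2O \to \mathrm{ADP} + P_i + H^+$ for ATP and
$\mathrm{NAD(P)H} \to \mathrm{NAD(P)}^+ + H^+$ (electrons implicit) for
the nicotinamide couples; an explicit dissipation reaction was chosen over
an open demand because it reports the offending cycle support directly as
the nonzero-flux reactions at the optimum. Any dissipation above
$10^{-6}$ fails.

`gene_deletion_screen()` evaluates each GPR under a knock-out (AND = all
subunits, OR = any isozyme, empty GPR = always active — orphan reactions
are never silenced) and re-solves; since deletions only tighten the LP,
no knock-out can grow faster than wild type, which the tests assert.

## Curation and gap-filling

Homology evidence enters as BLAST-style hit tables (`qseqid`, `sseqid`,
`pident`, `evalue`, `qcovs`). `filter_hits()` accepts a hit iff identity
$\ge 40\%$, e-value $\le 10^{-4}$ and query coverage $\ge 85\%$, all
inclusive; coverage is interpreted over the query length (the `qcovs`
BLAST semantics). Best hits are chosen by lowest e-value, ties by higher
identity, then lexicographic subject id — a deterministic rule where no
canonical one exists.

`remap_gpr()` renames mapped template genes and simplifies the boolean
tree around unmapped ones. The default `strict` policy removes an entire
AND branch when any subunit is unmapped: a complex is not asserted
catalytically active with a missing subunit. A `permissive` policy is
available. Associations that vanish are flagged `exogenous-only`, and
`prune_exogenous()` removes such reactions only when they are also
flux-blocked under *every* supplied condition, asserting afterwards that
no condition optimum moved by more than $10^{-6}$ relative. Native orphan
reactions are never pruned.

`gapfill()` restores growth from a universal reaction pool by smallest-set
parsimony (the likelihood-weighted alternative is out of scope): subsets
are enumerated by increasing size, lexicographically within a size, so
ties resolve deterministically; pools beyond 12 reactions fall back to
greedy selection with a deletion-minimality prune. "Growth" means
exceeding 0.001 1/h — the same strict threshold `call_growth()` uses
everywhere, chosen once as the only numeric growth cut-off the workflow
needs.

## Biomass objectives

`build_bof()` distributes a protein mass fraction (default 0.55 g/gDW)
over the 20 amino acids proportionally to their molar frequencies in a
proteome, using dehydrated residue masses (free amino acid minus one
water, 18.02 g/mol), because polymerised protein is what the mass
fraction describes:

$$c_a = \frac{1000 \, f_{prot} \, f_a}{\sum_b f_b m_b} \;\; [\text{mmol/gDW}],
\qquad \sum_a c_a m_a = 1000\,f_{prot} \text{ mg exactly.}$$

Proteins are weighted equally (genome-encoded theoretical abundance, not
expression). Non-protein constituents and the polymerisation energy cost
pass through unchanged from a template biomass reaction.
`build_alginate_bof()` derives a second objective that additionally
consumes periplasmic alginate at a configurable coefficient (no canonical
default exists; it is an input), keeping the original objective in the
model — exactly one is active per simulation. Growth is monotonically
non-increasing in the alginate coefficient, which the tests verify.

## Phenotype screens and statistics

`build_condition()` encodes the plate protocol: carbon screens close all
competing organic-carbon uptakes (CO2 is not an organic source) and open
the probed source at 10 mmol/gDW/h by default — plate-level uptake
estimates are rarely published, so a single configurable default is used;
nitrogen screens fix pyruvate as the sole carbon source and make the
probed compound the only nitrogen supply. The two nitrogen regimes are
exclusive: non-diazotrophic opens ammonium and closes N2, diazotrophic the
reverse, with N2 uptake left unconstrained at the cap. Mineral exchanges
stay open. A probed source with no exchange reaction in the model is
excluded with a reason code rather than counted as a negative.

`confusion_stats()` computes accuracy, sensitivity, specificity, PPV, NPV
and the Matthews correlation coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}$$

from the counts. Any 0/0 ratio is reported as `NA`, never as 0, and the
MCC is always the formula value — the package never adjusts a statistic
toward an externally reported number. The tests verify MCC against the
phi coefficient (the Pearson correlation of the binary vectors), an
independent identity. Printed percentages round half away from zero.
`growth_rate_accuracy()` defines the per-pair percent error as
$|pred - exp| / exp \times 100$ with accuracy $= 100 -$ error; pairs with
a zero experimental value are excluded with a flag. Note that aggregate
accuracies depend on this denominator convention; alternative conventions
(error relative to the prediction) give different means, so the package
reports per-pair values alongside any mean.

## Elemental partitioning and production

The element throughput of a reaction is $|v| \sum_{i: s_i > 0} s_i \,
\mathrm{atoms}_e(i)$ — the product side at absolute flux. For balanced
reactions this equals the substrate side (asserted against a brute-force
atom tally); the convention also covers pseudo-reactions. It deliberately
includes cofactor atoms: a reaction turning over 16 ATP moves that
adenine carbon through the subsystem, which is what makes energy
metabolism and oxidative phosphorylation the dominant carbon subsystems
in genome-scale flux states. A corollary, visible on the toy network, is
that the *global* cofactor-inclusive carbon throughput can rise under
diazotrophy (nitrogenase's ATP bill is itself throughput) even while
every growth-coupled subsystem declines.

`partition_fluxes()` averages member-reaction throughput per subsystem,
zero-flux members included (the literal reading of a per-subsystem
average; an active-only mean is available via a flag). Transport and
exchange subsystems are computed but flagged out of headline summaries,
since they double-count every uptake. `compare_conditions()` correlates
the diazotrophic and non-diazotrophic subsystem profiles across
conditions (Pearson r, undefined for constant vectors, flagged similar
above 0.9) and reports the global percent change.

Production analysis uses either route a practitioner would: a sink
(`add_sink()`, `SK_<met>`, irreversible, for intracellular PHB) or the
secretion pathway plus exchange (alginate, modelled throughout as its
mannuronate monomer unit since polymer length is not stoichiometric).
`production_rate()` is the standard two-stage LP — maximise growth, pin
it to a fraction of the optimum, maximise product. Growth-coupled
production through the alginate-augmented biomass objective is measured
with secretion closed, where branch flux equals coefficient times growth
exactly. `normalize_flux_map()` rescales a flux state so an anchor
reaction (typically glucose uptake) maps to 100, and
`compare_flux_maps()` scores percent error per reaction against a
reference map with a 20% agreement threshold; a zero reference with a
nonzero prediction is flagged infinite rather than hidden.

## The synthetic toy diazotroph

`make_toy_diazotroph()` emits a deterministic three-compartment network
(73 reactions, 63 metabolites, 56 genes) that exercises every pipeline
stage: eight assimilable carbon sources (glucose, fructose, galactose,
mannose, sucrose, mannitol, glycerol, pyruvate) plus glutamate; lumped
glycolysis and Entner-Doudoroff routes; lumped TCA and respiration
(P/O = 2); the canonical 16-ATP Mo-nitrogenase with a ferredoxin couple
(the vanadium and iron-only alternatives are not modelled); glutamate
dehydrogenase for ammonium assimilation; a six-reaction alginate branch
ending in the periplasm; a PHB branch from acetoacetyl-CoA; and a lumped
amino-acid biomass objective scaled so growth rates land in the
physiological 0.05-0.25 1/h range at a 10 mmol/gDW/h sugar uptake. The
network is larger than a minimal demonstration would be because a
phenotype plate with eight growth-supporting wells needs eight genuinely
assimilable sources; six declared-but-disconnected decoy sources (with
exchanges but no transporters) provide the negative wells, emulating
plate compounds that exist in a reconstruction but cannot be metabolised.
The ammonium transporter is reversible: assimilated amino-acid nitrogen
is excreted as ammonium, which is both biologically faithful for this
guild and necessary for amino acids to serve as carbon sources.

Every internal reaction is element- and charge-balanced by construction
(the generator's manifest declares the counts, ground-truth growth calls
and media, and the tests hold the generator to it). Three optional
defects each trip exactly one QC check: an oxygen-losing water-splitting
reaction (mass balance only), a balanced uncosted ATP regeneration
(ATP energy cycle only — it cannot leak into the NAD(P)H checks because
no reaction converts ATP back to reducing power), and a
produced-but-never-consumed metabolite (dead-end classification only).

What the toy does *not* emulate: genome-scale redundancy and isozyme
richness, realistic uptake kinetics, condition-dependent biomass
composition, regulation, and the absolute subsystem flux magnitudes of a
real reconstruction. Green tests on the toy therefore certify the
machinery — balance auditing, cycle detection, screening statistics,
partitioning arithmetic — not the biology of any particular organism.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run the whole pipeline at
deliberately small scale: networks of 4-73 reactions, plates of 5-12
wells, proteomes of 50-100 proteins, homology tables of 24-40 rows, and
random-LP cross-checks on 20+ instances of up to 9 reactions — sizes at
which every expected value can be recomputed by an independent oracle
(vertex enumeration, subset enumeration, atom tallies, the phi identity).
All stochastic generators are pure functions of their seed;
`scripts/acceptance.R` threads a single `--seed` through every stochastic
input and writes its recomputed quantities as JSON.

## Known limitations

Single-objective LP only (no MILP, no loopless constraints, no flux
variability beyond the blocked-reaction test); no thermodynamic
feasibility checks; SBML support covers the FBC modelling subset (no
kinetic laws, events or rules); gap-filling parsimony is cardinality-based
rather than likelihood-weighted; and dense simplex linear algebra targets
curated-model scale (thousands of reactions are workable, but this is not
a high-performance solver).
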