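---
title: "Constraints-based analysis of haloarchaeal growth on a single carbon source"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraints-based analysis of haloarchaeal growth on a single carbon source}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haloflux)
```

## The scientific problem

Haloalkaliphilic archaea such as *Natronomonas pharaonis* grow in soda
brines: saturating salt, pH around 9, and — under the laboratory conditions
this package models — a single organic carbon source, acetate, oxidized
aerobically. Three questions organize the analysis:

1. Given a curated genome-scale metabolic reconstruction, is the network
   internally consistent — mass- and charge-balanced, with coherent
   gene–reaction logic and documented evidence?
2. Given measured biomass composition (bulk organic carbon and per-amino-acid
   content as functions of optical density), what does one unit of new
   biomass cost in precursors and ATP, and how does the theoretically
   maximal growth rate depend on the acetate:oxygen consumption ratio and
   on the maintenance energy?
3. Given growth time series (optical density, acetate concentration,
   cumulative O2), where does the consumed carbon end up — biomass, CO2, or
   unaccounted?

`haloflux` implements the full chain: a network data model with balance
auditing, SBML/tabular I/O, biomass-reaction construction from composition
measurements, an LP-based flux balance core, phenotype-plane sweeps, and
carbon-fate accounting — together with synthetic-data generators that make
every stage testable without any external data.

## The flux balance model

A network of $m$ metabolites and $n$ reactions is summarized by its
stoichiometric matrix $S \in \mathbb{R}^{m\times n}$; column $j$ holds the
signed coefficients of reaction $j$ (negative = consumed left-to-right). At
steady state, flux vector $v$ satisfies $Sv = 0$, and flux balance analysis
picks the flux distribution maximizing an objective $c^\top v$ (here: the
growth reaction) subject to reaction-class constraints:

* **reversible internal** reactions: $v_j$ free in sign;
* **irreversible internal** reactions (and the growth reaction):
  $v_j \ge 0$;
* **ubiquitous** compounds (CO2, water, Na+, Cl−, K+, H+): free two-way
  exchange — these are assumed always available in, or dischargeable to,
  the brine;
* **abundant** compounds (sulfate, orthophosphate, trace ions): free
  uptake, no secretion;
* **parameterized** compounds (acetate and O2 in this study): exchange
  flux fixed to the uptake parameter, i.e. an equality constraint;
* **secretion-only** exchanges: one-way outflow, allowing overflow
  metabolism without permitting uptake.

Because the constraints and objective are all linear and homogeneous in the
uptakes, scaling both parameterized uptakes by $k>0$ scales the optimum by
$k$ (asserted as a test invariant). The phenotype therefore depends only on
the acetate *fraction* $f = a/(a+w)$ of the total uptake and on the
maintenance energy, which is how the sweep module parameterizes it. The
paper-scale sweep uses fractions 0.10–0.90 (quotients 1:9 to 9:1) and
maintenance 0–100 µmol ATP per ΔOD·ml.

### Solving the LP

No dedicated LP package is part of this package's dependency footprint, so
the backend is a self-contained two-phase primal simplex
(`solve_lp()`) on the equality form with variable bounds. Numerical
choices:

* Bland's anti-cycling rule throughout — FBA bases are massively
  degenerate and cycling is a real risk with classical pivoting;
* free variables are split, finite bounds become rows, and fixed
  variables (parameterized exchanges) are substituted out before
  iteration;
* feasibility of a returned optimum is verified *a posteriori*:
  $\lVert Sv\rVert_\infty \le 10^{-7}$ after scaling each row to unit
  maximum coefficient. A solution failing this check is reported as a
  `NUMERICAL` status, never as infeasible;
* `INFEASIBLE` is declared only when phase 1 proves a positive artificial
  optimum.

Correctness is cross-checked in the test suite against (i) closed-form
optima of the toy network, (ii) an independent vertex-enumeration oracle
(`brute_force_lp()`, which solves small LPs by enumerating
active-constraint subsets and linear algebra alone), and (iii) random small
LPs against a second, test-local enumerator. The oracle refuses problems
with more than 8 free dimensions rather than approximate.

Alternate optima are possible in degenerate networks; the objective value
is the contract, and the flux vector is reported as-is without
lexicographic tie-breaking.

### Pruning

Before a sweep, reactions that can never carry steady-state flux are
removed (`prune_blocked_reactions()`): iteratively, any internal reaction
touching a metabolite with no possible producer, no possible consumer, or
touched by no other reaction at all (a dead end — even through a reversible
reaction, such a metabolite would accumulate) is deleted. This is standard
constraint-based-model preprocessing; it cannot change the optimum, and a
test asserts optima before and after pruning agree.

## Building the growth reaction

The growth (biomass) pseudo-reaction consumes precursors in measured
ratios (µmol per OD·L of culture — the canonical biomass unit here) and
produces one unit of population. The pipeline:

1. **Bulk carbon.** Total organic carbon against optical density is fitted
   through the origin (`fit_through_origin()`): zero biomass means zero
   carbon, so the origin constraint is the default, with an intercept mode
   available for sensitivity checks. The reference slope is 18.2 mmol C
   per OD·L.
2. **Amino acids.** Per-analyte slopes (`fit_amino_acid_slopes()`); the
   analyser reports Asp+Asn and Glu+Gln jointly, so those pools are split
   by relative proteome abundance (`split_combined_pool()`, exact
   conservation), and cysteine/tryptophan — not reliably measurable — are
   estimated from proteome frequencies relative to the measured set
   (`estimate_unmeasured_aa()`). Frequencies are an input table computed
   under the one-copy-per-gene convention; the package does not parse
   genomes.
3. **Nucleotides.** Two modes (`residual_nucleotide_pool()`): a fixed
   fraction of the TOC budget (default 20%), or the residual left after
   all other components — the latter closes the carbon balance exactly and
   is what the synthetic reference composition uses. The pool is spread
   over the four NMP+dNMP pairs by `allocate_nucleotides()` with an
   explicit `split_fraction_AT` parameter, default 0.634. The default
   deliberately gives the *A/T* pairs the larger share: the reference
   composition table prints the A-pair at 81.6 and the G-pair at 47.1
   µmol/OD·L — a 63.4 : 36.6 split in favour of A/T — even though the
   genome's *GC* content is the 63.4% figure. The committed behaviour is
   the table's ratio; the parameter makes either reading available, and
   the exact arithmetic behind the printed 81.6/47.1 values is not
   recoverable from the stated rules (carbon- and mass-based
   back-calculations disagree), so only the ratio is asserted.
4. **Minor components.** Lipids (archaeol), S-layer sugars and a free-ATP
   pool are scaled from a reference halophile's composition by the ratio
   of measured amino-acid content (`scale_reference_components()`).
5. **Salts.** Na+ (with K+) and Cl− at 2813.4 µmol/OD·L each — the
   salt-in osmotic strategy means biomass is, by mole, mostly ions.
6. **Maintenance.** Non-biosynthetic ATP expenditure (assembly, repair,
   motility, division) enters the growth reaction as an ATP-hydrolysis
   term proportional to growth flux, in µmol ATP per ΔOD·ml converted to
   the OD·L coefficient scale (×1000). Modelling it growth-proportional
   rather than as a constant flux matches its definition per unit biomass
   produced.

`assemble_growth_reaction()` turns the composition plus maintenance into
an irreversible GROWTH-kind reaction (components + ATP + H2O →
ADP + phosphate + biomass unit). Every coefficient carries a provenance
tag (`MEASURED`, `SPLIT_FROM_POOL`, `PROTEOME_ESTIMATED`, `GC_ALLOCATED`,
`REFERENCE_SCALED`, `FIXED`) that survives into the composition report.

An independent estimate of the maintenance parameter comes from
respiration: O2 consumed per unit ΔOD, times the P:O ratio
(`estimate_maintenance_energy()`). P:O is defined here per oxygen *atom*
(so one O2 credits two ATP at P:O = 1), with `atoms_per_o2 = 1` available
for the per-O2 reading; published results are figure-bound and cannot
adjudicate between the two conventions, so the choice is an explicit
argument with the per-atom default.

## The balance audit

Internal reactions are checked for elemental and charge balance
(`check_reaction_balance()`): the signed sum of `coefficient × formula`
and `coefficient × charge` over participants must vanish. Three verdicts:

* `BALANCED` — all deltas zero;
* `UNBALANCED` — a nonzero delta with all participants known;
* `UNVERIFIABLE` — some participant's formula or charge is unknown.
  "Cannot check" is deliberately distinct from "fails check": in curated
  reconstructions the unbalanced residue is typically a handful of
  reactions whose reactants are chemically uncharacterized, and an audit
  that conflated the two would misreport them.

Exchange and growth reactions are exempt (they intentionally create or
destroy matter). No automatic proton/water slack is inserted — the model
is expected to be balanced as annotated at its reference pH, and the audit
reports deltas verbatim. Verdicts are invariant under reaction reversal
and positive rescaling (property-tested).

Charges at pH 9 are consumed as annotations; the package does not compute
microspecies distributions.

## Gene logic and evidence

Gene–protein–reaction rules are boolean trees over opaque gene
identifiers: `AND` for complexes (both subunits of a two-subunit
oxidoreductase are required), `OR` for isoenzymes. The grammar fixes
`AND` tighter than `OR` with parentheses for overrides; `render` is the
canonical (flattened) form and `parse(render(x))` is the structural
identity on parsed trees. Empty logic — no genetic support — evaluates to
`FALSE` under every gene set, and evaluation is monotone in the present
set (property-tested).

Evidence is a three-way genetic class (`SPECIFIC`, `GENERAL_ONLY`,
`NONE`) plus independent literature and gap-fill flags; gap-filled
reactions by definition have neither genetic nor literature support.
`evidence_summary()` tallies the partition by functional category, with
literature as an overlapping count. Gene counting
(`network_genes()`) by default excludes genes appearing only in
`GENERAL_ONLY` reactions — transporters with unclear substrate
specificity — matching the reconstruction's stated convention; a flag
includes them.

## The synthetic-data generators

Everything above is exercised end-to-end on generated data. The
generators define the study conditions; their defaults are fixed once and
are not tuning knobs.

### AC-CORE toy network

`generate_toy_network()` builds the smallest network with acetate-like
energetics: exchanges for acetate, O2 and CO2; activation
(acetate + 1 ATP → acetyl); lumped oxidation (acetyl + 2 O2 → 2 CO2 + 4
ATP); growth (acetyl + 2 ATP → biomass); and an explicit ATP sink, a
toy-only construct that keeps surplus-energy states feasible so the
closed forms hold everywhere. With total uptake $T = a + w$:

* acetyl balance forces $g = a - w/2$, so feasibility requires
  $a \ge w/2$, i.e. $f \ge 1/3$;
* the ATP budget requires $2w \ge a + (2+m)g$, giving $f \le 1/2$ at
  $m = 0$;
* maximal growth is $(3a - T)/2$ and the optimal uptake is
  $a^* = T\,(6+m)/(12+3m)$, decreasing from $f^* = 0.5$ toward $1/3$ as
  maintenance grows.

These closed forms are the acceptance oracle for the whole LP stack. All
toy reactions are elementally balanced using synthetic formulas: the
acetyl carrier is C2H4O2, and ATP/ADP are a conserved moiety pair whose
formulas differ by exactly HPO3, so ATP + H2O → ADP + Pi is elementally
neutral and energy bookkeeping never perturbs the audit. Toy maintenance
is in ATP per biomass unit (applied directly), matching the closed forms.

### Synthetic reference network

No real curated reconstruction is distributed with this package;
`synthetic_reference_network()` is a full-scale, generated stand-in,
labelled synthetic throughout. Its summary statistics
are construction targets chosen to emulate the published reconstruction:
683 reactions, 597 metabolites, 654 distinct non-transport genes, exactly
10 reactions whose balance cannot be verified because a reactant is
unknown (7 in cofactor biosynthesis, 3 in amino-acid degradation), and
168 literature-supported reactions. Parsing, auditing and evidence
reporting *measure* these numbers on the serialized-and-reparsed network;
they demonstrate the machinery at realistic scale, not a reproduction of
the real reconstruction's content.

Its metabolic core is lumped but biochemically shaped: acetate activation
(6/7 ATP per acetate), complete oxidation of the C2 carrier to CO2
yielding 4 reduced-carrier equivalents, respiration at P:O = 1 per O
atom, and per-component biosynthesis from the acetyl pool that emits 0.5
reduced equivalents per acetyl. Two of these numbers are calibration
choices made once so the stand-in reproduces the *published phenotype
envelope*: the oxidation wall sits at $f = 1/3$ (an elemental fact — two
O2 per C2 acid), and the activation cost $c$ places the energy wall at
$f = 2/(2+c) = 0.70$, the published 7:3 quotient. Around this core, 640
decorative reactions in 40 self-contained metabolite groups (isomerase
chains, isoenzyme duplicates, some ATP-coupled) pad the network to full
scale; they are constructed cycle-free so pruning removes them all and
they cannot alter any optimum. The biomass composition is produced by the
real composition pipeline from synthetic measured slopes, in residual
nucleotide mode so its carbon closes exactly on the 18.2 mmol C/OD·L TOC
budget; organic components carry synthetic formulas
C<sub>2k</sub>H<sub>k</sub>O<sub>k</sub> chosen so every lumped synthesis
reaction balances exactly.

### Growth-series and composition simulators

`simulate_growth_experiment()` builds an exponential OD curve and then
*derives* acetate disappearance and cumulative O2 so that incorporated
carbon is exactly `incorporation_fraction` of uptake (default 0.35) and
respired carbon exactly `respiration_fraction` (default 0.63) at the
given RER (default 1.0 — the theoretical respiratory exchange ratio for
complete acetate oxidation). With zero noise the carbon-fate accounting
recovers the fractions to machine precision; with noise, Gaussian errors
are independent per channel (O2 noise on increments, truncated at zero to
keep the cumulative series monotone — a small bias accepted to keep all
generated series valid). Default conditions: 35 ml culture, initial OD
0.1, 40 mM acetate, sampled over ~100 h. The simulator does not model
autocorrelated drift, lag/stationary phases, evaporation, or sampling
volume loss; recovery tests therefore demonstrate estimator correctness
under the stated error model, not robustness to real-world artefacts.

`simulate_composition_samples()` draws `slope × OD + noise` panels
(truncated at zero) for the regression stages; parameter-recovery tests
require the fitted slope within three standard errors of truth at n = 20.

## Carbon-fate accounting

For each sampling interval: carbon uptake is twice the acetate
disappearance (two carbons per acetate — valid because stable-isotope
work showed no net inorganic-carbon fixation under these conditions);
incorporated carbon is ΔOD × volume × TOC slope; respired carbon is O2
consumed × RER. The unaccounted delta is defined as
`uptake − incorporated − respired` and therefore the ledger identity is
exact by construction, per interval and cumulatively. Intervals where
acetate *increases* are flagged and excluded from uptake with a warning
rather than silently clipped. The delta is reported neutrally: it may be
secreted carbon or methodological error; the package does not attribute
it. With RER = 1 and a complete-oxidation FBA solution, the LP's carbon
closure and the experimental ledger agree on respired carbon (tested).

## Problem sizes and tolerances used in the checks

The shipped test-and-acceptance workload was sized as follows: toy sweeps
at fraction step 0.01 (0.0025 where the optimality curve is compared to
closed forms, giving a 0.003 assertion width); reference-network sweeps at
81 × 21 cells (script) and 41 × 5 cells (tests); oracle cross-checks over
25 (uptake, maintenance) combinations at 10⁻⁶; noisy recovery at n = 30
growth samples and n = 20 composition samples with three-propagated-sigma
acceptance widths; balance tolerance 10⁻⁹ absolute; LP feasibility 10⁻⁷
after row scaling. Stoichiometric coefficients and element counts are
stored as doubles, not exact rationals: element counts are integers, the
coefficients in play are small rationals, and all committed balance
examples are exact in double arithmetic at these magnitudes; the 10⁻⁹
audit tolerance covers the residue.

## Known limitations

* The LP backend is dense; it is sized for networks of order 10³
  reactions (seconds per solve unpruned, milliseconds pruned), not for
  multi-compartment giants.
* No flux variability analysis, no alternate-optimum enumeration, no
  thermodynamic or integer constraints, no gene-deletion simulation.
* The SBML dialect is Level 2/3 core with notes-based annotations; the
  fbc extension is not interpreted beyond plain reversibility.
* The synthetic reference stand-in shares summary statistics and
  phenotype structure with the real reconstruction, not its biochemistry;
  conclusions about the real organism require the real network files.
* 2-sulfotrehalose osmolyte synthesis is excluded (not relevant under
  the modelled salt-in conditions), and carbon-fate attribution of the
  delta region is out of scope.
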