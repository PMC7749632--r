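---
title: "The virtual circular genome model in vcgsim: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The virtual circular genome model in vcgsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcgsim)
```

## The model

A virtual circular genome (VCG) is an abstract circular sequence of
length $L$ that exists physically only as an ensemble of short linear
oligonucleotides beginning and ending at every position on both strands.
`vcgsim` simulates the nonenzymatic replication of such an ensemble
inside a model protocell. The state of a simulation is a multiset of
oligonucleotide species — each a sequence with explicit 5′ and 3′ end
chemistry — plus fed small molecules (2-aminoimidazole-activated
monomers and 5′–5′ imidazolium-bridged dinucleotides) in a vesicle of
fixed volume, so that counts and concentrations are interconvertible.

Dynamics are organised around environmental cycles rather than
continuous-time kinetics: each cycle the ensemble is fully denatured (a
thermal/salt/pH spike), single-stranded fate chemistry applies, fed
species are replenished, and the pool re-anneals into one kinetically
trapped configuration in which reaction sites are classified and fired.
This cycle-synchronous design reflects the model's central premise that
productive configurations are transient and must be reshuffled by
repeated environmental fluctuations; it also makes every run exactly
reproducible from a master seed.

### Annealing into kinetically trapped configurations

Candidate duplexes are all maximal perfectly complementary runs of at
least `min_duplex` (default 2) base pairs between molecule pairs, in
every antiparallel alignment; internal mismatches end a run (they
contribute no energy), but mismatched or dangling flanks are allowed, so
mutant oligos still bind through their complementary cores. Each
candidate carries the Boltzmann weight $\exp((-\Delta G -
\Delta G_\mathrm{assoc})/RT)$, with $\Delta G$ the per-pair additive
duplex energy and $\Delta G_\mathrm{assoc}$ a translational association
penalty; every molecule also carries a unit-weight "stay unbound"
alternative. Annealing is a weighted race: items are realised in the
order of their Gumbel-perturbed log-weights (equivalent to sampling
without replacement proportional to weight), and each accepted duplex
locks its template positions and molecule roles. Strong duplexes
therefore tend to form first, weak two-base-pair contacts usually lose
to the unbound state, and the outcome is a sampled metastable
configuration rather than a free-energy minimum. The relative occupancy
of two binders competing for the same template stretch equals the ratio
of their Boltzmann weights (the association penalty cancels), which is
the property the test suite verifies against the two-state closed form.

Two design points deserve emphasis:

- **The association penalty.** A per-pair additive energy model with
  ~2.5 kcal/mol per base pair would otherwise predict that even
  dinucleotides bind essentially always, which is unphysical: forming a
  duplex costs translational entropy. By default
  $\Delta G_\mathrm{assoc} = -RT\ln(1/(V N_A))$, the cost of
  co-locating two molecules at single-molecule concentration in the
  vesicle volume $V$; concentration effects on duplex stability then
  emerge naturally through candidate multiplicity (an $n$-copy species
  contributes $n$ racing candidates, worth $RT\ln n$).
- **Role exclusivity.** A molecule is either bound as an oligo onto one
  template, or acts as template for one or more oligos, or stays free;
  branched multi-molecule networks and intramolecular hairpins are out
  of scope in this version. Open single-stranded stretches — gaps on
  templates and the unpaired 5′ tails of bound oligos — are available
  to initiation regardless of role.

### Reaction repertoire

Each annealed duplex presents up to two primers: the bound oligo, whose
3′ end extends along the template's free downstream positions, and
symmetrically the template strand itself when its own 3′ end is paired.
A primer with at least one free downstream position is an extension site
if the complementary bridged dinucleotide is in stock; with exactly one
free position the site is a *last-base* site (the dinucleotide can pair
only one base) and fires at `f_last` times the normal rate. A primer
abutting a 5′-activated downstream oligo at zero gap is a ligation
site. Open stretches of ≥ 4 nt seat two adjacent bridged dinucleotides
and form initiation sites that create templated trinucleotides (5′ ends
activated or plain with equal odds, a default the chemistry leaves
open). Extension is processive within a cycle: while the configuration
lasts, additions continue until a Bernoulli `p_ext` trial fails or the
overhang/substrate is exhausted, consuming one bridged dinucleotide and
releasing one activated monomer per added base. Errors occur per
incorporation with probability `eps` (a uniformly chosen wrong base),
after which the primer is stalled — its extension probability is
multiplied by `p_stall_after_mismatch` until one further success.

Off-template fates: 5′-2AI groups hydrolyse (`k_hyd`) and re-activate
(`k_act`) as a two-state chain with stationary activated fraction
$k_\mathrm{act}/(k_\mathrm{act}+k_\mathrm{hyd})$; strands cleave at
internal bonds (`p_cleave`) leaving a 5′-hydroxyl downstream product
(which can grow but never ligate onto an upstream oligo) and a
2′,3′-cyclic phosphate upstream product, which hydrolyses (`h_cp`) to a
2′-phosphate (inert for growth) or 3′-phosphate (extendable at the cost
of a pyrophosphate linkage that later re-cleaves with `p_pp`, the
downstream product reverting to a normal 5′-phosphate oligo);
incorporation of a chain terminator (`p_ara`) blocks a 3′ end
permanently; unbound oligos of length ≤ `cyc_len` cyclize away with
`p_cyc`; and duplexes with ≥ `dead_end_len` matched pairs never
denature, accumulating as inert material that division dilutes.

A strict nucleotide mass ledger runs across all of this: feed is the
only source, cyclization the only sink, and `step_cycle()` aborts on any
imbalance.

### Protocells, division and lineage statistics

Protocells divide by binomial segregation — every molecule, fed species
and inert duplex independently to a daughter with probability 1/2 — and
the lineage view follows one random daughter. A region covered by $N$
molecules is lost with probability $2^{1-N}$, the closed form behind
copy-number stability; at the default gradient a 12-mer class at ~1 µM
corresponds to ~3×10⁵ copies in a 10 µm protocell. The `mass_doubling`
trigger defines a generation as a doubling of the ensemble's nucleotide
mass; `every_k_cycles` imposes an environmental schedule instead (the
cap on cycles per generation also divides, since division is ultimately
imposed by the environment, not by replication progress).

### Gradient arithmetic

With class counts $c_k \propto r^{-k}$, growing every oligo by $m$
nucleotides (bottom classes replenished by initiation at their prior
inflow) multiplies every class by $r^m$; doubling therefore needs
$m = \ln 2 / \ln r$, i.e. one nucleotide on average at $r = 2$. The
same arithmetic read the other way — a stated average growth of two
nucleotides per doubling corresponds to $r = \sqrt 2$, not $r = 2$ — is
occasionally quoted inconsistently in discussions of this model;
`doubling_extension_requirement()` implements the closed form and leaves
the interpretation to the caller. The melting-stability coupling is
analogous: each added base pair contributes $|\Delta G_{bp}|$ (~2–3
kcal/mol) while each step down the gradient costs $RT\ln r$ in
concentration-dependent stability — 0.41 kcal/mol for a twofold step at
298 K (computed from $RT\ln 2$ at the configured temperature; a
frequently quoted rounder figure of ~0.3 kcal/mol corresponds to a lower
temperature than the default). In the constructed limit
$|\Delta G_{bp}| = RT\ln r$ the stability-versus-length profile is
flat: a constant duplex melting temperature independent of length.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `dG_bp` | −2.5 | kcal/mol/bp | midpoint of the 2–3 kcal/mol per-pair stabilisation range; pair modifiers rescale A:U, G:C, I:C |
| `temperature` | 298.15 | K | ambient annealing conditions |
| `ratio` (r) | 2 | — | reference gradient; dimers anchored at 1 mM so trimers sit at 0.5 mM and 12-mers at ~1 µM |
| `monomer_feed`, `bridged_feed` | 5, 1 | mM | lower range of concentrations required for efficient primer extension; chemostat set-points |
| `p_ext` / `p_lig` / `p_init` | 0.5 / 0.05 / 0.02 | per site per cycle | qualitative ordering: extension dominant, ligation slow and inefficient, initiation rare |
| `f_last` | 0.1 | — | ~10-fold last-base slowdown ("dramatic" but not absolute) |
| `eps` | 0 | per incorporation | fidelity studies raise it explicitly |
| `p_stall_after_mismatch` | 0.1 | — | post-mismatch extension is strongly disfavoured |
| `k_hyd`, `k_act` | 0.1, 0.1 | per cycle | continuous in-situ activation balancing hydrolysis; stationary activated fraction 1/2, matching the initialisation default `p_act0 = 0.5` |
| `p_cleave` | 0.001 | per bond per cycle | brief thermal spikes; cleavage slow relative to copying so that replication outpaces degradation |
| `h_cp`, `p_pp` | 0.1, 0.5 | per cycle | cyclic-phosphate hydrolysis slow; single-stranded pyrophosphate linkages extremely labile |
| `p_cyc`, `cyc_len` | 0.005, 3 | per cycle, nt | short oligos cyclize faster than long ones |
| `dead_end_len` | 12 | bp | duplexes at the top of the length range no longer denature |
| `min_duplex` | 2 | bp | the two-base-pair binding mode of bridged dinucleotides |
| `toehold_min`, `p_invade` | 3 nt, 0.5 | — | single-step toehold displacement of occluding strands |

All are exposed through `reaction_params()` / `energy_params()` and the
YAML run configuration.

## What the synthetic generator emulates — and what it does not

`generate_fixture_genome()` draws a random circular sequence (default
L = 16, the scale of the worked concentration ledger) with a
configurable purine bias, and `init_gradient_pool()` realises the full
fragment ensemble on the abundance gradient with stochastically rounded
molecule counts, activated 5′ ends at probability `p_act0`, and fed
stocks at their set-points. The default simulation vesicle is 50 nm
(hundreds of nucleotides, ~80 molecules), with 65 nm used for the
error-threshold experiment — small enough for exact molecule-level
simulation of every duplex and reaction, at the cost that the longest
length classes (10–12 nt, sub-single-molecule expectations) are present
only intermittently. Consequences to keep in mind when extrapolating to
µm-scale protocells: copy numbers per species are tiny, so segregation
and drift are far stronger than at realistic scale; chance
complementarity between unrelated fragments is proportionally more
consequential (a mispaired primer has fewer correct partners to
outcompete the wrong ones); and absolute growth per cycle is slow
because long templates are scarce. Passing tests demonstrate the
mechanisms and their arithmetic, not the absolute rates of a laboratory
system.

## Numerical choices

- Coordinates are 0-based modulo $L$; minus-strand placements are
  recorded by the plus-strand interval they pair with, so coverage from
  both strands shares one frame. Fragments may wrap the origin.
- Mapping is exact by default (`max_mismatch = 0`); coverage
  distributes a multi-mapping species' count equally over its exact
  placements, so total depth equals mapped mass.
- Sub-integer expected counts are resolved by seeded stochastic
  rounding (floor plus Bernoulli remainder), preserving expectations in
  tiny vesicles.
- The annealing race uses one Gumbel key per candidate and a single
  descending sweep; ties are measure-zero. Energies enter through a
  per-pair $\Delta G$ lookup, so variant alphabets (inosine, 2-thio-U)
  are pair-modifier entries, not new code paths.
- The gradient ratio is estimated by least squares on log counts
  versus length, with a delta-method standard error; at least three
  occupied classes are required.
- Reactions fire as Bernoulli trials per classified site in a random
  order, with resource re-checks at firing time (bridged stocks are
  finite and shared).
- All stochastic entry points accept a seed; named substreams derived
  from a master seed decouple fixtures, annealing, chemistry and
  division, and reruns are bit-identical.

## The error-threshold experiment

`error_threshold_experiment()` runs seeded lineages across an error-rate
grid spanning both sides of $1/L$ and tracks the nucleotide-weighted
fraction of oligos still mapping exactly to the circle. The frozen
study design: L = 16, a 65 nm vesicle, grid
{0.01, 0.03, 0.0625, 0.125, 0.25}, four lineages per grid point, three
division epochs of 200 cycles — a horizon over which cumulative
synthesis roughly equals the initial ensemble, i.e. about one full
distributed replication — and the pooled exact fraction (total exact
nucleotides over total nucleotides across lineages) as the estimator.
The decay of identity is monotone in `eps` within sampling error. Two
genuine behaviours of the model at this scale limit the sharpness of a
0.5-crossing threshold statistic, and we report them rather than hide
them: a floor of original and cleavage-derived fragments that are never
extended (blocked geometries, non-extendable 3′ ends) and therefore map
exactly forever; and, at high error rates, post-mismatch stalling that
suppresses turnover and so protects the remaining exact material.
Relatedly, even at `eps = 0` the ensemble slowly accumulates
single-mismatch variants through chance complementarity between
fragments from different parts of the circle — mispaired primers copying
the wrong context. This is an intrinsic error mode of small virtual
circular genomes (and the reason chance mispairing is expected to bound
their size): at L = 16 its effective rate is comparable to $1/L$, so
the simulated system sits near its error threshold by construction.

## Known limitations

- No intramolecular secondary structure, no branched three-strand
  complexes, and only single-step toehold invasion.
- The energy model is per-pair additive, not nearest-neighbour
  (calibrated NN tables do not exist for primordial chimeric polymers);
  an NN table would slot into the same per-pair lookup.
- 2′–5′ regioisomers, explicit Mg²⁺ dependence and sugar identity
  beyond the blocked-terminator state are not modelled.
- One circle per genome; multi-circle ensembles are future work.
- Simulation scale is tens of nanometres; µm-scale protocells are
  treated analytically (copy numbers, segregation closed forms), not by
  direct simulation.
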