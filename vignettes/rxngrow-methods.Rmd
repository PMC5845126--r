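---
title: "rxngrow: methods, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rxngrow: methods, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rxngrow` performs structure-based fragment growing in which every move is a
virtual chemical reaction. This vignette is the package's own account of the
model: what is computed, which knobs matter, what the synthetic fixtures do
and do not emulate, and where the method's conventions are choices rather
than ground truth.

## 1. The molecular model

Molecules are heavy-atom graphs with implicit hydrogen counts, formal
charges, kekulized integer bond orders and an aromatic flag per atom/bond.
Aromaticity uses one pinned perception model applied identically to parsed
molecules and patterns: candidate rings are the smallest rings (one per
cyclic bond), sizes 5–6 only, atoms from {B,C,N,O,P,S}; an atom
double-bonded into the ring system contributes one pi electron, a
single-bonded neutral N/O/S/P (or C⁻) contributes a lone pair, an exocyclic
double bond contributes nothing; 4n+2 makes the ring aromatic. This
deliberately small model handles the chemistry the rule database speaks
(benzenoids, pyridines, five-membered heteroaromatics, fused benzenoids) and
is *not* a general-purpose perceiver (no 7-membered aromatics, no global
pi-system analysis). Stereochemistry is parsed and dropped throughout:
matching and assembly are constitution-only, because rule application as
defined here has no stereo-propagation model.

Canonical keys come from BLISS canonical labeling on a bond-subdivided,
vertex-colored auxiliary graph (each bond becomes a vertex colored by
order/aromaticity). Colors are derived with locale-independent (radix)
string ordering, so keys — and everything seeded from them — are identical
across sessions and locales.

cLogP is a coarse Crippen-type atom-contribution scheme with a parameter
table pinned in `R/descriptors.R`. Absolute values are
implementation-relative (the upstream method named only "calculated
lipophilicity"); the package relies on ordering and on the strict `< 5`
filter semantics, never on agreement with any particular external logP.

## 2. Rule extraction

An atom of a mapped reaction is in the **reaction core** iff it is unmapped,
its map number is absent from the other side, or any tracked attribute
differs from its mapped partner: element, formal charge, aromatic flag,
heavy-neighbor count, or the multiset of (bond label, partner map) over
mapped neighbors. Hydrogen counts are not tracked directly — H changes at
reacting atoms always co-occur with neighbor/bond changes in this scheme.

**Moiety extension** grows the core breadth-first: extension passes through
atoms that are neither sp³ carbons nor aromatic, stops at (and includes) the
first sp³ carbon per direction, and pulls entire aromatic rings in before
stopping (fused systems are pulled ring-by-ring until closed). The stop
atoms — sp³ carbons and aromatic ring atoms — are the moiety's **open**
positions.

Matching a moiety is subgraph monomorphism with these semantics: every atom
must agree on element, aromatic flag and charge; *closed* atoms must also
reproduce the pattern's heavy degree and hydrogen count exactly; *open*
atoms accept arbitrary substitution, except that an sp³-carbon pattern atom
must land on an sp³ carbon (otherwise an acid's O–H would "match" the
alcohol slot through its carbonyl carbon). Hydrogens at open positions are
not compared because a moiety records the hydrogens of its *source*
molecule, not of the match site. One consequence worth knowing: a bare `C`
pattern means "an aliphatic carbon", not "any carbon".

Each moiety atom also records the valence it lost to excluded source
neighbors (its *excised* valence). At assembly this free valence is filled
by re-attached substituents, the rest by hydrogens — this is what makes an
ester rule extracted from ethyl acetate apply correctly to methanol, and a
nitroarene SNAr rule re-attach its nitro group.

Multi-product reactions record the product sharing the most mapped atoms
with the largest reactant as principal; small co-products (water, HBr,
boric acid) are retained in the rule text but never emitted as products.
Rules with more than two reactant moieties are rejected at database build:
growth steps are pairwise couplings or unimolecular transforms.

## 3. Conformers, alignment, scoring

**Conformers** are built by penalty-function distance embedding: restraints
for bond lengths (covalent radii, order-scaled), 1–3 distances from ideal
angles by hybridization (109.47°/120°/180°), all intra-ring pairs of
aromatic rings from a regular-polygon template (rings come out planar and
rigid), and a one-sided repulsion floor (0.78 × vdW sum) for non-bonded
pairs; BFGS minimizes from a seeded chain-walk start. Different seeds give
different torsional minima; ensembles are deduplicated by a rounded sorted
distance-matrix signature and sorted by strain. The ensemble is a pure
function of (molecule, k, seed). This is a stand-in for a force-field
conformer generator: it gets connectivity, rings, sterics and torsional
diversity right, but knows nothing of electrostatics, conjugation planarity
beyond rings (amides can pyramidalize), or true strain energies.

Inside the growth engine, a product's ensemble is generated from the
molecule alone — *not* seeded from coordinates inherited from the posed
reactant — so that a molecule reached by different routes always has the
same ensemble. That choice makes beam search, the exhaustive verifier and
the conformer cache mutually consistent; nothing is lost because the next
step, alignment, re-poses the core anyway. (`generate_conformers()` still
initializes near inherited coordinates when handed a `product_record`
directly.)

**Alignment** superposes the conformer's preserved-fragment atoms on the
fragment's reference pose: Kabsch least-squares start, then a short
Nelder–Mead polish of the six rigid parameters maximizing Gaussian-sphere
volume overlap (ρ = 2.7·exp(−2.418 r²/r_vdW²), ROCS-style cross term); the
reported overlap is the fraction of the fragment's self-overlap volume.
With symmetric fragments all symmetry-equivalent embeddings are tried and
the best kept — which is why a preserved fragment should be chosen
asymmetric if growth directions matter (see §5).

**Scoring** is a deterministic pairwise potential, more negative = better:
hydrogen bonds over ligand-donor/receptor-acceptor and converse pairs with
a piecewise-linear well (−1 on 2.6–3.2 Å, rising to 0 at 2.2 and 4.0 Å);
hydrophobic carbon–carbon contacts (−1 up to 4.5 Å, 0 beyond 5.5 Å); +5 per
heavy-atom pair closer than 0.8 × the vdW-radius sum; weights w_hb = 1.0,
w_ph = 0.2, w_cl = 1.0, all config-overridable. Units are scorer-native
("kcal/mol-like"); the original workflow used external docking energies
whose units are tied to that software, so the −0.1 group-efficiency
threshold here applies in scorer units and is configurable.

**Group efficiency** is read incrementally: GE = ΔE/Δheavy-atoms between
consecutive growth states, accepted iff strictly below −0.1. The per-pose
total E/N is available for diagnostics but plays no role in acceptance.
The **direction check** is the simplest falsifiable reading of "same
interaction direction": the new atoms' minimum distance to the target
anchor must strictly decrease relative to the previous state, and the
nearest new atom must be chemotype-compatible with the target (donor-capable
N/O for `hbond-donor` sites, N/O for `hbond-acceptor`, carbon for
`hydrophobic`, aromatic atom for `aromatic`). Angular cones were considered
and rejected as under-specified.

## 4. The growth engine

Targets are processed strictly in the user's order. Per target, each beam
state enumerates rule products, keeps per product the best-GE conformer
passing the direction check, accepts steps with GE < −0.1, and the top-B
states by (GE, energy) survive; a target is satisfied when a compatible new
atom lies within its `satisfied_radius`, and each target gets at most
`step_cap` (default 2) accepted steps — the cap is the guard against a
product immediately re-matching a rule and oscillating. B = 3 by default;
B = 1 reproduces the greedy keep-only-the-best-conformer behavior; B = full
width makes the search exhaustive over acceptable chains. Filters
(MW < 600, cLogP < 5, strict) are applied to the final list, not per step.
Ranking refines each pose by rigid + torsion coordinate descent on the
scorer (fixed sweeps, accept-only-if-lower, hence provably non-increasing)
and sorts by refined energy with ties broken by fewer heavy atoms, then key.

Every stochastic call is seeded from the master seed and the molecule's
canonical key, so identical config + seed gives byte-identical
`routes.json`. Routes are exported as ordered (rule, participant,
reactant-key, product-key) steps and are *replayed* through the synthesis
machinery before being written; a replay mismatch is an internal error that
aborts the pipeline.

## 5. The synthetic fixture world

`make_reaction_set()` returns nine fixed atom-mapped reactions (amide
coupling to alkyl and aryl amines, esterification, Williamson ether,
sulfonamide, Suzuki coupling, urea formation, SNAr amination, reductive
amination) — a miniature of the hundreds-strong classic-reaction databases
such pipelines use in production. `make_block_library()` returns ~50 blocks
with at least three per reactant-moiety class plus inert decoys, standing in
for a commercial catalog of thousands.

`make_pocket()` builds a pseudo-receptor around a **planted** product: the
seed `Oc1cc(Br)cc(N)c1` carries three meta handles (phenol, aniline,
aryl bromide); the planted route is anilide coupling with propionic acid,
Suzuki coupling with 4-methylphenylboronic acid, then Williamson
etherification with 1-bromopropane. Probes are placed from the final
product's aligned pose (a donor against the amide carbonyl; hydrophobic
probes along the acyl chain, over both faces of the distal ring, and along
the alkoxy chain) with a 3.2 Å self-clash guard. Three design rules keep
the planted route uniquely recoverable:

* the preserved fragment (`Oc1cccc(N)c1`) is *asymmetric* — a bare phenol
  ring is mirror-symmetric and alignment could flip the growth directions;
* each planted participant is the *largest* of its class in the pocket
  sub-library, so the planted product collects strictly more probe contacts
  than any competitor;
* the ether participants are pure alkyl bromides and the targets' kinds are
  (hbond-acceptor, hydrophobic, hydrophobic), so only the amide step can
  serve the first target and the route order is pinned by chemistry, not by
  luck.

Generation verifies, by exhaustive enumeration of the ≤ 3-step reachable
space (27 molecules here), that the planted product's refined energy is the
strict minimum, and fails loudly otherwise. The pocket's recommended config
uses 4 conformers per product (the pipeline default is 30) purely for
test-time budget; the planted margin (≈ 1.6 scorer units) is insensitive to
this at the fixture's scale.

What a green fixture run establishes: rule extraction, matching, assembly,
alignment, scoring, gating, beam search, filtering, ranking and route
replay compose correctly and deterministically. What it does not establish:
anything about real binding affinity, real pocket geometry, force-field
quality conformers, or the behavior of the method at commercial database
scale.

## 6. Numerical conventions and degenerate inputs

* Strictness everywhere: GE < −0.1, MW < 600, cLogP < 5, distance decrease
  in the direction check — all strict; boundary cases are rejected.
* Identity reactions (empty core) are an error at rule build; a
  disconnected core within one molecule extends from each component and
  unions the result.
* Valence checking rejects over-saturation against a standard table with
  charge adjustments; under-saturation (radical-like) is tolerated on input
  but never produced by assembly, whose hydrogen bookkeeping is exact.
* Conformer requests for rigid molecules return fewer distinct members
  (deduplication by distance signature); k = 1 returns exactly one.
* Alignment with a single-atom fragment reduces to translation; overlap is
  1 by construction.
* Seeds: the master seed must be a 32-bit integer; per-molecule seeds are
  derived by hashing the canonical key modulo 2³¹ − 1.

## 7. Known limitations

The scorer is not a force field and its units are not kcal/mol; refinement
is coordinate descent with a fixed budget, not minimization to convergence;
the conformer generator ignores electrostatics and amide planarity;
aromaticity perception is intentionally narrow; no tautomers, no
protonation states, no stereochemistry, no reaction conditions or yields
(the upstream method excludes these too); and the rank of a candidate among
*thousands* of commercial-database products is outside the reproducible
scope of the fixtures — only relative ordering within the toy space is
meaningful here.
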