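# rxngrow

Structure-based lead optimization with built-in synthetic accessibility.
`rxngrow` grows a query ligand inside a receptor pocket toward user-chosen
interaction sites, where **every growth step is the virtual application of a
reaction rule extracted from an atom-mapped reaction** — so each proposed
compound comes with a concrete synthetic route over a purchasable
building-block library, instead of being an arbitrary graph edit that a
chemist then has to figure out how to make.

It is aimed at computational chemists prototyping reaction-driven fragment
growing, and at method developers who need a fully deterministic, hermetic
test bed for such pipelines (the package ships a synthetic reaction set,
block catalog and pseudo-receptor pocket with a *planted*, exhaustively
verified optimum).

## The method

1. **Rule extraction.** For an atom-mapped reaction, the *reaction core* is
   the set of atoms whose attributes change between sides (element, charge,
   aromaticity, heavy-neighbor count, or the multiset of (bond order,
   partner map) over mapped neighbors). The core is extended outward to
   chemically meaningful *moieties*: extension passes through sp²/hetero
   atoms, stops at (and includes) the first sp³ carbon in each direction,
   and always pulls whole aromatic rings in. A rule = reactant moieties +
   product moiety + map-number correspondence.
2. **Virtual synthesis.** A molecule matching a reactant moiety is *clipped*
   (moiety removed, attachment bookkeeping kept); the product is clipped
   reactant + clipped participant + product moiety, joined through the map
   correspondence, valence-checked and kekulizable.
3. **Pose evaluation.** Up to *k* = 30 conformers per product (deterministic
   distance-geometry embedding), each rigidly aligned onto the preserved
   fragment of the query by Gaussian-volume overlap, then scored against the
   receptor with a deterministic pairwise potential
   (H-bond well −1 on 2.6–3.2 Å; hydrophobic C···C −1 up to 4.5 Å;
   +5 per clash; weights 1.0 / 0.2 / 1.0).
4. **Group efficiency.** A step from state *prev* to *new* is accepted iff

   GE = (E_new − E_prev) / (N_new − N_prev) < −0.1

   with N the heavy-atom count — i.e. every added heavy atom must buy at
   least 0.1 energy units. The best-GE conformer that also moves strictly
   toward the current interaction target becomes the next reactant; a
   configurable beam (default 3; 1 = greedy) generalizes the single-best
   choice.
5. **Final selection.** Candidates are filtered by MW < 600 g/mol and
   cLogP < 5 (strict, Rule-of-Five style), locally refined (rigid +
   torsion coordinate descent on the same scorer), ranked by refined
   binding energy, and exported with machine-replayable routes.

## Worked example

Grow the fixture seed (a 1,3,5-trisubstituted phenol with aniline and
aryl-bromide handles) inside the toy pocket toward its three targets
(hinge H-bond, aryl pocket, hydrophobic channel):

```r
library(rxngrow)

pocket <- make_pocket(verify = TRUE)        # exhaustively checks the planted optimum
seeds  <- find_seed_blocks(pocket$frag, pocket$library)
cands  <- grow(seeds, pocket$targets, pocket$db, pocket$library,
               pocket$receptor, pocket$frag, pocket$config)
cands  <- filter_candidates(cands, pocket$config)
ranked <- rank_candidates(cands, pocket$receptor, pocket$config)

top <- ranked[[1]]
cat(sprintf("rank %d  E = %.3f  MW = %.1f  cLogP = %.2f\n  %s\n",
            top$rank, top$energy, top$descriptors$molecular_weight,
            top$descriptors$clogp, write_smiles(top$mol, keep_maps = FALSE)))
cat(format_route(export_route(top)), sep = "\n")
```

prints

```
rank 1  E = -7.543  MW = 297.4  cLogP = 4.84
  c1(OCCC)cc(cc(c1)c2ccc(cc2)C)NC(CC)=O
seed: seed_trisub
  step 1: amide_aryl + acid_propionic
  step 2: suzuki_coupling + boronic_4me
  step 3: williamson_ether + bromide_propyl
  product: c1(OCCC)cc(cc(c1)c2ccc(cc2)C)NC(CC)=O  (E = -7.543)
```

`E = -7.543` is the refined receptor interaction energy in scorer units
(more negative is better); MW and cLogP pass the < 600 / < 5 filters; the
three steps are the pocket's planted route (anilide coupling, Suzuki
biaryl coupling, Williamson etherification), and
`replay_route(export_route(top), pocket$db, pocket$library)` rebuilds the
exact molecule from the seed — the route is not an annotation but a
verified synthesis plan over the rule database.

A config-driven CLI wraps the same pipeline:

```r
rxngrow_main(c("fixtures", "demo"))          # writes reactions.smi, blocks.smi, pocket.json, query.sdf
rxngrow_main(c("grow", "demo/config.json"))  # emits candidates.sdf + routes.json
```

## Layout

| Path | Contents |
| --- | --- |
| `R/mol.R`, `R/smiles.R`, `R/rings.R`, `R/molfile.R`, `R/pdb.R` | molecular graph, SMILES/SDF/PDB I/O, aromaticity + kekulization |
| `R/match.R`, `R/descriptors.R` | substructure matching, canonical keys, MW/cLogP |
| `R/reaction.R`, `R/rule_extraction.R` | mapped reactions, core → moiety → rule |
| `R/block_library.R`, `R/virtual_synthesis.R` | block library + rule DB, clip/assemble/enumerate |
| `R/conformers.R`, `R/pose_eval.R` | conformer embedding, overlap alignment, scorer, GE |
| `R/growth.R`, `R/cli.R` | beam-search engine, filters, ranking, routes, CLI |
| `R/fixtures.R` | synthetic reactions/blocks/pocket with planted optimum |
| `vignettes/rxngrow-methods.Rmd` | the methods vignette (model, knobs, limits) |
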