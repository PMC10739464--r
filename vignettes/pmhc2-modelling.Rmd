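---
title: "Template-based modelling of peptide-MHC class II complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based modelling of peptide-MHC class II complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

MHC class II molecules present extracellular peptides to CD4+ T cells. The
binding groove -- two alpha-helices over a beta-sheet floor -- holds a
9-residue segment of the peptide (the *binding core*), whose positions 1, 4,
6 and 9 (P1, P4, P6, P9) insert side chains into four conserved pockets.
Residues outside the core form the peptide flanking regions (PFRs), which
stay flexible and solvent-exposed. Experimental pMHC-II structures are
scarce relative to the diversity of alleles and peptides, so structures of
new peptide/allele combinations are routinely *modelled* from existing ones.

Two pieces of domain knowledge make this tractable:

1. **MHC folds are highly conserved**, so a structure solved for one allele
   is a usable scaffold for another ("pan-allele" modelling).
2. **Peptides anchor into the groove at fixed core positions**, so the
   geometry of the template's anchor contacts transfers to the target as
   distance restraints.

`pmhc2model` implements this homology-driven, anchor-restrained strategy
end to end: curated template handling, sequence-based template selection,
restraint derivation, conformer generation and ranking, and a backbone
L-RMSD benchmark harness. The conformer engine and its pseudo-energy are
this package's own construction (no external modelling engine is called),
and the binding-core predictor is a pluggable interface with a transparent
built-in fallback.

## Pipeline

```{r}
library(pmhc2model)

db <- make_fixture_set(4, seed = 1, dir = "templates")  # or read_template_db()
ens <- model_pmhc2(db, peptide = "AAAWRTYARQMVHHK",
                   alpha_seq = chain_sequence(db[[2]]$complex, "M"),
                   beta_seq = chain_sequence(db[[2]]$complex, "N"),
                   anchors = c(4, 7, 9, 12), n_models = 20, seed = 1)
tidy(ens)        # per-model pseudo-energies and ranks
autoplot(ens)    # energy vs rank
```

### Template set curation

Structures are standardized to the field's chain convention -- alpha chain
`M`, beta chain `N`, peptide `P` (class I keeps its heavy chain as `M` and
beta2-microglobulin as `B`) -- with the peptide renumbered contiguously from 1.
The curated set keeps peptides of 7 to 25 residues and discards complexes
containing the DM chaperone (which distorts the groove) or presenting the
CLIP placeholder peptide. DM and CLIP detection is by exact substring match
against packaged, user-extensible sequence lists; the shipped DM signatures
are synthetic markers, and production template sets should supply curated
HLA-DM sequences. Modified residues (MSE, SEP, PTR, ...) map to their parent
amino acid through a packaged table; residues outside that table raise a
typed error rather than being modelled with a wrong identity, mirroring the
known failure mode of peptides with exotic chemistry.

### Template selection

Candidate templates are ranked by MHC sequence identity against the target
chains, computed by global Needleman-Wunsch alignment with BLOSUM62 and
affine gaps (open 11, extend 1, the protein-BLAST defaults; MHC chains are
globally homologous, so global identity is the appropriate statistic). The
two chain identities are aggregated as their mean by default -- the paperwork
of which aggregate to use is genuinely open, so `min` is exposed as an
option. Identity ties are broken by the *core-anchored peptide alignment
score*: the two 9-mer cores are paired column-to-column without gaps, flanks
extend outward position-by-position, the shorter flank is padded with
terminal gaps, and non-gap columns are summed under PAM30 (a shallow matrix
suited to short, similar peptides). Gap columns score 0, not a penalty, so
flank-length differences are neutral. Remaining ties resolve by resolution,
then template id, making the ranking total and deterministic.

### Anchor restraints

The four anchor residues of the template core are scanned against the
receptor: every heavy-atom pair within the contact cutoff (default 5.0 Å,
the standard interface-contact distance; the source protocol does not state
one) becomes a harmonic distance restraint whose target is the observed
template distance. All heavy atoms of the anchor residue are restrained (not
only side-chain atoms; this too is exposed through the restraint table,
which users can filter). Restraints are re-indexed to target numbering
through the core-anchored alignment; an anchor with no contact under the
cutoff warns, and a fully contact-free template is an error.

### Conformer generation

The target core adopts the template core conformation exactly (backbone
copied; side chains copied where the residue type matches, truncated to CB
otherwise -- backbone L-RMSD is the quality metric of record, and full
rotamer repacking would add machinery without touching it). Flank residues
are grown outward one at a time with ideal bond lengths and angles (NeRF
internal-coordinate placement). Backbone torsions come from the aligned
template residue where the alignment provides one (jittered by 6 degrees,
k = 32 candidates per residue) and from a packaged Ramachandran-favoured set
otherwise (jitter 10 degrees). Candidates are scored by soft-sphere clash
against the receptor plus a quadratic pull toward the aligned template CA
(weight 10); the best candidate is kept. This is the same use of template
information a restraint-satisfaction engine makes implicitly: with no
template information the flanks are de novo loops, and self-recovery to
sub-Angstrom accuracy would be impossible.

Each model then relaxes under a transparent three-term pseudo-energy:

* **bonded** -- harmonics (k = 100) on all intra-peptide atom pairs within
  2.9 Å at build time (covalent bonds and 1-3 pairs), referenced to the
  built geometry;
* **clash** -- soft-sphere repulsion `(r0/d)^12` with `r0 = 3.0` Å between
  peptide atoms two or more residues apart and against receptor atoms within
  10 Å of the start conformation, capped below 2.0 Å so the gradient stays
  finite;
* **restraint** -- flat-bottom harmonic `((d - target)/max(sd, 0.01))^2`
  active when `|d - target| > sd`, weight 10.

Minimization is monotone gradient descent with adaptive step control: a
step is accepted only if the total decreases, so the energy trajectory is
non-increasing by construction; it stops at the step budget, a gradient
norm below 1e-3, or step collapse. In the default `fixed_core` mode every
atom of the core residues is frozen (the spatial restraints are then exactly
satisfied because the template geometry is copied); `flex_core` lets the
core move within the restraints' standard deviation `sd` (Å), the dial
between the rigid and restraint-flexible protocols. `sd = 0` uses an
`sd` floor of 0.01 Å purely to avoid division by zero.

Ensembles default to 20 models; model *i* draws all randomness from seed
`seed + i`, so ensembles are bit-reproducible and single-model failures are
isolated (recorded, excluded from ranking). Models are ranked ascending by
final total pseudo-energy. The pseudo-energy is a ranking device, not a
binding-affinity estimate.

## Evaluation

Model quality is backbone ligand-RMSD (L-RMSD): superpose model and
reference on the *receptor* backbone (chains M + N; a groove-domain-only
fit is exposed as an option), then measure RMSD over peptide backbone atoms
(N, CA, C, O) with no re-fitting. Three regions are reported: *core* (the 9
core residues), *flanking* (residues N-terminal of P1 and C-terminal of P9;
the anchors themselves belong to the core -- the boundary convention is
ambiguous in common usage, so this package fixes and documents it), and
*whole*. With no flank residues the flanking value is `NA`, not 0, so
9-mer cases do not dilute flank aggregates. The three values satisfy
`whole^2 * n_total = core^2 * n_core + flanking^2 * n_flank` exactly.

The benchmark harness runs leave-one-out over a template set: each entry is
removed, re-modelled from the remainder, and compared against its own
structure; per-case best-sampled and top-k-ranked metrics, median/mean/sd
aggregates, and the top-k success rate (fraction of cases below a threshold,
default 2 Å for the top 5) are reported. "Oracle anchors" (cores read from
the target structure) isolate modelling quality from core-prediction
quality. When a cross-length template donates its receptor, the evaluation
fits on the shared receptor residues.

## The synthetic fixture generator

Real template sets cannot ship with a package, so every quantitative
statement the tests make is grounded in generated fixtures with known
geometry: two ideal poly-alpha helices flank the groove axis, a flat
synthetic strand per chain lies under the peptide as a floor proxy, and the
peptide runs along the axis in an extended beta conformation with anchor CB
atoms oriented floor-ward, guaranteeing every anchor a receptor contact
within 5 Å and no contact tighter than ~2.9 Å. Sequences are caller-chosen,
so identity rankings and PAM30 scores can be engineered exactly;
`perturb_fixture()` adds displacements whose ground-truth RMSD contributions
are known in closed form.

What the fixtures do **not** emulate: real MHC fold geometry, pocket shape
and chemistry, side-chain packing, crystallographic noise, missing atoms
and alternate conformations at scale. Passing the self-recovery and
near-duplicate benchmarks therefore demonstrates that the machinery is
correct and self-consistent -- core transfer is exact, restraints are
satisfied, flank rebuilding recovers template-supported conformations --
not that any particular accuracy will be achieved on experimental
structures, which additionally depends on template availability and
binding-core prediction quality.

Problem sizes used by the shipped tests and the acceptance script are
deliberately desk-scale: 10-case fixture sets, 3-5 models per case in the
benchmarks (the ensemble-size default of 20 is exercised separately), and a
60-step refinement budget -- chosen as the smallest sizes at which the
properties under test are meaningful.

## Numerical and design notes

* **Alignment engine**: pairwise global alignment is delegated to
  `Biostrings::pairwiseAlignment`; tests verify it against an independent
  exhaustive-enumeration oracle (all gapped alignments, affine costs). The
  oracle check is exhaustive for short sequences and sampled across all
  length combinations up to 6x6 -- full enumeration over the 4-letter
  alphabet would be ~30 million pairs.
* **Identity denominator**: matches over aligned columns (double-gap columns
  cannot occur in an optimal pairwise alignment).
* **Altlocs** collapse to the highest-occupancy variant, ties by label
  order. Hydrogens and waters are dropped at parse time.
* **Superposition** is Kabsch (SVD with determinant correction, proper
  rotations only); degenerate near-planar atom sets are handled by the
  determinant sign. Tests cross-check against a quaternion-search oracle.
* **Tie-breaks** are all deterministic and documented: smallest window start
  for core prediction, lexicographic ids in ranking and allele assignment,
  first-encountered minimum in candidate selection.
* **Degenerate inputs**: peptides shorter than 9 residues carry no core and
  are kept in template sets but never selected as templates; glycine can
  appear anywhere except fixture anchor positions (its missing CB is the
  designated contact atom there).

## Limitations

Receptor conformational change is not modelled (the template receptor is
copied rigidly); side chains are not repacked; the pseudo-energy has no
electrostatics or solvation and must not be read as a binding affinity; the
built-in pocket-profile core predictor is a fallback, not a trained
predictor -- wrong cores shift the modelled register exactly as wrong
external predictions would, which is why the predictor interface is
pluggable and user anchors take precedence.
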