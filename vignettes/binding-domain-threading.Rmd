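---
title: "Characterizing DNA-binding domains and threading genomic targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing DNA-binding domains and threading genomic targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbdthreadr)
```

## The problem

Some proteins that are not classical transcription factors — heme
oxygenase-1 (HO-1) in its heme-free, nuclear-translocated apo form is the
motivating case — appear to bind double-stranded DNA through surface
regions that were never annotated as DNA-binding domains (DBDs).
`dbdthreadr` implements a desk-scale structural-bioinformatics workflow
for characterizing such putative DBDs and predicting which genes they can
bind:

1. **Contacts.** Given a modeled protein–dsDNA complex, find every DNA
   fragment position that makes direct heavy-atom contact with the
   protein, classified as protein-*backbone* versus protein-*side-chain*
   contact. Candidate domains whose fragment has fewer than three DNA
   contact positions are discarded.
2. **Energies.** Given a per-position mutational scan of the docked
   fragment — the change in Gibbs free energy ΔΔG (kcal/mol) of the
   complex when each fragment position is mutated to each of the four
   nucleotides — read off the *consensus binding sequence*: the
   per-position minimum-ΔΔG nucleotide, i.e. the most stable sequence.
3. **Threading.** Slide a contact-restricted profile (consensus
   nucleotide required at contact positions, wildcard elsewhere) along
   each gene sequence *and its complement simultaneously*, count
   compatible sites, and rank genes by binding-site **density** —
   sites per base pair — so long genes do not win by length alone.

Upstream of step 1, the package can also chain short docked dsDNA
backbone fragments into extended fragments by linking terminal backbone
atoms (3′ O3′ → 5′ P) that lie within bonding distance on both strands.

## The model and its conventions

**Contact model.** A contact record (residue *r*, base *b*, class *c*)
exists iff some heavy atom of *b* lies within a cutoff of some heavy atom
of *r* in class *c*. The protein backbone atom set is {N, CA, C, O, OXT};
all other protein heavy atoms are side chain, so glycine can only make
backbone-class contacts. Hydrogens are ignored throughout; alternate
locations are reduced to the highest-occupancy conformer. The default
cutoff is **4.5 Å**, the conventional van-der-Waals heavy-atom contact
threshold; it is a parameter (`cutoff`) because the structural literature
uses values from 3.5 to 5 Å, and all printed-table worked examples in the
test-suite are cutoff-independent (they start from transcribed contact
lists rather than detection).

**Strand convention.** A fragment of length *L* has strand-A positions
1..*L* and strand-B positions *L*+1..2*L*, antiparallel, with position
*i* on strand A paired with 2*L*+1−*i* on strand B (for *L* = 10, A1 ↔
B20). Published contact tables can carry fragment-global numbering
outside this range, so contact-map validation only requires positive
positions by default; the strict 1..2*L* numbering is enforced where
threading actually needs it, in `compile_profile()`.

**Consensus.** Because the per-position energies enter additively, the
per-position argmin is also the global minimum over all 4^*L* sequences
(the test suite checks this against exhaustive enumeration). Ties within
`tie_tolerance` (default 1e−9 kcal/mol) are broken A &lt; C &lt; G &lt; T
and always flagged, so degenerate matrices are auditable rather than
silent. When strand-B energy rows are present, the strand-B minimum at
the paired position is complemented onto strand A; on disagreement the
lower of the two minima wins and a warning is raised. At an exact tie the
strand-A choice is kept *silently*: a complemented copy of a tied row
maps, through the lexicographic tie-break on strand-B letters, to a
different strand-A letter, and warning there would flag every degenerate
row of a perfectly consistent matrix.

**Threading.** `strict` mode (default) demands the consensus nucleotide
at every contact position — the most literal reading of "compatible"
— while `threshold` mode allows any nucleotide within `epsilon`
kcal/mol of the row minimum, for sensitivity analyses; `epsilon = 0`
reduces to strict. `N` never matches. Every window start is counted
independently (no overlap deduplication; no such rule is defined for this
workflow), except that a window matching in both orientations — possible
only for palindromic profiles — is one physical site and is counted once,
with strand "±". Coordinates are 0-based half-open internally and in BED
output. Gene "length" is the length of the supplied sequence: whether
that sequence is a gene body, a promoter-padded locus or anything else is
deliberately the caller's choice, since region choice is a scientific
decision upstream of this package.

**Ranking.** density = sites / length, sorted descending, ties broken by
`gene_id` ascending for determinism. `top_n` (default 10) marks the head
of the table; the full table is always returned.

## What the synthetic generator emulates — and what it does not

The generators in `simulation_config()` / `simulate_bundle()` produce
every input the pipeline consumes, with ground-truth manifests:

- **Gene sets** (`simulate_genes()`): i.i.d. background with
  P(G) = P(C) = `gc_background`/2, defaulting to 0.41 (a mammalian
  genome-wide average), with consensus copies planted at recorded
  coordinates and strands, non-overlapping and at least *L* from the
  ends. The `zero_background` option rewrites accidental background
  matches (one mutated contact position per offending window, always
  outside planted sites) until the only matches are the planted ones.
  Default scale: 20 genes of 1–5 kb — large enough that background hits
  occur at realistic rates for a 5-contact profile, small enough that the
  full test-suite runs in seconds.
- **Energy files** (`simulate_energy_file()`): the designated nucleotide
  holds each row minimum, with the other three nucleotides at least
  `margin_ddg` (default 1.0 kcal/mol) above it plus half-normal noise of
  sd `noise_ddg` (default 0.1, keeping margin ≥ 3·noise). Setting the
  margin to zero produces a fully tied, adversarial matrix.
- **Complexes** (`simulate_complex()`): minimal heavy-atom residues and
  bases placed on a widely spaced slot grid so each intended (residue,
  base, class) pair sits exactly at its target distance (default 3.0 Å)
  while every unintended protein–DNA atom pair is ≥ ~20 Å apart — far
  beyond cutoff + 2 Å. Backbone contacts are realized through backbone
  atoms, side-chain contacts through side-chain atoms, and unused
  mandatory atoms are parked in separate protein and DNA regions.
- **Fragment clouds** (`simulate_fragment_cloud()`): idealized collinear
  duplex backbones with a 3.4 Å rise and 1.6 Å O3′–P junction gaps
  (the covalent bond length), exposing exactly the terminal atoms that
  chaining inspects.

These fixtures are deliberately *not* realistic structures or genomes: no
dinucleotide composition structure, no nucleosome or promoter geography,
no protein fold, no base stereochemistry. Passing tests therefore
demonstrate that the algorithms are correct on inputs with known truth —
contact detection equals an all-pairs distance scan, threading equals a
naive window scan, planted parameters are recovered exactly — not that
predictions on real structures are biologically valid. On real data the
dominant uncertainties live upstream, in the docking poses and the
force-field ΔΔG values this package consumes as given.

## Numerical and design choices

- **Docking energetics are out of scope.** Fragment *poses* are ingested
  from PDB files and fragment *chaining* is geometric; a pluggable score
  hook would be the natural extension point, but no statistical potential
  is reimplemented here.
- **Fragment chaining** links a 3′ end to the nearest 5′ end within
  `max_gap` (default 2.0 Å ≈ covalent O3′–P at 1.6 Å plus tolerance) on
  both strands with consistent antiparallel directionality; each fragment
  accepts at most one predecessor and one successor, output fragments are
  maximal, and a closed loop raises an explicit cycle error. Total base
  pairs are conserved (the output is a partition of the input).
- **Energy-file dialect.** No public format exists for per-position
  mutational-scan output, so the package defines a documented TSV
  (`domain_id`, `strand`, `position`, `ddG_A..ddG_T`) with strict
  validation: missing columns, duplicate rows and non-numeric cells are
  reported with the offending row number.
- **Degenerate inputs** are first-class: empty contact maps summarize to
  zero counts; genes shorter than *L* scan to zero hits (logged, not an
  error); all-N genes match nothing; all-zero energy matrices parse and
  flag every position tied.
- **Determinism.** All generator randomness flows from one integer seed,
  split per artifact by fixed offsets; fixed inputs give byte-identical
  pipeline outputs (the rank-table writer formats densities explicitly to
  avoid locale/precision drift).

## Problem sizes used in the checks

The bundled checks run at desk scale, chosen to exercise every code path
in seconds: oracle-equivalence sweeps use 200 random contact fixtures
(≤ 8 residues × ≤ 6 bases), 200 random profile/gene pairs (profiles of
4–12 bp, genes ≤ 500 bp), exhaustive consensus enumeration up to
*L* = 6, reverse-complement invariance on 100 random genes, and full
synthetic runs with 20 genes of 1–5 kb. All quantities reported by
`scripts/acceptance.R` are recomputed from scratch on each run.

## Known limitations

- Contact detection treats all heavy atoms equally; no hydrogen-bond
  geometry, base-specific atom chemistry, or water-mediated contacts.
- The strict profile is a hard match — no position weight scoring at
  contact positions beyond the threshold band (the Boltzmann weight
  matrix from `to_weight_matrix()` is exported for interoperability, not
  used in matching).
- Ranking by density assumes site counts scale meaningfully with the
  supplied sequence length; very short sequences make densities noisy.
- The i.i.d. background of the generator understates the match rate in
  GC-rich isochores relative to real genomes — relevant because
  low-ΔΔG consensus sequences tend to be GC-rich.
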