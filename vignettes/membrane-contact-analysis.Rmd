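---
title: "Protein-lipid contact analysis with memlens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-lipid contact analysis with memlens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(memlens)
library(dplyr)
```

## Scientific background

Peripheral membrane proteins are recruited to cell membranes largely through
electrostatic interactions with anionic lipids. Phosphatidylinositol
4,5-bisphosphate (PIP2) is the paradigmatic example: although it makes up only
a few percent of the inner-leaflet lipid, its headgroup carries three
phosphate groups and a charge of roughly -4 to -5 at physiological pH, so
basic protein residues (arginine, lysine) bind it strongly and selectively.
Phosphatidic acid (POPA) is a second, smaller anionic lipid that competes for
the same basic patches.

memlens analyses molecular dynamics trajectories of such systems. Its
questions are the standard ones of membrane-recruitment studies:

* Which protein residues touch which lipid species, and how often?
* How persistent is each interaction (binding lifetime), and how many
  individual lipid molecules does a residue engage (partner count)?
* Which part of the PIP2 headgroup is contacted — the 1-, 4- or 5-phosphate,
  and in which protonation state?
* Do residues and lipids organise into connected interaction clusters?

## Contact definition and numerical choices

A **contact** is a pair of one protein heavy atom and one lipid heavy atom
whose distance is *strictly below 3.5 Å*. Three choices deserve comment:

* **Heavy atoms only.** Hydrogen positions are the least reliable part of a
  force-field trajectory (and absent from united-atom models), so the
  definition uses non-hydrogen atoms exclusively. `read_topology()`
  classifies hydrogens by element when the PDB provides it, falling back to
  the atom-name convention (a leading `H` after stripping digits).
* **Strict inequality.** A pair at exactly 3.5 Å is *not* a contact. This
  matters for reproducibility: analyses that disagree at the boundary can
  drift apart by whole contact counts over long windows.
* **Minimum-image convention.** Simulation boxes are periodic; the distance
  between two atoms is the minimum over all periodic images. For the
  orthorhombic boxes supported here this separates by axis:
  each coordinate difference is reduced by the nearest multiple of the box
  edge. Triclinic cells are rejected rather than silently mis-measured.

The search itself uses a cell list (spatial hash) implemented in C++: space
is divided into cells at least as large as the threshold and only the 27
neighbouring cells of each atom are examined. This is an *exact* algorithm,
not an approximation — the test suite compares it against a brute-force
all-pairs reference on random systems. Because the per-axis minimum image is
only valid when the threshold does not exceed half the shortest box edge,
`find_contacts()` refuses thresholds beyond that bound.

```{r}
# strictly-below semantics at the threshold
sep <- function(d) {
  topo <- build_topology(tibble::tibble(
    atom_name = c("CA", "P"), element = c("C", "P"),
    residue_name = c("ALA", "POPA"), residue_number = c(1L, 1L),
    chain_id = c("A", "L")
  ))
  coords <- rbind(c(5, 5, 5), c(5 + d, 5, 5))
  nrow(find_contacts(new_frames(coords, c(20, 20, 20)), topo))
}
c(at_3.5 = sep(3.5), at_3.4999 = sep(3.4999))
```

## PIP2 binding-site classification

The PIP2 headgroup is an inositol ring with phosphates at positions 1, 4 and
5. At physiological pH one of the 4- or 5-phosphates carries a proton, so the
lipid is modelled as two species: one protonated at P4, one at P5 (CHARMM
residue names SAPI24/SAPI25, abbreviated PI24/PI25 in the synthetic systems).
`build_site_map()` assigns every PIP2 heavy atom to one of six categories:

* `P1np` — the 1-phosphate, never protonated (it bridges to the glycerol);
* `P4p` / `P4np` — the 4-phosphate, protonated or not depending on species;
* `P5p` / `P5np` — likewise for the 5-phosphate;
* `OTHER` — inositol ring, glycerol backbone and acyl chains.

Each phosphate group is its phosphorus plus terminal oxygens and (by default)
the ring-side ester oxygen. `site_ratios()` then distributes the contact
instances of a window over the six categories as percentages; the categories
partition the heavy atoms, so the percentages always sum to 100.

```{r}
sys <- make_toy_system(
  n_frames = 1,
  planted = data.frame(
    frame = 1, residue = 1:4, lipid = c(3, 3, 3, 1),
    atom_name = c("P4", "OP42", "OP43", "P5")
  )
)
contacts <- find_contacts(sys$frames, sys$topology)
site_ratios(contacts, build_site_map(sys$topology))
```

## Per-residue statistics and block averaging

`residue_table()` produces the package's central summary: one row per
residue, ranked by the window-mean number of contact pairs with the chosen
species, with residues below `min_mean = 1` suppressed. Alongside the mean it
reports:

* **Block-averaged standard error.** Consecutive trajectory frames are
  highly correlated, so the naive standard error of per-frame values is far
  too small. Instead the series is cut into `n_blocks` contiguous equal
  blocks (default 5, matching the common practice of analysing a 1000 ns
  window as 5 × 200 ns) and the SE is the standard deviation of the block
  means divided by `sqrt(n_blocks)`. For the series 1..10 in 5 blocks this
  gives mean 5.5 and SE `sqrt(2)` — a hand-checkable oracle used in the
  tests. Windows that do not divide evenly are an error unless the caller
  opts into truncating the tail (`allow_ragged = TRUE`).
* **Binding lifetime**: the percentage of window frames in which the residue
  has at least one contact with the species.
* **Partner count**: distinct lipid molecules contacted anywhere in the
  window (`"cumulative"`), or at most simultaneously in any one frame
  (`"simultaneous"`).
* **Domain label**: residues up to `n_term_end` (default 325, the PX + PH
  region of human phospholipase D2) are labelled `N`, the rest `C`.

```{r}
block_stats(1:10, n_blocks = 5)
```

## Interaction networks

`build_network()` condenses a contact table into an undirected bipartite
graph: residue nodes on one side, individual lipid molecules on the other,
with an edge wherever the pair's window-mean contact count reaches
`min_weight` (default 1, i.e. at least one contact pair on average per
frame). Connected components of this graph are the interaction *clusters*;
component labels are deterministic (size descending, ties by smallest node
id) so exports are reproducible. `export_network()` writes GraphML (full
attributes), SIF or a tidy edge-list CSV; GraphML and SIF load directly into
Cytoscape.

## Synthetic data: what it is and is not

Real binding trajectories are microseconds long and gigabytes large, so the
package carries a synthetic-data module in which the ground truth is *known
by construction* rather than estimated.

`make_composition()` builds the bilayer manifest of the study conditions: an
asymmetric bilayer with 600 lipids per leaflet whose inner leaflet carries
the anionic lipids. At 10% PIP2 the lower leaflet is PIP2 60 / cholesterol
180 / POPC 90 / POPE 150 / POPA 60 / PSM 60; at 1% it is 6 / 210 / 144 /
174 / 6 / 60; the outer leaflet is PIP2- and POPA-free (0 / 210 / 240 / 30 /
0 / 120) in both conditions. Hydration is 144 waters per lipid. Other
percentages interpolate the anionic counts and rebalance POPC/POPE so the
leaflet total stays at 600.

```{r}
make_composition(10)$leaflets
```

`make_toy_system()` generates a topology and trajectory with *planted*
contacts: a short extended protein chain and coarse lipids (headgroup atoms
with CHARMM-style names plus a few tail beads) on a jittered grid. For every
planted (frame, residue, lipid) triple, one lipid atom is placed at exactly
the requested distance (default 3.2 Å) from a protein heavy atom —
optionally across the periodic boundary, so the unwrapped separation is
nearly a full box length while the minimum-image distance is 3.2 Å. All
*non*-planted protein-lipid pairs are kept at least threshold + margin
(3.5 + 0.5 = 4.0 Å) apart, and the generator verifies this guarantee with an
all-pairs sweep before returning. Analysis of the trajectory must therefore
recover the planted ledger exactly — no more, no fewer, no different pairs.

Two realism limits are deliberate:

* The lipids are *not* physical molecules — a PIP2 stand-in has 21 heavy
  atoms, enough to exercise the full site map, but no realistic geometry,
  and the protein is an extended chain of 5-heavy-atom residues. The
  generator tests bookkeeping and numerics, not force-field physics.
* The planted distance must stay in a narrow feasible band (roughly
  3.13-3.5 Å with the default geometry): a much closer planted atom would
  also approach the *neighbouring* protein atoms, violating the exclusion
  guarantee. The generator detects and rejects such infeasible requests
  rather than producing ambiguous ground truth.

`make_schedule_trajectory()` lifts this to whole schedules (which residue
binds which lipid with how many pairs in which frame), and
`make_study_system()` produces the package's reference scenario: a scaled
composition plus a seeded schedule mixing permanently bound residues,
a residue alternating between two PIP2 partners, intermittent binders and a
POPA binder.

## A worked example

```{r}
sys <- make_study_system(pip2_percent = 10, n_frames = 50, seed = 1)
contacts <- find_contacts(sys$frames, sys$topology)
residue_table(
  contacts,
  species = "all", n_blocks = 5,
  site_map = build_site_map(sys$topology)
)
```

The means, SEs, lifetimes and partner counts above follow exactly from
`sys$schedule`; the site-ratio columns reflect which PIP2 atoms the schedule
touched. The same pipeline is available from the command line via the
`memlens` script (`simulate`, `contacts`, `stats`, `network` subcommands),
which round-trips through on-disk PDB/DCD files.

```{r}
net <- build_network(contacts, min_weight = 1)
glance(net)
```

## File formats

`write_system()` emits a PDB topology (fixed-width ATOM records, with
residue names up to four characters and a CRYST1 box record) and either a
CHARMM-dialect binary DCD — Fortran-framed records with per-frame unit-cell
blocks, readable by bio3d, MDAnalysis, mdtraj and VMD — or a multi-model
PDB. `read_frames()` accepts both and refuses triclinic cells. Frame times
are assigned as frame index × `frame_interval_ns` (default 0.24 ns per
frame, i.e. roughly 4 frames per ns of the usual saving cadence).
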