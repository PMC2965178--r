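---
title: "Random-walk reference-state potentials: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-walk reference-state potentials: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwpot)
```

## The statistical model

A knowledge-based pair potential converts frequency statistics of solved
structures into energies through the inverse Boltzmann relation: for atom
types $\alpha, \beta$ at distance $R$,

$$E(\alpha,\beta,R) \;=\; -kT\,
  \ln\frac{N_{obs}(\alpha,\beta,R)}{N_{exp}(\alpha,\beta,R)},$$

with $kT \equiv 1$ throughout this package (only rankings and ratios of
energies matter for model selection, so the temperature scale is
irrelevant). Everything interesting lives in the reference count
$N_{exp}$ — the pair count expected when no specific interaction acts.

### The random-walk reference state

This package models the reference as an ideal polymer chain whose nodes
map to residues. In the Gaussian (random-walk) limit, the displacement
across $n$ links has the radial density

$$P(R \mid n) = 4\pi R^2
  \left(\frac{3}{2\pi n \lambda}\right)^{3/2}
  e^{-3R^2/(2n\lambda)},$$

a proper density for every $n$ with $\langle R^2\rangle = n\lambda$ (both
asserted by quadrature in the test suite). A chain of $N$ residues
realises separations $n = 1..N-1$; beyond that the contribution is exactly
zero. The aggregate reference shape is

$$P_{RW}(R; N) = \sum_{n} P(R \mid n),$$

and the trained energy is anchored at the cutoff $R_0$, where pair
interactions are taken to vanish:

$$E_{RW}(\alpha,\beta,R) = -\ln
  \frac{N_{obs}(R)/N_{obs}(R_0)}{P_{RW}(R)/P_{RW}(R_0)}.$$

Because the chain reference concentrates less probability at short
distances than an ideal gas (at 3 Å its cutoff-normalised ratio is ~0.057
versus ~0.075 for the $\,(R/R_0)^{1.61}$ gas reference), the resulting
potential is steeper at short range — the feature that sharpens the
energy gap between well-packed and clashing conformations.

### Aggregation over separations

Two aggregation shapes are implemented, because the choice is genuinely
open: `"uniform"` sums $P(R|n)$ with equal weight over $n$, and
`"multiplicity"` weights separation $n$ by the $N-n$ residue pairs that
realise it — the exact marginal distance law of a random-walk chain. The
package default is uniform; the multiplicity variant is what the
synthetic-chain self-consistency analysis uses, since it is the law the
generator provably samples from. Overall constants cancel in the anchored
ratio, so only the shape over bins matters, and the two variants differ
only mildly there. Both are exposed (`train_rw(weighting =, n_min =)`)
so their effect can be measured rather than argued about. When training
on ensembles whose pairs are filtered at `min_separation`, `n_min` should
match that filter; for real structure libraries the uniform default over
all separations follows the model as published.

### The orientation term

Side-chain packing is directional. Each residue contributes up to three
*vector pairs*: a side-chain triple (18 residue types — all but GLY and
ALA) and two backbone triples, (CA, N, C) and (CA, C, O), defined for
every residue — 20 types. A triple $(X_0, X_1, X_2)$ spans the frame
$\hat z = \widehat{X_0 X_1}$, $\hat x$ the Gram–Schmidt complement of
$X_0 X_2$, $\hat y = \hat z \times \hat x$. The relative orientation of
two triples A, B is coded by

* the direction of $B_0$ in A's frame (26 sphere bins),
* the direction of $A_0$ in B's frame (26 bins),
* the torsion $A_1$–$A_0$–$B_0$–$B_1$ (4 bins of $\pi/2$),

giving $26 \times 26 \times 4 = 2704$ bins. The sphere partition is 2
polar caps ($\theta < \pi/6$, $\theta > 5\pi/6$) plus 3 latitude bands cut
into 8 azimuth sectors opening at $\phi = \pi/8$ (the last sector wraps
through $2\pi$). Its reference probabilities are analytic area fractions
— caps $(1-\cos\frac{\pi}{6})/2$, equatorial sectors $1/16$, mid-band
sectors $(\cos\frac{\pi}{6}-\cos\frac{\pi}{3})/16$ — and the torsion
reference is $1/4$ per bin, so the 2704-bin reference is a product of
three normalised factors. Counting runs over *contacting* residue pairs
(any heavy-atom pair strictly under 10 Å) at sequence separation ≥ 2, and

$$E_{orient}(A,B,O) = -\ln\frac{N_{obs}(A,B,O)}{N_{tot}(A,B)\,p_{ref}(O)}.$$

A geometric note: the signed IUPAC dihedral is invariant under reversal
of its four atoms, so swapping A and B exchanges the two direction bins
but *preserves* the torsion bin. The mirrored bookkeeping and the
symmetry tests rely on this identity.

### The hybrid score

$$E_{RWplus} = E_{RW} + w_{orient}\,E_{orient}, \qquad w_{orient} = 0.1 .$$

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `lam` | 460 | Å² | squared Kuhn length $b^2$; sets the chain scale of the reference ($b = 21.4$ Å) |
| `R0` | 15.5 | Å | interaction cutoff and anchoring point ($E(R_0)=0$) |
| `dR` | 0.5 | Å | distance bin width (31 bins) |
| `min_separation` | 2 | residues | smallest \|i−j\| counted/scored; excludes intra-residue and consecutive pairs |
| `cap` | 10 | kT | energy for unobserved bins of observed pairs; bounds all entries |
| `contact_cutoff` | 10 | Å | strict heavy-atom contact threshold for the orientation term |
| `w_orient` | 0.1 | — | weight of the orientation term in the hybrid |

`lam`, `R0` and `w_orient` are the published constants of the method;
this package treats them as configuration, and deliberately ships no
re-optimisation loop (the original tuning ran against large external
decoy collections that are out of scope here).

## Numerical choices

* **Bins are half-open** $[k\,dR, (k+1)\,dR)$; a pair exactly at $R_0$ is
  not counted, a contact at exactly 10 Å is not a contact. Azimuth
  sectors and torsion bins open at their lower edge.
* **Shell integration** of the reference uses 16-point Gauss–Legendre per
  0.5 Å shell; a dense midpoint refinement agrees to $10^{-4}$ relative
  (tested). Midpoint rules drift near $R = 0$ where the $R^2$ factor
  bends sharply.
* **Anchoring fallback**: if a pair has no counts in the top bin, the
  anchor ratio pools the outer 2 Å, then the whole range; pairs never
  observed at all are uninformative and score a flat 0. Each fallback is
  reported via a message.
* **Unobserved-bin cap** of +10 kT keeps $-\ln 0$ finite while dominating
  typical favourable energies of a few kT.
* **Degenerate geometry**: collinear atom triples (frame undefined) and
  coincident vector-pair origins are skipped with a log entry rather than
  propagating NaNs; residues missing the atoms of a definition simply
  contribute no instance.
* **Ranking ties** in decoy reports break deterministically by decoy
  name.
* **Coordinates are rounded to 0.001 Å** by the generators, which makes
  PDB round-trips bit-exact — the same convention the tests rely on.

## What the synthetic generators emulate — and what they do not

`make_training_set()` builds chains whose nodes take iid isotropic
Gaussian steps with mean-square `lam`, so the displacement over $n$ links
is exactly the Gaussian-chain law the reference integrates. This is a
deliberate choice over fixed-length steps: an exact freely-jointed chain
deviates from its own Gaussian limit at short distances for small $n$
(the two-step chain has density $\propto R$ near zero, the Gaussian limit
$\propto R^2$), and the generator's purpose is to realise the reference
law so that training must return zero energies up to counting noise. All
atoms of a residue sit at its node with 0.05 Å scatter — far below the
bin width, so the atom-pair law equals the node law. These structures are
*statistical* stand-ins: they have no excluded volume, no secondary
structure, no realistic bond geometry, and a 21 Å step is not a protein's
inter-residue distance. Passing self-consistency on them validates the
estimator and the reference mathematics, not biological realism.

`generate_fixture()` is the opposite trade: an idealised, self-avoiding
backbone with standard bond lengths/angles and seeded coil torsions, plus
compact algorithmic side-chain stubs whose vector-pair triples are always
well-conditioned. It produces compact, contact-rich structures for
scoring and decoy tests, but its side-chain geometry is schematic — tests
passing on fixtures say nothing about rotamer-level realism.

Perturbation decoys (`make_decoy_set()`) add iid Gaussian coordinate
noise, giving a controlled RMSD ladder. Real decoys have correlated,
physically plausible errors; the funnel observed on a noise ladder is a
necessary sanity property, not a benchmark result.

## Statistical form of the self-consistency checks

"Energies vanish within counting noise" is operationalised with care:

* The anchored log-ratio of a bin with $O_k$ observed counts and anchor
  count $O_K$ has variance $\approx 1/O_k + 1/O_K$.
* Merged symmetric types (e.g. the shared PHE CD1/CD2 type) carry two
  atoms per residue, so one residue-pair encounter contributes
  $m_\alpha m_\beta$ *correlated* counts; the variance scales by that
  factor and the band widens accordingly.
* With ~16,000 bins tested simultaneously, a per-bin 3σ bound is
  *expected* to be exceeded ~0.27% of the time under a true null, and its
  maximum fluctuates with the seed. The acceptance checks therefore
  assert the null-calibrated family-wise form: violation fraction below
  1% and no bin beyond 5σ. The same logic fixes the sphere-partition
  Monte Carlo band at 4σ across its 26 simultaneous bins.

## Problem sizes

The shipped checks run at desk scale, chosen so the full suite and the
acceptance script each finish in a few minutes on one CPU: 200 chains of
50 residues for self-consistency, 150 for bias recovery, 100 near-native
training conformations and a 200-decoy ladder for the funnel and
native-recognition statistics. These sizes give the bias and funnel
effects z-scores far beyond their thresholds while keeping every run
reproducible from a single seed.

## Known limitations

* Single-chain scoring only; multi-domain and interface statistics are
  out of scope, as are mmCIF input and NMR multi-model handling beyond
  the first model.
* The 158-type partition reproduces the canonical count via nine
  symmetric merges, but the historical partition it follows is not
  published as a table; the typing is therefore written out by
  `write_typing_table()` and stamped into every saved potential, and
  tables from a different partition are refused on load.
* The exact side-chain triples and frame axes of the orientation term are
  conventions (any fixed convention yields a self-consistent potential);
  they are shipped as an editable definitions table rather than asserted
  to be *the* canonical choice.
* The built-in TM-score is a simplified implementation with fixed residue
  correspondence, intended for fixtures; published comparisons should use
  the canonical external program through the quality-table input.
* Potentials trained on the synthetic generators are test instruments.
  Scientific use requires training on a curated experimental structure
  library via `train_rw()`/`train_orientation()` or the CLI.
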