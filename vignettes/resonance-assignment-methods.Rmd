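---
title: "Automated resonance assignment from 4D HCNH spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated resonance assignment from 4D HCNH spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chains4d)
```

## The assignment problem

Two 4D experiments drive the method. The HC(CC-TOCSY(CO))NH experiment
correlates each backbone amide (15N, HN) with the aliphatic 13C-1H pairs of
the *preceding* residue (i-1); the 4D HMQC-NOESY-HSQC (HCNH NOESY)
correlates an amide with every spatially close aliphatic CH, dominated by
intraresidue (i) and sequential (i-1) contacts. All peaks sharing one amide
root resonance form an *amino-acid index group* (AAIG) — the unit that gets
mapped onto the protein sequence. Once each AAIG is placed, its TOCSY
frequencies are atom-typed, transferred to the NOESY spectrum, and the
remaining gaps are filled from *common NOEs*: cross-peaks that the amides of
residues i and i+1 share because both report on residue i's aliphatic
atoms.

## Correlated chemical-shift statistics

Amino-acid typing rests on two-dimensional probability density maps of
correlated 13C-1H shifts, one per (amino acid, atom type). Each map is a
Gaussian kernel density estimate over reference observations
\((H_i, C_i)\):

\[
G(H_0,C_0)=\frac{1}{2\pi n h_H h_C}\sum_{i=1}^{n}
 \exp\!\Big(-\tfrac12\Big[\tfrac{(H_i-H_0)^2}{h_H^2}+
 \tfrac{(C_i-C_0)^2}{h_C^2}\Big]\Big).
\]

Bandwidths use Scott's factor \(n^{-1/6}\). The factor alone is
dimensionless, so each dimension multiplies it by the sample standard
deviation to obtain ppm units; a single-observation map falls back to the
display bin sizes (0.04 ppm 1H, 0.2 ppm 13C). Evaluation is always the
exact kernel sum — the binned grid exists only for display and for the
normalization check (`density_grid()` integrates to 1 within 1e-3).

The package ships a parametric table of per-atom-type Gaussian means and
standard deviations consistent with published BMRB aliphatic ranges
(`shift_gaussians_synthetic.tsv`; the filename marks it as a synthetic
stand-in for a re-referenced experimental compilation, which the same
reader accepts). `default_stats_library()` samples 150 observations per
atom type from it, deterministically.

**Percentile filter.** The common-NOE step only considers atom-type
candidates whose density lies "inside the q-th percentile region" of the
map (default q = 80). The cutoff is rank-based over the map's own data
points: with q = 80 exactly 80% of the data points pass. This is
data-driven and grid-independent; note that it deliberately rejects the
lowest-density 20% of even *correct* candidates — the price of refusing
decisions when the correct option may be absent.

## Amino-acid typing

For a TOCSY AAIG with observed pair set CCS, the posterior over types is

\[
P(\mathrm{AA}\mid \mathrm{CCS})=
\frac{P(\mathrm{CCS}\mid \mathrm{AA})\,P(\mathrm{AA})}
     {\sum_{\mathrm{AA}'}P(\mathrm{CCS}\mid \mathrm{AA}')\,P(\mathrm{AA}')}.
\]

\(P(\mathrm{CCS}\mid\mathrm{AA})\) is the best atom-type combination: pairs
whose carbons differ by at most 0.2 ppm may be grouped into a methylene
(its probability is the geometric mean of the two pair densities), the
(grouped) units are assigned injectively to the amino acid's atom types,
and the product of densities is maximized over all such combinations. A
spin system with more pairs than an amino acid can carry scores zero.
Ties between equal-probability combinations resolve deterministically in
favour of backbone CA/CB assignments (slots are tried in topology order).

Design choices the source material left open:

* **Prior.** \(P(\mathrm{AA})\) is the frequency of each type among
  residues *followed by a non-proline*: a TOCSY AAIG reports position
  i-1, and prolines contribute no amide root, so that is exactly the
  population an AAIG can represent.
* **Z-score.** Ranked predictions carry a Z-score computed on the natural
  logs of the nonzero posteriors; the per-round cutoff controls how many
  alternatives enter peptide generation. The top-ranked prediction is
  always retained, so spin systems with abnormal shifts can still be
  mapped.
* **Posterior floor.** Inside the mapping rounds, retained non-top
  predictions must also exceed a small absolute posterior (1e-4). Log-scale
  Z-scores otherwise retain types with posteriors of 1e-80, and such
  "predictions" can assemble internally consistent but wrong placements in
  the permissive late rounds.

## Sequential connectivities, chains, and mapping

A connectivity is established when the TOCSY frequencies of one AAIG are
found (within tolerance) among the NOESY frequencies of another AAIG with
a different root; its **occupancy** is matched/total TOCSY frequencies.
Matching tolerances default to 0.04 ppm (1H), 0.4 ppm (13C), 0.2 ppm
(15N), 0.04 ppm (amide 1H) — typical digital resolution of sparsely
sampled 4D spectra; all are configurable. Chains are simple paths through
the connectivity digraph (maximum length 6), each carrying
\(P(X)=\prod_k P(\mathrm{occupancy}_{k\to k+1})\); the occupancy ratio
itself serves as \(P(\cdot)\), since only monotonicity is required.

Chains become peptides via the Cartesian product of each member's retained
type predictions (capped at 2000, highest posterior product first), and
peptides are placed on the sequence by an ungapped Needleman–Wunsch fitting
alignment under BLOSUM90; placements with any mismatch are discarded. The
alignment score is normalized to (0,1] as
\(S_\mathrm{align} = \mathrm{logistic}(\mathrm{raw}/L)\) so that the
per-position assignment score
\(S(X)=P(\mathrm{AA}\mid\mathrm{CCS})\cdot P(X)\cdot S_\mathrm{align}\)
multiplies commensurate factors, and confidence scores sum \(S(X)\) over
all chains proposing an AAIG at a position.

**Contigs and consensus.** Aligned chains of length L merge into contigs
wherever AAIG series and offsets overlap by exactly L-1; a contig stops
rather than re-admit an AAIG it already contains, and chains that merge
with nothing are discarded as spurious. A position is accepted only when
(a) every covering contig proposes the same AAIG, (b) that AAIG is the
strict confidence-score maximum at the position, and (c) the position is
also that AAIG's best-scoring position. Condition (c) is this package's
own tightening: without it, an AAIG whose true position temporarily fails
consensus can be accepted at a shifted position it fits weakly. Ties are
always resolved by *not* assigning — the method favours a low error rate
over coverage.

**Iteration.** The default schedule runs chain lengths 6, 5, 4, 3 with
Z-cutoffs 0, -0.5, -1, -1 and occupancy floors 0.5, 0.4, 0.3, 0.3; the
last round repeats until it adds nothing. After each round, mapped AAIGs
are restrained: their prediction collapses to the mapped residue type and
connectivities contradicting sequence adjacency are deleted. Assignments
are never revoked.

## Atom assignment

TOCSY frequencies of every mapped AAIG are typed with the residue type
fixed by the mapping; grouped methylene protons share the mean carbon
shift and are named in decreasing proton-shift order (assignments are not
stereo-specific). Assignments transfer to the NOESY spectrum from the last
residue backwards — intraresidue peaks first, then sequential — each peak
taking at most one label, closest scaled match first.

Missing atom types are then sought among common NOEs: per residue,
NOESY intensities are normalized to the strongest peak of the spin system,
peaks below 0.1 are left out, unassigned peaks of amide i are matched to
unassigned peaks of amide i+1, and each match is scored per candidate type
as \(\mathrm{density}\times(100\times\mathrm{intensity}^2)\) subject to
the 80th-percentile filter. The quadratic intensity transform favours
methyls, whose intraresidue amide NOEs are strong; for a methylene the
score product of a grouped peak pair is used and grouping is preferred
when available. The NOESY-only scenario reuses exactly this machinery with
externally fixed amide assignments and every atom type missing.

On merge conflicts TOCSY-derived shifts win over NOESY-derived ones,
mirroring their lower observed error rates.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the algorithm
exploits, with ground-truth labels for every peak:

* True shifts are drawn from the same density maps the classifier uses
  (kernel-smoothed resampling); amides from N(119, 4.5) / N(8.3, 0.55)
  ppm. Root pairs closer than one tolerance-scaled unit are resampled:
  resolving truly overlapped amides is explicitly out of scope, so the
  generator does not produce them (they are still *detected* and warned
  about by the clustering).
* Per non-proline position i: TOCSY peaks for each aliphatic CH of residue
  i-1 (present with probability 0.9 by default), NOESY peaks for residue
  i's own CH (0.99) and residue i-1's CH (0.89), the latter further
  thinned for the atom types known to fade sequentially (Lys CD/CE, Arg
  CD, Met CE, and more mildly Leu CG, Ile CG1).
* Jitter decomposes into a resonance-level offset per (atom, spectrum) —
  shared by the two peaks of a geminal methylene, which observe a single
  carbon frequency — plus a small per-peak picking error (0.02 / 0.002
  ppm). Modelling the full 0.1 ppm carbon jitter as independent per peak
  would push a sixth of methylene pairs past the 0.2 ppm grouping
  threshold, a failure mode real spectra do not exhibit.
* Spurious peaks (5% by default) are added to the NOESY list only,
  uniformly over the occupied shift ranges: they stand in for long-range
  NOEs and artifacts, which are NOESY physics; TOCSY lists are clean
  (a separate `p_tocsy_noise` knob exists). No long-range NOEs are
  generated explicitly — the assignment logic only exploits intra and
  sequential contacts, so everything else acts as noise anyway.
* Intensities are log-normal (sdlog 0.4) with a 3x boost for intraresidue
  methyls.

What passing tests on this generator do *not* show: performance under
genuinely overlapped amide roots, under systematic referencing errors,
under structured (secondary-structure-dependent) NOE absence, or with
experimental peak-picking artifacts. The generator's jitter is Gaussian
and its noise uniform; real spectra are less polite.

Near-duplicate CH pairs inside one spin system are merged at a quarter of
the matching tolerance (keeping the strongest peak): duplicate picks of one
resonance scatter only by picking noise, while genuinely distinct atoms —
Val and Leu prochiral methyl twins in particular — routinely sit within the
full matching tolerance and must not be fused.

## Evaluation conventions

`evaluate_assignments()` scores carbon-type entries: correct means an
equivalent carbon of the same residue (prochiral methyl pairs may swap)
within 0.4 ppm. Mapping completeness is reported over *mappable*
positions: maximal runs of at least four consecutive amide-bearing
positions, because a contig needs two overlapping minimum-length (L = 3)
chains and shorter proline-flanked islands are unreachable by
construction. Recovery bookkeeping counts carbons of typed residues that
lack a TOCSY entry and asks how many gained a common-NOE entry.

Expected behaviour at the benchmark scale used throughout the tests
(120-residue proteins, 10% TOCSY dropout, 5% spurious NOESY peaks, five
seeds): mean mapping completeness above 95% with zero mapping errors,
aliphatic carbon error rates of 0–2%, methyl error rates below 5%.
Common-NOE recovery of deleted TOCSY assignments runs at roughly 45–70%
with near-zero error: its ceiling is the product of NOE presence rates
(0.99 × 0.89), the intensity threshold, and the percentile filter — which
by construction passes at most ~80% of correct candidates and less for
fresh draws — so high recovery fractions are not attainable under this
scoring, only high precision. The NOESY-only scenario assigns roughly
55–65% of all aliphatic carbons at an error rate of a few percent; problem
sizes (120 residues, 150 reference observations per density map) were
chosen so a full run completes in seconds.

## Numerical and degenerate-input conventions

* Density evaluation is exact summation; batch evaluation stacks all maps
  into one vectorized pass (`density_all_maps()`), with identical results.
* Matching boundaries are closed (a difference equal to the tolerance
  matches).
* Empty record sets, empty sequences, inconsistent NH tables, out-of-range
  percentiles and non-positive tolerances raise errors; parse errors name
  the offending line.
* All randomness is seeded; re-running any stage with the same inputs and
  seed produces byte-identical output files.
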