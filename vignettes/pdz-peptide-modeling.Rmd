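---
title: "Template-based modeling and contact-potential scoring of PDZ-peptide interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based modeling and contact-potential scoring of PDZ-peptide interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdzthread)
```

## The model

PDZ domains recognise the extreme C-terminus of their partner proteins —
typically the last four to six residues, written in the P-register with P0
the C-terminal residue, P-1 the one before it, and so on. Specificity
classes are traditionally written in this register (class 1 `X-phi-X-phi`,
with `phi` any hydrophobic residue), which is why everything in this package
is anchored at P0.

`pdzthread` predicts PDZ-peptide binding without any training on binding
data, by combining two ingredients:

**Template-based complex modeling.** The working assumption is that backbone
variation across PDZ domains and across their bound peptides is small: when
two PDZ domains are superposed, their bound peptides superpose well too.
Under that assumption a peptide-bound model of an apo domain can be built
rigidly: superpose a peptide-bound (holo) template domain onto the apo
structure and move the template's peptide with it (`graft_peptide()`). Any
query sequence is then *threaded* through the grafted peptide
(`thread_peptide()`): residue identities are replaced, geometry is kept,
registration is at the C-terminus. The modeled length is capped by the
template peptide's length; since most PDZ recognition motifs are about five
residues, that cap rarely binds in practice.

**Residue-pair statistical scoring.** The binding energy of a modeled
complex is

\[ E \;=\; \sum_{(i,j)\,:\; d_{ij} < 4.5\,\text{\AA}} e(a_i, a_j), \]

summed over all receptor-peptide residue pairs whose minimum any-atom
distance is strictly below 4.5 Å, with `e` a symmetric 20x20 contact
potential (more negative = stronger). Contact potentials of this family are
derived from contact frequencies in solved structures normalised against a
reference state; the Betancourt-Thirumalai (BT) variant uses a Thr-like
reference molecule, which keeps hydrophilic interactions on a sensible
scale (its signature is a near-zero Thr row). A residue-level sum is crude
compared with all-atom energies, but it is orders of magnitude faster,
which is what makes genome-scale screening of a proteome's C-termini
feasible; the score is treated as a classifier statistic, not as a
quantitative free energy.

## The bundled contact matrix

The package ships
`inst/extdata/bt_style_contact_potential_synthetic.tsv`, a *synthetic*
reconstruction of the BT potential, and `load_bt_matrix()` says so in its
documentation. The reconstruction is built as
\( e(a,b) = -g_a g_b + \kappa q_a q_b \) (plus a small deterministic jitter
making all 210 unordered-pair values distinct), with `g` a contact
propensity anchored at \(g_{\text{Thr}} \approx 0\) and `q` the formal
charge, \(\kappa = 0.35\). This reproduces the published potential's units
and range (about \([-1.35, +0.34]\) in RT-like units), its Thr-row
reference-state behaviour, hydrophobic/aromatic attraction, like-charge
repulsion and attractive salt bridges — but not its exact digits. All
structural and chemical invariants are enforced by the test suite; every
scoring function accepts a user-supplied 20x20 table, so the genuine
published matrix drops in unchanged via `load_bt_matrix(path)`.

## Superposition and its parameters

`superpose()` performs a least-squares (Kabsch, SVD-based) fit of
alignment-mapped C-alpha pairs, with the reflection case handled by sign
correction so the rotation is always proper (determinant +1, tolerance
1e-6). Fold-level structural aligners superpose on a common core rather
than on every residue; as a deterministic stand-in for that behaviour the
fit iteratively discards aligned pairs deviating by more than twice the
current RMSD and refits, stopping at convergence or at a floor of 20 pairs
(never below 3). In the high-identity regime where templates are actually
selected the trimming is almost always inert; it exists to keep a stray
divergent loop from dominating the fit. Degenerate inputs are explicit:
fewer than three mapped C-alpha pairs is an error, collinear points produce
a warning and a best-effort fit.

Sequence alignment uses global Needleman-Wunsch with BLOSUM62 and affine
gap penalties (open 11, extend 1) — the standard protein defaults — and
identity is defined over aligned columns only, making it symmetric.
Template selection maximises this identity; ties are broken by lower
superposition RMSD, then lexicographic template id, so library builds are
bit-reproducible.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| contact cutoff | 4.5 (strict `<`) | Å | the any-atom residue-contact convention used to define both the binding pocket and scored contacts |
| binder-call threshold | -2.11 | score units | the operating point at which the balanced benchmark reports its confusion statistics; treated as a raw contact-potential sum, not normalised per contact |
| gap open / extend | 11 / 1 | BLOSUM62 score | standard protein alignment defaults |
| trim factor / floor | 2 x RMSD / 20 pairs | — | deterministic core-focusing stand-in for a fold aligner |
| `max_mismatch` | 0 (0-2 allowed) | residues | proteome matching: exact by default; "a few mismatches" is exposed as an explicit 0-2 knob rather than one fixed policy |
| hydrophobic P0 set | A C F I L M V W Y | — | covers the `phi` positions of the canonical class motifs; configurable because the constraint is stated only as "hydrophobic" |
| equal-sample subsets | 100 | subsets | enough for stable means at desk scale; the repeat count is not dictated by the protocol |
| peptide auto-detection | shortest chain ≤ 12 residues | residues | holo PDB files do not label the peptide; 12 comfortably covers C-terminal ligands while excluding domains |

The score orientation is fixed: lower = stronger predicted binding, and a
record is called positive at threshold `t` when `score <= t` (inclusive).
Contacts involving nonstandard (`X`) residues are skipped and counted, not
errors, because real PDB files contain them.

## Benchmarking machinery

ROC curves sweep every distinct score as a threshold; the trapezoid area
equals the Mann-Whitney pair statistic with ties counting one half (the
test suite checks this identity exhaustively on small random instances).
PR curves use trapezoid integration over recall, with the zero-recall
endpoint carried back from the first real point — no interpolation scheme
is canonical there, and the choice is documented rather than hidden.

Real non-binder data are scarce, so score sets are typically imbalanced.
Two balancing strategies are provided: `equal-sample` (average over 100
random balanced subsamples) and `binder-partition` (split the majority
binders into `ceiling(n_b/n_n)` disjoint subsets, each paired with all
non-binders, and average). Both are seeded and reproducible. With equal
class sizes both collapse to the plain AUC.

Confusion statistics at a cutoff follow the defining formulas exactly
(sensitivity = TP/(TP+FN), FPR = FP/(FP+TN), specificity = 100 - FPR,
PPV = TP/(TP+FP), accuracy = (TP+TN)/total, F1 = harmonic mean of
precision and recall); on balanced classes accuracy is algebraically the
mean of sensitivity and specificity, which the acceptance checks exploit.
The packaged 43-domain benchmark table (domains with at least five binders
and five non-binders each) and its summary statistics ship as plain TSV
fixtures under `inst/extdata/`.

## What the synthetic generators emulate — and what they do not

`make_toy_complex()` builds a two-strand groove with C-alpha/C-beta
pseudo-atoms at controlled separations, so the contact map is known in
closed form from the geometry; it emulates *contact bookkeeping*, not PDZ
folds. `make_apo_copy()` applies a known rigid motion (plus optional
Gaussian coordinate noise) and returns the truth transform, exercising
superposition and grafting against an oracle. `make_score_set()` draws
class-conditional Normal scores, for which the expected ROC-AUC is
\(\Phi\!\big((\mu_n-\mu_b)/(\sigma\sqrt2)\big)\) in closed form; its
defaults emulate the balanced benchmark design (290 per class, class means
straddling -2.11 symmetrically, separation tuned to an expected AUC of
0.79). `make_toy_proteome()` generates random proteins with planted or
avoided C-terminal 5-mers so match results are decidable by construction.

Passing tests on these fixtures demonstrates that the geometry, scoring,
curve and matching machinery is correct; it does **not** demonstrate
predictive accuracy on real PDZ domains, which depends on template quality,
side-chain packing and the genuine potential. A full-scale benchmark on
real phage-display and literature non-binder data requires the complete
human template library and external interaction datasets and is out of
scope here; the published per-domain results are packaged as reference
fixtures instead.

Problem sizes in the test and acceptance runs were chosen for a
single-CPU desk machine: 500 random ROC instances (n ≤ 20 per class)
against the exhaustive pair-count oracle, 10^4 random rigid transforms
against a 15-point Kabsch fit, 1000-entry toy proteomes against the
brute-force Hamming scan, and 2000-per-class Normal score sets against the
closed-form AUC (within three Hanley-McNeil standard errors).

## Design choices in open territory

* **Side chains.** The reference pipeline rebuilds side chains with a
  rotamer library before measuring all-atom contacts. `pdzthread` instead
  scores *positional threading*: contacts are measured once on the template
  complex's geometry and query residues are scored through those fixed
  contact positions. This is deterministic and dependency-free, and it is
  consistent with the potential being residue-level — the information a
  rotamer would add is below the resolution of a 20x20 contact matrix. An
  external side-chain builder can be applied to the written PDB models and
  the rescored coordinates fed back in.
* **The -2.11 cutoff** is interpreted as a raw contact-potential sum (not
  per-contact normalised), matching how scores are tabulated where the
  cutoff is reported.
* **Peptide self-contacts** are excluded: only receptor-peptide pairs are
  scored, per the contact definition used throughout.
* **Whole-domain vs core superposition** before peptide transfer is not
  uniquely specified anywhere; the trimming heuristic above is flagged as a
  stand-in, and with `trim_factor = Inf` the fit uses all aligned pairs.

## Known limitations

* Rigid grafting cannot capture induced fit; domains whose recognition
  depends on conformational flexibility will be scored poorly, and that is
  a property of the approach, not a bug in the implementation.
* Internal (non-C-terminal) peptide binding and tandem-PDZ supramodules are
  out of scope.
* The bundled contact matrix is a labelled synthetic reconstruction (see
  above); absolute score values with it are not comparable to published BT
  scores, although orderings of chemically distinct peptides are.
* The PDB reader is deliberately minimal: `ATOM` records only, altloc
  blank/'A' with first occurrence winning, one model at a time; mmCIF and
  full NMR-ensemble handling are not goals.
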