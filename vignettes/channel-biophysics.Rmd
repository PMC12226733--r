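---
title: "Models and methods: polyamine block, bi-ionic permeability and ligand-site rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: polyamine block, bi-ionic permeability and ligand-site rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iGluRphys)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters and their defaults, the
numerical choices behind the fitters, what the synthetic generators do and
do not emulate, and the known limitations.

## The single permeant blocker model

Cytoplasmic polyamines such as spermine block the open pore of many
ionotropic glutamate receptors in a voltage-dependent way: depolarization
drives the polycation into the selectivity filter (block onset), while
strong depolarization pushes it through the pore (permeation, relieving
block). At equilibrium the conductance is

$$G(V) = \frac{G_{\max}}{1 + [\mathrm{Spm}]/K_d(V)}, \qquad
K_d(V) = g\,e^{V/h} + L\,e^{V/k},$$

where, at 0 mV, $g = k_\mathrm{off}/k_\mathrm{on}$ and
$L = k_\mathrm{perm}/k_\mathrm{on}$ (µM), and $h < 0$, $k > 0$ (mV) are
their voltage dependencies. Only the ratios $g$ and $L$ are identifiable
from equilibrium G-V data; the underlying rate constants are not, and the
package deliberately does not expose them. The dissociation constant at
0 mV is $K_d(0) = g + L$. With $g, L > 0$ the model yields the
characteristic U-shaped G-V relationship: a conductance minimum at an
interior voltage with relief at strong depolarization.

`fitBlocker()` estimates $(G_{\max}, g, h, L, k)$ by bounded
Levenberg-Marquardt least squares (`minpack.lm::nlsLM`):

- $g$ and $L$ are optimized in log space, which enforces positivity without
  penalty terms; $h$ is bounded to $[-500, -0.5]$ mV and $k$ to
  $[0.5, 1000]$ mV, wide enough for every receptor variant we model
  (observed $k$ values range from ~14 mV to ~164 mV across variants).
- $[\mathrm{Spm}]$ is a fixed experimental input, never a free parameter:
  scaling $[\mathrm{Spm}]$, $g$ and $L$ by a common factor leaves $G(V)$
  invariant, so a free $[\mathrm{Spm}]$ would make the model
  unidentifiable. The test suite asserts this invariance explicitly.
- Initialization reads the conductance at 0 mV:
  $K_d(0) \approx [\mathrm{Spm}]\,G(0)/(G_{\max} - G(0))$ with $G_{\max}$
  started at the maximal observed conductance, split 85:15 between the $g$
  and $L$ branches ($g$ dominates $K_d(0)$ near the physiological range;
  the split is resolved by the voltage wings, and the fit diagnostics
  report the correlation of $\hat g$ and $\hat L$).
- The least-squares surface is multimodal in $(h, k)$, so the fitter runs a
  small deterministic multi-start over typical voltage-dependence scales
  ($h_0 \in \{-10, -20, -40\}$, $k_0 \in \{15, 30, 60, 150\}$ mV) and keeps
  the lowest-RSS solution. On noise-free self-generated data this recovers
  the generating parameters to numerical precision.
- Weighting is unweighted least squares by default; per-point weights were
  considered and rejected as a default because no weighting scheme is part
  of the reference analysis.
- On max-normalized data $G_{\max}$ is fitted with bounds $[0.8, 1.2]$;
  `gmaxFixed = TRUE` pins it at 1 instead. Both conventions are supported
  because either could plausibly have been used upstream; fitting with a
  bound is the default since it absorbs normalization error from noisy
  maxima.

Block-free inputs (zero spermine, or conductance with no resolvable
voltage-dependent modulation) are refused with an `iglur_block_free`
condition rather than fit: a four-parameter fit to flat data returns
arbitrary numbers, and a refusal is the only honest output. Channels with
genuinely linear G-V relationships (e.g. after neutralizing the +4
aspartate) are fit with the intrinsic exponential
$G = 1 + (G_0 - 1)e^{V/V_c}$ (`fitIntrinsic()`), which reports the fitted
$G_0$ and the empirical minimum conductance separately — a deliberate
choice, since summaries of such fits conventionally quote both.

A practical note on windows: `fitBlocker(window = )` restricts the
objective to a voltage range. This mirrors the occasional need to exclude
voltages where large-conductance states contaminate the G-V shape.

## Reversal potentials and conductance

`estimateReversal()` fits a degree-9 polynomial to the I-V relationship and
returns the real root nearest the empirical sign change. Numerical choices:

- Degree-9 monomial fitting on raw millivolt values is catastrophically
  ill-conditioned (condition numbers ~$10^{18}$); voltages are affinely
  rescaled to $[-1, 1]$ before fitting and roots mapped back. This changes
  conditioning, not the method.
- Root selection is not defined by the polynomial alone (a degree-9 fit can
  have several real roots in range): roots bracketed by the empirical sign
  change are preferred, with ties broken by proximity to the
  linear-interpolation zero crossing.
- With fewer than 11 points the degree is reduced to $n - 2$ and the
  reduction is recorded in the estimate.
- If the current never changes sign in the window — as happens for strongly
  rectifying receptors — the estimator raises `iglur_no_reversal` instead
  of extrapolating, matching the experimental reality that reversal
  potentials cannot be measured reliably for such records.

`computeConductance()` applies $G = I/(V - V_\mathrm{rev})$ and flags (but
retains) voltages within 2.5 mV of $V_\mathrm{rev}$, where the quotient is
numerically meaningless. The 2.5 mV default is a quarter of the standard
10 mV voltage step: it removes at most the single grid point adjacent to
the reversal potential. Normalization supports both conventions in common
use — to the maximal conductance (for G-V shape comparisons) and to the
value at an anchor voltage such as −100 or −80 mV (for I-V families) — and
records the mode, anchor and raw reference value in the result, because a
conductance difference is only meaningful between series normalized the
same way. `conductanceDiffAtZero()` enforces that, interpolating linearly
at 0 mV if needed.

## Bi-ionic permeability ratios

With one permeant cation inside and another outside, the reversal potential
yields the relative permeability. For two monovalents,
$p_X/p_{Na} = \exp(F\Delta E_\mathrm{rev}/RT)$. For external Ca²⁺ against
an internal monovalent X⁺ the package uses the Lewis form

$$\frac{p_{Ca}}{p_X} = \frac{[X]_\mathrm{in}}{4[Ca]_\mathrm{out}}
  \, e^{E_\mathrm{rev}F/RT}\,\bigl(1 + e^{E_\mathrm{rev}F/RT}\bigr),$$

the standard monovalent/divalent bi-ionic expression (the factor 4 comes
from the $z^2$ of the divalent in the constant-field flux). A variant of
this equation with trailing factor $(e^{E_\mathrm{rev}F/RT} - 1)$ circulates
in print but yields negative ratios for negative reversal potentials — a
sign typo; the package evaluates the Lewis form by default, which reproduces
the documented worked examples (0.66 from −59.2 mV and 1.14 from −46.9 mV
at 100 mM X⁺ / 4 mM Ca²⁺), and retains the as-printed variant behind
`asPrinted = TRUE` purely for auditability. Concentrations are used as
activities (no activity-coefficient correction), matching standard practice
for these summary calculations. Constants are F = 96485.33 C/mol,
R = 8.314463 J/(K·mol), T = 294 K by default; voltages are converted to
volts internally, with mV at every interface.

## Dose-response and recovery kinetics

`fitHill()` fits $y = 1/(1 + 10^{(\log_{10}x_0 - x)p})$ on the
log₁₀-concentration axis; `fitInhibition()` fits $1 - $ Hill and reports
the IC50. Zero-concentration control rows cannot be log-transformed and are
excluded from the objective (they define the normalization, $y = 1$).
Responses are not constrained to $\le 1$, since potentiation above the
ligand-alone response is a real phenomenon the biphasic model must capture.

The biphasic model is the product of one stimulatory and one inhibitory
Hill term,

$$y(c) = \Bigl(1 + a\,\frac{c^{n_s}}{EC_{50,s}^{n_s} + c^{n_s}}\Bigr)
         \Bigl(1 - \frac{c^{n_i}}{IC_{50,i}^{n_i} + c^{n_i}}\Bigr).$$

The exact parameterization used by dedicated curve-fitting programs for
biphasic responses is not published, so this form was chosen as the
simplest model with exactly one stimulatory and one inhibitory phase; with
$a = 0$ it reduces to the pure inhibition model, and the test suite asserts
this nesting numerically. Degenerate single-phase data trigger a fallback
to the monophasic fit with a warning. Because only the two midpoints are
typically reported for biphasic fits, equivalence with other software can
only be asserted at the midpoint level.

Recovery from desensitization is fit as $y = 1 + A\,e^{-x/\tau}$ with
$A \in [-1, 0]$: the paired-pulse ratio rises from $1 + A$ toward 1. The
decaying exponent is the only sign convention consistent with recovery
(the growing-exponent variant diverges); the generator and fitter both use
it. A fully recovered (flat) series leaves $\tau$ unidentifiable and is
flagged rather than fit.

## Ligand-binding-domain and pore-site annotation

Sequences are mapped onto mature rat GluA2 numbering by global pairwise
alignment (BLOSUM62, gap opening 10, extension 0.5 — standard protein
defaults; the alignment parameters behind the published numbering
convention are not documented, so these are package choices). Reliability
is judged by coverage over the two ligand-binding-domain segments
(reference positions 430–543 and 692–816); below 30% coverage the mapping
is refused. The residues feeding the classifier are read at positions 653,
655 and 732; backbone-contact positions (450, 478, 480, 485, 654, 705) are
extracted for annotation and two advisory warnings (`missing_D705`,
`missing_R485` — absent electrostatic anchors for the ligand α-amino and
α-carboxyl groups). Warnings never change the label. The +4 residue is
counted four residues downstream of the Q/R/N residue in the query's own
ungapped sequence, which is robust to alignment gaps between the two
positions. The Q/R/N locus is anchored at mature-GluA2 position 607 and the
+4 site at 611, the anchors implied by the standard mutant nomenclature
(Q607S, D611A).

The classifier itself is a disjoint pair of rules: glutamate specificity
for 653 ∈ {G,S,T} ∧ 655 = T ∧ 732 = Y; glycine/D-serine specificity for
653 = S ∧ 655 ∈ {V,L,A,I,P} ∧ 732 = F; anything else (including gaps) is
"unpredictable". The two rule sets cannot both match — they differ at
655/732 — and the test suite proves this by enumeration over all 8000
residue triples. SYTANLAAF/lurcher/site-G extraction is annotation only; no
functional rule is attached to those motifs.

**The bundled reference is synthetic.** The natural mature rat GluA2
sequence (UniProt P19491) is not redistributed with the package; instead a
deterministic synthetic scaffold of the same kind of length (840 residues)
carries the documented residue identities at every annotated position (Q at
607, D at 611, the LBD contact residues, SYTANLAAF with its lurcher
alanine, the site-G alanine-threonine pair). The LBD anchor positions
follow the mature-GluA2 numbering convention; the M3/site-G motif
coordinates are scaffold-defined and recorded in `referenceSites()`, which
is the single source of truth for every extraction. Self-annotation of the
scaffold therefore behaves exactly as the natural reference would at the
annotated positions (Q/R/N = Q, +4 = D, glutamate-specific LBD). Users who
need numbering fidelity along the whole sequence should pass the natural
P19491 sequence to `mapToReference()`; full-length precursors are handled
through the `signalOffset` argument.

## Synthetic generators: what they emulate, and what they do not

The generators produce every input modality the analysis consumes, each
with a closed-form noise-free backbone and additive Gaussian noise scaled
to the maximum absolute signal (the simplest noise model sufficient for
parameter-recovery testing):

- `simulateIV()` draws bi-ionic I-V families from the
  Goldman-Hodgkin-Katz constant-field flux summed over ions (z = 2 form for
  divalents, consistent with the factor 4 in the divalent permeability
  equation). Real recordings come from cells, not from the GHK model; the
  GHK backbone is a standing generative model chosen because its reversal
  potentials are exact and independently computable by bisection, which is
  what the reversal estimator is tested against.
- `simulateGVBlocker()` inverts the single permeant blocker model;
  `simulateDoseResponse()` and `simulateRecovery()` invert the Hill and
  exponential recovery forms. Default truths are the wildtype-like study
  conditions: $K_d(0) = 11.4$ µM split 10:1.4, $h = -18.5$ mV,
  $k = 36.5$ mV, $[\mathrm{Spm}] = 30$ µM on the −100..+100 mV grid in
  10 mV steps; EC50 = 0.11 mM; τ = 184 ms with A = −0.9.
- Noise magnitudes of real recordings are not documented, so recovery
  tolerances are calibrated by simulation (5% additive noise; median
  relative errors over 50 replicates: ≤10% for $K_d(0)$ and EC50, ≤15% for
  τ). The g:L split of the generating truth is a package choice — only the
  sum is documented.
- Deliberately not modelled: kinetic (Markov) gating, full current time
  courses (everything is peak-summary level), series-resistance and
  capacitance artifacts, liquid junction potentials. Passing
  parameter-recovery tests therefore demonstrates correctness of the
  estimators under the stated generative models, not robustness to every
  artifact of real recordings.

Determinism: every generator takes a `seed` and restores the caller's RNG
state; identical seed and parameters give bit-identical output, and the
pipeline logs every seed so a run can be replayed exactly.

## Problem sizes and runtime

The test suite and examples run at desk scale by design: 21-point voltage
grids, 8–12 concentration points, 10-interval recovery series, 50-replicate
noise studies, 100 random conditions for the reversal-oracle comparison,
and 60–200 random alignment fixtures. The full suite completes in well
under a minute on a single core.

## Known limitations

- The blocker fit reports asymptotic standard errors from the
  Jacobian; for the strongly correlated $\hat g$/$\hat L$ pair these are
  optimistic, which is why the correlation is reported alongside.
- The biphasic parameterization is one of several used in the field;
  midpoints transfer across parameterizations, amplitudes and slopes may
  not.
- The GHK generator assumes independent ion movement; anomalous mole
  fraction effects and pore saturation are outside its scope.
- The residue rules are a deterministic classifier distilled from
  structural reviews; receptors with non-canonical binding modes (e.g.
  lobe-bridging salt bridges) can bind glycine while violating the rules,
  and such cases are labelled by the rules as they stand, not by their
  physiology.
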