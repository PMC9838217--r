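---
title: "Quantifying AT-rich DNA-binding specificity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying AT-rich DNA-binding specificity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexat)
```

## The analysis problem

HT-SELEX characterises a protein's DNA-binding specificity by iterative
selection: a random oligonucleotide library is mixed with the protein,
bound molecules are captured on beads and washed, and the retained pool is
PCR-amplified into the next cycle's library. Sequencing each cycle turns
specificity into a counting problem. For binders that read overall base
composition — such as zinc-finger modules that prefer AT-rich DNA — the
natural readout is not a single consensus motif but the behaviour of *all*
k-mers grouped by their A/T content.

`selexat` implements that readout end to end:

1. **Canonical k-mer counting.** DNA is double-stranded, so a k-mer and its
   reverse complement are indistinguishable to the protein. Every length-k
   window is mapped to its *canonical* form — the lexicographically smaller
   of the pair under base order A < C < G < T — and counting is
   presence/absence per read: a read contributes at most once to a k-mer no
   matter how often it contains it. The fraction of reads containing each
   canonical k-mer is the library-size-free abundance measure. At k = 6 the
   4096 k-mers collapse to 2080 canonical ones.
2. **Fold-change enrichment.** A k-mer's enrichment at cycle *t* is the
   ratio of its containment fraction at cycle *t* to its fraction in the
   unselected cycle-0 library. K-mers absent from cycle 0 get an undefined
   flag rather than an infinite value and are excluded from summaries; no
   pseudocounts are applied by default (at realistic library sizes cycle-0
   coverage of the 6-mer space is essentially complete — in an 800-read toy
   library it is not, which the tests exercise).
3. **Composition grouping.** Fold changes are summarised per group of
   total A/T count (0–6) and, separately, of longest contiguous A/T run.
   Comparing the two groupings distinguishes a binder that reads base
   composition (tolerating an interrupting G/C) from one that needs an
   uninterrupted A/T tract.
4. **Top-set overlap and motif matrices.** The top-100 k-mers of different
   samples are compared by exact Venn counts, and the top-9 k-mers seed a
   one-mismatch window search whose hits are stacked into a position
   frequency matrix (PFM) for logo rendering.

Alongside the sequencing layer, the package fits EMSA titrations to the
one-site isotherm and scores protein domains for missense-variant
depletion; both are described below.

## The synthetic SELEX generator

Real SELEX datasets are large and external; the package therefore ships a
generator that simulates the experiment with a *known* ground truth, so
every analysis stage can be validated by parameter recovery rather than by
eyeballing. The generator is first-class, tested code, not a fixture.

### Affinity model

In `at_energy` mode every length-`w` window (default `w = 6`) has binding
energy

$$E = n_{AT} - g \cdot n_{GC},$$

with `gc_penalty` \(g = 0.5\) by default: a G or C base forfeits the A/T
contribution *and* costs half a unit more, a graded penalty that lets a
single G/C be tolerated at a measurable cost — the behaviour the
composition analysis is designed to detect. Sequence affinity sums the
Boltzmann weights of all windows:

$$a(s) = \text{affinity\_scale} \cdot \sum_{w \in \text{windows}(s)}
  e^{\beta E_w}.$$

Two design points deserve explanation:

* **Sum, not max.** Treating only the best window as the binding site makes
  selection blind to secondary sites: k-mers with four A/T bases become
  selectively neutral (their fold changes hover at 1 for any protein
  strength), and a saturating best-site occupancy inverts the expected
  ordering between a strong and a weak binder at the top composition
  group. The summed form is the standard statistical-mechanics treatment
  of a ligand with multiple potential sites (the max is its
  low-temperature limit) and couples selection to every partially AT-rich
  site, which is what makes group-level enrichment respond smoothly to
  composition.
* **A/T count is strand-symmetric**, so in `at_energy` mode one strand's
  windows enumerate each double-stranded site once; in `pwm` mode (an
  explicit 4 × w energy matrix) both orientations are summed explicitly.
  Either way `affinity(s) == affinity(reverse_complement(s))`.

`affinity_scale = 1` is the wild-type-like reference; `affinity_scale =
0.1` models a mutant with a ten-fold reduced affinity; `beta = 0` makes
affinity constant, which is how the no-protein negative control is
represented.

### Selection and amplification

Each cycle retains sequence *s* independently with occupancy probability

$$p(s) = \frac{\sigma\, a(s) + b}{\sigma\, a(s) + b + c},$$

where \(\sigma\) is `selection_strength`, \(c\) is `half_saturation`, and
\(b\) is `background_affinity` — nonspecific retention of DNA on the
beads. The background term is essential, not cosmetic: it is what the
no-protein control amplifies, and it is why a weak binder enriches *less*
across all composition groups — its specific signal sinks towards the
background, flattening selection — rather than more slowly saturating its
way to higher relative enrichment. Amplification is multinomial: the
retained pool is resampled with replacement back to `n_reads_per_cycle`,
a PCR model without per-molecule efficiency bias (the experiment controls
such bias with the negative control, which the simulator provides for the
same purpose).

The defaults (\(b = 200\), \(c = 350\), \(\beta = 1\), \(g = 0.5\)) were
chosen once from the occupancy model itself: the control retains
\(b/(b+c) \approx 36\%\) of molecules per cycle, so its fold changes drift
only by resampling noise; a wild-type-like read whose best site is all-A/T
sits near 60% retention, strong enough to discriminate composition groups
without taking over the library within six cycles; and the 0.1-scale
mutant's specific signal at its best sites is about a quarter of the
background, giving the weak, graded enrichment expected of a
reduced-affinity variant.

### Experiment structure and determinism

`simulate_selex()` runs the full factorial of samples × replicates ×
cycles (defaults: 3 replicates, 6 cycles with cycles 0, 1, 3, 6 retained,
20-nt random regions, 50,000 reads per library) and writes
`sample_replicate_cycle.fastq.gz` files plus a JSON manifest. Every
(sample, replicate) stream derives its own seed from the master seed via a
fixed string hash (`stream_seed()`), so streams are independent but the
whole experiment is byte-reproducible; `run_pipeline()` extends the same
guarantee to every table it writes, and can re-execute itself from its
manifest alone.

The random-region length of 20 nt is a configuration default, not an
inferred fact about any particular published library: it comfortably
contains 6-bp sites while keeping window co-occurrence realistic.

### What the generator does and does not emulate

Emulated: fixed-length random libraries; selection/amplification cycles
with tunable stringency; nonspecific background retention and a
no-protein control; independent replicates; a reduced-affinity mutant;
strand symmetry. Not emulated: sequencing errors, primer/adapter
chemistry, bead-capture kinetics, per-molecule PCR efficiency bias, and
molecule-count bookkeeping of input masses. Passing tests therefore show
that the *analysis* recovers a known ground truth under clean conditions;
they do not certify behaviour under adapter contamination or
base-calling noise, which should be handled upstream of this package.

## EMSA quantification and isotherm fitting

Gel band intensities are normalised as
\(Y = 1 - (D_x - D_\mathrm{bound}) / (D_0 - D_\mathrm{bound})\), where
\(D_x\) is the unbound-band intensity at protein concentration \(X\),
\(D_0\) the unbound intensity at zero protein and \(D_\mathrm{bound}\) an
equal empty-lane area (the 100%-bound background). The titration is fitted
by unweighted nonlinear least squares to the one-site hyperbola
\(Y = B_\mathrm{max} X / (K_d + X)\) (Levenberg–Marquardt via
`minpack.lm`).

Numerical choices:

* **Initialisation**: \(B_\mathrm{max} \leftarrow \max Y\), \(K_d
  \leftarrow\) the concentration whose \(Y\) is closest to half-maximum —
  robust for any monotone titration.
* **Bounds**: \(K_d \in (0, 10 \max X]\), \(B_\mathrm{max} \in (0, 1.5]\),
  so non-binding titrations are reported as *not converged* ("could not be
  determined") instead of diverging. A titration whose maximum \(Y\) is
  below 0.05 short-circuits to that report.
* **No clipping**: noisy \(Y\) values outside \([0, 1]\) are retained;
  clipping would bias \(K_d\) downward. Values outside \([-0.2, 1.2]\)
  trigger a warning.
* **No ligand-depletion correction**: the plain hyperbola is the stated
  model even though the probe is at finite concentration; a
  depletion-aware quadratic model is a deliberate non-goal.

`simulate_gel()` inverts the normalisation exactly at zero noise
(round-trip identity to 1e-12), making fit validation a closed loop:
titrations generated at dissociation constants spanning 0.76–23 µM refit
to relative error below 1e-6 noiselessly, and at 5% gel noise the median
\(K_d\) recovery error over 100 seeded gels stays under 15%.

## Domain-level missense depletion

For a protein of length \(L\) with observed missense-variant positions
\(V\), the protein score is \(V_p = |V| / L\) (the fraction of residues
carrying at least one missense variant) and each domain's score \(V_d\) is
the same fraction restricted to the domain span (1-based inclusive
coordinates, `aa870–920` style). The ratio \(V_d / V_p\) is 1 for a domain
indistinguishable from the protein background and well below 1 for a
domain depleted of variation; the whole-protein pseudo-domain has ratio 1
by construction. Under uniform random placement the domain ratio is
unbiased around 1, which the tests verify by Monte-Carlo.

This positional-fraction definition matches the published semantics of
such scores (ratio ≥ 1 ⇒ not depleted) but is this package's own
formalisation; reproducing any published protein's printed values
additionally requires the same variant snapshot that publication used,
which is why no such reproduction is claimed here. Equivalence between
clinical and population variants is positional, not allele-level:
`filter_candidates()` is an exact set difference on residue positions.
Mutation-rate-calibrated expectations and allele-frequency weighting are
non-goals.

## Problem sizes and tolerances

The validation suite runs the SELEX generator at its default study
conditions (50,000 reads/cycle, 3 replicates, 6 cycles) for the
composition-group properties, and smaller libraries (300–20,000 reads)
for unit-level contracts; the byte-reproducibility check of the demo
pipeline uses 2,000 reads/cycle, determinism being independent of scale.
Monte-Carlo calibrations use 100 seeds with 3σ tolerances. Exhaustive
checks (canonicalisation, enumeration) cover the full 6-mer space.

## Known limitations

* Counting is read-containment (presence/absence); occurrence-count
  statistics and Markov background corrections are out of scope.
* The PFM stage does no EM/Gibbs refinement and handles fixed-length
  motifs only.
* Fold changes against sparse cycle-0 libraries need the optional
  pseudocount to be informative; the default reports them as undefined.
* `k` is capped at 12 because canonicalisation uses exhaustive
  lookup tables (4^k entries).
* The depletion module scores observed positional variation only; it does
  not model mutational opportunity per residue.
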