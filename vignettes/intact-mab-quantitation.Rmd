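---
title: "Quantifying intact antibody proteoforms by extracted ion current chromatograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intact antibody proteoforms by extracted ion current chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mabquant)
```

## The problem

A therapeutic IgG1 antibody is not one molecule but a population of
proteoforms: each heavy chain carries one N-glycan (so the intact molecule
carries a glycan *pair*), the heavy-chain C-terminal lysine is variably
clipped (0K/1K/2K, +128.17 Da per lysine), and low-level modifications
(glycation +162 Da, deamidation +1 Da, N-terminal truncations) add further
heterogeneity. Cation-exchange chromatography with a volatile-salt pH
gradient separates charge-variant classes while the mass spectrometer,
acquiring MS1 spectra of the native molecule at m/z 2500–8000, resolves
glycoforms by mass. `mabquant` turns such runs into relative proteoform
abundances and derived glycan quality attributes.

## The quantitation model

For a proteoform of neutral average mass $M$ observed at charge $z$ the
positive-mode proton adduct appears at

$$ m/z = \frac{M + z\,m_p}{z}, \qquad m_p = 1.007276\ \mathrm{Da}. $$

The extracted ion current chromatogram (EICC) of a species sums, per scan,
the intensity of all centroids within a tolerance of any of its theoretical
m/z values over a charge range (default $z = 22\dots32$, which keeps a
~147 kDa antibody inside the acquisition window). Trapezoidal integration
over a half-open retention-time window $[t_0, t_1)$ gives an area $a_i$,
and fractional abundances are

$$ f_i = a_i \Big/ \sum_j a_j $$

over the quantified set, so they are invariant to global intensity scaling
and sum to one by construction. This is *semi*-quantitation: it assumes
equal ionization response across glycoforms of the same backbone, which is
reasonable for species differing by a few hexoses but is not absolute
quantitation.

Masses are bookkept in the **average-mass** domain: at a resolving power of
17,500 the isotopic envelope of a 147 kDa protein is unresolved and the
centroid of the envelope tracks the average mass, not the monoisotopic one.
Monoisotopic masses are still computed for every composition (they are the
natural unit for small deltas such as the +0.984 Da deamidation shift).

## Mass arithmetic

All masses derive from elemental compositions: signed integer element
counts with element-wise arithmetic, built from a fixed bundled snapshot of
atomic masses (monoisotopic from AME2020/CODATA, average from the IUPAC
2021 abridged standard atomic weights). Residues are amino acids minus
water; a chain is the residue sum plus one water; the intact antibody is
2 HC + 2 LC minus two hydrogens per disulfide (16 for IgG1 by default,
configurable since antibodies differ) with N-terminal Gln cyclized to
pyroglutamate (−17.027 Da) where present.

```{r masses}
mass_of(residue_table()[["K"]])                       # one lysine residue
mass_of("C6H10O5")                                    # one hexose residue
mass_of(sequence_composition("QIVLS", water = FALSE)) # LC N-terminal pentapeptide
```

Two conventions deserve a note:

* **Glycation vs. galactose.** A glucose adduct and an extra galactose are
  the same composition (one hexose, +162.053 Da mono). The modification
  registry stores them as two names over one composition; no mass-based
  method can tell them apart, only the chromatographic dimension can.
* **The −540 Da truncation.** The light-chain N-terminal pentapeptide
  QIVLS sums to 540.33 Da (mono) *with unmodified Gln*. If the lost
  peptide carried pyroglutamate the shift would be −523.3 Da. We follow
  the reported −540 Da reading (residue-sum with free Gln, with the intact
  chain regaining its pyroGlu on the new terminus being one consistent
  interpretation) and expose the delta as an ordinary registry entry so
  users can swap it.

## Glycan nomenclature

Oxford-style names are parsed by a small grammar: `M5`–`M9` are
oligomannose (HexNAc2 Hex5–9); `A1`/`A2` complex types count one antennal
HexNAc per arm over the HexNAc2Hex3 core, `G0`–`G2` add galactoses, `S1`/`S2`
sialic acids (each sialylated arm also carries its galactose), `F` the core
fucose. Anything outside the grammar — such as minor variants known only by
a local letter code — is registered explicitly as a name → composition
pair; the grammar never guesses.

Isobaric glycan pairs (A2G1F/A2G1F vs. A2G0F/A2G2F) are merged into a
single library entry with a combined label: both carry two galactoses, so
every downstream attribute is identical under either reading.

## Quality attributes

The galactosylation level is the weighted galactose occupancy of the four
galactose sites of the fucosylated biantennary main set:

$$ \mathrm{Gal} = 100 \cdot \frac{\sum_i f_i\, g_i}{4 \sum_i f_i}, \quad
   g_i \in \{0,\dots,4\}. $$

This formula is this package's definition (the attribute is commonly
reported without one); the normalizing scope is selectable (`"main"`
restricts to the fucosylated biantennary pairs, `"all"` uses every entry
with a galactose count) because published values do not state their scope.
Class aggregates are plain fraction sums over disjoint predicates:
sialylated (any NeuAc), oligomannose (both arms HexNAc2), afucosylated (a
complex-type arm without core fucose — oligomannose arms lack fucose by
construction and are *not* counted here, otherwise the classes would
double-count). Deamidation and glycation are deliberately **not**
quantified by EICC: +1 Da is unresolvable at the intact level and +162 Da
is isobaric with galactosylation; the pattern-shift detector flags them
instead.

Replicate uncertainty uses the exact t-based interval
$\bar{x} \pm t_{0.975,\,n-1}\, s/\sqrt{n}$; for triplicates
$t = 4.3027$, so replicates (1, 2, 3) give a halfwidth of 2.484.

## Tolerances and numerical choices

* **Extraction tolerance**: the wider of 50 ppm and an absolute floor of
  0.4 Th. The floor must cover the unresolved envelope width (~0.3 Th at
  m/z 5000 and R 17,500) but stay below half the closest library spacing:
  species differing by the lysine/hexose composition difference (33.97 Da)
  approach 1.06 Th at z = 32, so floors ≥ 0.53 Th would cross-assign
  signal between lysine groups.
* **Integration**: trapezoidal, with the trace linearly interpolated at
  the window edges, so adjacent half-open windows split the total area
  exactly and a constant trace of 1 over two minutes integrates to 2.
* **Spectrum averaging**: intensities are summed on a logarithmic m/z grid
  with bin width (m/z)/R divided by 4 (fourfold oversampling of the peak
  width); each bin reports its intensity-weighted centroid. Averaging is
  linear in intensities and invariant to scan order.
* **Auto windows**: when no retention windows are configured, each
  species' EICC apex is moment-fitted to a Gaussian and windows are
  apex ± 3σ, merged when overlapping.
* **Degenerate inputs**: empty compositions, empty sequences, all-zero
  runs, and unassignable peaks are valid inputs with defined results;
  all-zero areas, empty glycan-pair lists, and windows without scans are
  errors.

## The deconvolution stand-in

Commercial zero-charge deconvolution algorithms are proprietary; this
package deliberately uses a transparent grid projection instead. For each
candidate mass $M$ on a 1 Da grid, each charge contributes the intensity of
its best-matching centroid within tolerance of $(M + z m_p)/z$, linearly
tapered with m/z distance. Two refinements make the scorer usable:

* **Charge support gating.** A real species is supported by its whole
  envelope; the wrong-charge image of a peak (apparent mass $M z'/z$) is
  supported by a single charge. Masses with fewer than 3 supporting
  charges are zeroed, which removes the ghost ridges that otherwise
  carry half the score mass.
* **Centroid refinement.** Score local maxima above
  $\mathrm{median} + 3\,\mathrm{MAD}$ (plus a 0.1% relative floor, since
  sparse score traces have a near-zero median) are refined to the
  score-weighted centroid of the region above half the apex, which is what
  brings a 1 Da grid to ~1 ppm mass accuracy on clean data.

Pattern-shift detection normalizes two peak lists to unit score sum,
greedily matches reference peaks (descending score, each peak used once)
to the strongest query peak within 0.5 Da of mass + offset over a
−600…+600 Da offset grid (0.05 Da step; only offsets near an observed
pairwise mass difference can score), and reports the offset maximizing the
matched $\sum \min(s_r, s_q)$ overlap — refined to the weighted mean of
matched residuals so the reported shift is not limited by the tolerance
plateau. A conserved pattern shifted by one lysine, one hexose, or a
truncation is recovered at its exact offset with score near 1.

## What the simulator does and does not emulate

The generator produces centroid-mode MS1 runs with: Gaussian elution peaks
(σ = 0.10 min default) at class-dependent retention times — sialylated
glycoforms 0.68/1.35 min earlier (one/two sialic acids), oligomannose
0.21 min later, galactosylation neutral, lysine groups as separate peaks —
Gaussian charge envelopes (z₀ = 26, σ = 2), multiplicative log-normal
intensity noise (CV 5%), Gaussian m/z jitter (10 ppm), and a Poisson
baseline of random centroids. The preset encodes a copy-product-like
profile (three lysine groups whose 0K group is richer in oligomannose and
slightly more galactosylated) and an originator-like profile (single 0K
group, higher galactosylation and sialylation); the within-group fractions
are the study conditions for all recovery tests.

Not emulated: isotopic fine structure (subsumed in the centroid, consistent
with average-mass bookkeeping), chromatographic tailing/fronting, ion
suppression and response differences between species, in-source decay, and
real baseline structure. Passing recovery tests therefore demonstrates the
correctness of the extraction/integration/normalization pipeline under
controlled noise — not robustness to every artifact of real data, where
retention windows and tolerances may need manual review.

Problem sizes used by the test-suite and validation script: 27-component
runs (three lysine groups × nine glycoform pairs) of 181 scans over 6 min
at a 2 s scan interval, deconvolution on a 15,000-point mass grid over 11
charges, and five-seed replicates for the noisy recovery checks. These
sizes resolve every simulated effect while keeping a full validation run
in seconds.

## Known limitations

* Absolute masses of the bundled rituximab chains depend on the editable
  FASTA fixture (public-record sequences); every delta-based statement
  (ladders, shifts, class attributes) is fixture-independent.
* Fractional abundances assume uniform response; no attempt is made at
  absolute or cross-backbone quantitation.
* The deconvolution stand-in targets well-separated species (≥ ~50 Da at
  147 kDa); it does not resolve the +1 Da deamidation shift, and is not
  intended to reproduce vendor algorithms peak-for-peak.
* Auto-windowing assumes roughly Gaussian, baseline-resolved elution of
  each variant group.
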