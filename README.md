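# mabquant

Semi-quantitation of intact monoclonal-antibody proteoforms from native
cation-exchange LC-MS runs.

A therapeutic IgG is a population of proteoforms: glycan *pairs* on the two
heavy chains (the galactose ladder G0F/G0F … G2F/G2F, oligomannose M5/M5,
afucosylated and sialylated species), variably clipped C-terminal lysines
(0K/1K/2K, +128.17 Da each), and small modification deltas (glycation
+162 Da, deamidation +1 Da, N-terminal truncations). `mabquant` is for
analytical scientists characterizing such products — e.g. comparing an
originator and a biosimilar candidate — from MS1 scans of a native LC-MS
run (mzML, m/z 2500–8000, resolving power ~17,500).

## What it computes

For a proteoform of neutral average mass *M* at charge *z*, the proton
adduct appears at *m/z* = (*M* + *z*·1.007276)/*z*. The package:

1. computes theoretical proteoform masses from elemental compositions
   (chains from FASTA, Oxford-style glycan names, lysine variants,
   user-defined modification deltas);
2. extracts one **ion current chromatogram per proteoform** (intensity
   within tolerance of any charge state's theoretical m/z, summed per
   scan, default z = 22–32), integrates it over a retention-time window,
   and reports **fractional abundances** *fᵢ = aᵢ / Σ aⱼ*;
3. derives quality attributes — galactosylation level
   100·Σ *fᵢ gᵢ* / (4 Σ *fᵢ*) over the main glycoform set, plus
   sialylated / oligomannose / afucosylated class fractions — with exact
   t-based confidence intervals over replicates;
4. annotates deconvoluted masses against the library by signed ppm error;
5. provides a transparent zero-charge deconvolution (grid projection with
   charge-support gating, ~1 ppm on clean data) and a pattern-shift
   detector that recognizes constant mass offsets between spectra —
   +128 Da lysine ladders, +162 Da glycation shifts, −540 Da truncations;
6. ships a synthetic-run generator with known ground truth (class-shifted
   retention times, Gaussian charge envelopes, multiplicative noise, m/z
   jitter) used to validate the whole pipeline end to end.

## Worked example

```r
library(mabquant)

chains <- read_chains(rituximab_fasta())
lib <- build_library(chains, list("A2G0F/A2G0F", "A2G0F/A2G1F", "M5/M5"),
                     lysine_variants = 0:1)
lib[, c("label", "mono", "avg", "gal_count")]
#>   label             mono     avg gal_count
#> 1 0K M5/M5       147324. 147417.        NA
#> 2 1K M5/M5       147452. 147545.        NA
#> 3 0K A2G0F/A2G0F 147780. 147873.         0
#> 4 1K A2G0F/A2G0F 147908. 148002.         0
#> 5 0K A2G0F/A2G1F 147942. 148036.         1
#> 6 1K A2G0F/A2G1F 148071. 148164.         1
```

Adjacent lysine variants differ by exactly one lysine residue (128.175 Da
average); the glycoform columns give each entry's galactose count and
class flags. Quantifying a simulated originator-like run:

```r
cfg <- preset_rituximab_like("originator", seed = 42)
sim <- simulate_run(cfg)                      # 181 scans, rt 7.5-13.5 min
tab <- quantify_run(sim$run, attr(cfg, "library"), quant_config())
tab[order(-tab$fraction), c("label", "area", "fraction")][1:3, ]
#>   label             area fraction
#> 1 0K A2G0F/A2G1F 379530.   0.382
#> 2 0K A2G1F/A2G1F 265302.   0.267
#> 3 0K A2G0F/A2G0F 207845.   0.209

galactosylation_level(tab)        # 32.65  (% of 4 galactose sites occupied)
class_fraction(tab, "sialylated") # 2.24   (% of quantified ion current)
triplicate_ci(c(32.61, 32.65, 32.70))
#>      mean halfwidth
#> 32.653333  0.112055   (95% CI, t = 4.3027 for n = 3)
```

The recovered attributes match the simulation's ground truth because the
generator's fractions are known; on real data the same calls apply to a
`read_run("file.mzML")` object with user-supplied retention windows (or
`auto_rt_windows()`).

A command-line wrapper covers the same pipeline:

```sh
Rscript inst/cli/mabquant.R simulate --out run.mzML --truth truth.json --seed 4
Rscript inst/cli/mabquant.R quantify --run run.mzML --out table.tsv
Rscript inst/cli/mabquant.R deconvolute --run run.mzML --rt 8.0:10.2 --out peaks.tsv
Rscript inst/cli/mabquant.R report --run run.mzML --out report.json
```

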