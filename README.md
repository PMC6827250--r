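# alginseq

Sequencing of alginate oligosaccharides from exolytic truncation series
and ¹H NMR signal areas, with an in-silico model of endolytic/exolytic
alginate lyase digestion, negative-mode mass annotation, and endo/exo
saccharification synergy.

## Who this is for

Alginate — the linear β-D-mannuronate (M) / α-L-guluronate (G)
polysaccharide of brown algae — is depolymerized by lyases via
β-elimination, which leaves a 4,5-unsaturated ring ("Δ unit") at the
non-reducing end of each product and erases that ring's M/G identity.
Determining the residue sequence of the resulting unsaturated
oligosaccharides normally requires heavy 2D NMR. A much simpler route
combines two one-dimensional observables with controlled exolytic
truncation, and this package implements that procedure end to end, plus
the enzyme modelling needed to study why endolytic and exolytic lyases
synergize during saccharification. It is aimed at glycobiologists and
enzyme engineers working with alginate lyases, and at anyone who wants a
seeded, testable surrogate for these experiments.

## The core ideas

**Sequencing.** For an unsaturated fraction of degree of polymerization
*n*, the H-4 resonance of the Δ ring reports whether position 1 is G
(≈5.71/5.67 ppm) or M (≈5.61/5.56 ppm), and the reducing-end β-anomeric
signal (G: doublet at 4.71 ppm, ³J = 8.4 Hz; M: singlet at 4.70–4.80 ppm)
reports position *n* − 1. After *k* exolytic cuts, interior position
*k* + 1 becomes the new Δ neighbour, so a truncation series yields the
G-fraction marginal p_i of every position:

    p_{k+1} = A(H-4 ΔG) / (A(H-4 ΔG) + A(H-4 ΔM))   at k cuts
    p_{n-1} = A(re G) / (A(re G) + A(re M))          from the parent

and the mixture is reconstructed as the outer product

    f(x_1 … x_{n-1}) = Π_i [ p_i if x_i = G else (1 − p_i) ] ,

the maximum-entropy joint consistent with the marginals (positional
independence — an assumption every report states explicitly, since
marginals cannot identify inter-position correlations).

**Masses.** A glycosidically linked uronate residue is C₆H₈O₆
(monoisotopic 176.0321 Da); an unsaturated DP *n* chain gives
`[M − H]⁻ = 176.0321·n − 1.00728`, a saturated one adds a water, and the
released monomer appears at nominal 175 (UDP1/DEH) and 193 (TPC).

**Digestion.** A Gillespie simulation in which every bond a(1→4)b of
every chain carries endolytic propensity u₁·k(a,b) (2 × 2 bond-pair
table, G-block-preferring preset, minimum fragment size 2) and every
chain carries exolytic propensity u₂·r(dp) (piecewise-linear size
profile, optimum at DP 4, r(4)/r(polymer) = 6.5). 2-AB-labelled chains
stop at the labelled disaccharide; ring count is conserved exactly.

## Worked example

Sequence a pentasaccharide fraction from its truncation series (parent
H-4 ratio 3.5:1 with a pure-M reducing end, 1.5:1 after one cut, "ΔM
only" after two):

```r
library(alginseq)
series <- read_series_json(system.file("extdata", "udp5_series.json",
                                       package = "alginseq"))
infer_sequences(series)
#> <inferred_composition> DP 5, 4 species (pruned mass 0.0000)
#>  sequence   fraction percent
#>     ΔGGMM 0.46666667    46.7
#>     ΔGMMM 0.31111111    31.1
#>     ΔMGMM 0.13333333    13.3
#>     ΔMMMM 0.08888889     8.9
#> marginals (G fraction by position): 0.778 0.600 0.000 0.000
#> assumption: positional independence (joint = outer product of marginals; ...)
#> consistency residual: 0
```

The four readout ratios resolve the fraction into four sequences; the
percent column is the display rounding (one decimal for ≥3 species,
integers for 2), and the residual confirms the reconstruction reproduces
the observed marginals. Mass annotation of the unsaturated ladder:

```r
mass_report(c("ΔG", "ΔGG", "ΔGMM", "ΔGGMM", "ΔGGMMM", "UDP1", "TPC"))
#>   sequence dp mz_monoisotopic mz_nominal
#> 1       ΔG  2        351.0569        351
#> 2      ΔGG  3        527.0890        527
#> 3     ΔGMM  4        703.1211        703
#> 4    ΔGGMM  5        879.1532        879
#> 5   ΔGGMMM  6       1055.1853       1055
#> 6     UDP1  1        175.0248        175
#> 7      TPC  1        193.0354        193
```

And a seeded endo+exo co-digestion of a synthetic polymer pool:

```r
pool <- generate_chains(alginate_preset("mixed", length_mean = 30), 4, seed = 1)
run_synergy(pool, enzyme_preset("endo_G_preferring"),
            enzyme_preset("exo_size_dependent"),
            endo_mU = 50, exo_mU = 50, duration = 10, replicates = 5, seed = 42)
#> <synergy_report> 5 replicates, 10 min, endo 50 mU + exo 50 mU
#>        arm yield       se
#>   combined  42.6 1.860108
#>  endo_only   0.0 0.000000
#>   exo_only   2.6 0.509902
#> synergy ratio (combined / exo-only): 16.38
```

The endolytic enzyme alone releases no monomer (minimum fragment size 2),
while pre-fragmenting the polymer toward the exolytic DP-4 optimum
multiplies the monomer yield of the same total activity.

A thin command-line wrapper ships in `inst/cli/alginseq.R`
(`Rscript .../alginseq.R mass --sequence ΔGMM`, `... sequence --series
series.json --out report.json`, `... digest --config cfg.yaml --seed 1`,
etc.); see `--help`.

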