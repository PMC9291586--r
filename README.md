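# sdturnover

Deterministic modelling of evolutionary transitions between genetic
sex-determination (SD) systems under sexually antagonistic (SA) selection
and sex-linked–autosomal epistasis.

## The problem

Genetic sex determination is ancient, yet the genes that control it turn
over surprisingly often: a novel male determiner can displace an
established Y (an XY → X'Y' transition), or a dominant female determiner W
can invade and convert a male-heterogametic system into a
female-heterogametic one. A classical driver of such turnovers is linkage
between an SD locus and a sexually antagonistic locus — an allele that
helps one sex and harms the other — as analysed by van Doorn &
Kirkpatrick. `sdturnover` implements a two-sex, infinite-population,
discrete-generation recursion that extends this framework with an
autosomal locus (**EPI**) that interacts epistatically with one SA locus
to modify **male** fitness, and asks when that interaction stabilises or
destabilises the ancestral sex chromosome pair.

## The model

The diploid genome has four independently assorting linkage groups:

| group | loci | focal alleles |
|-------|------|----------------|
| XY    | SD + SA, recombining at `r_XY` | Y (male determiner), SA^Y |
| I^A   | SD + SA, recombining at `r_A`  | A (male determiner), SA^A |
| II^W  | SD + SA, recombining at `r_W`  | W (dominant female determiner), SA^W |
| EPI   | one locus | EPI |

Every locus is biallelic (`+` = non-focal). Sex is genotypic: any W makes
a female; otherwise any Y or A makes a male; otherwise female. Each SA
locus contributes a viability factor 1, `1 + h_sex * s_sex`, `1 + s_sex`
for 0/1/2 focal copies, with `sM * sF < 0` (default dominance `hM = 0.6`,
`hF = 0.4` for the male-beneficial SA^Y and SA^A, mirrored for the
female-beneficial SA^W). Fitness is multiplicative across loci:

```
w_F = w_SAY * w_SAA * w_SAW
w_M = w_SAY * w_SAA * w_SAW * (1 + sigma * epsilon)
```

where the binary indicator `sigma` implements one of three epistasis
types between EPI and its partner SA locus — *dominance* (benefit when
both focal alleles are present), *overdominance* (double heterozygotes
only), *coadaptation* (matched double homozygotes only) — and epistasis
acts in males only.

The state is a pair of frequency vectors over the 2^7 = 128 gamete types:
an egg pool and a sperm pool. Each generation: random union of pools,
sex assignment, viability selection within each sex, and gametogenesis
with recombination. A transition scenario starts from an ancestral XY
population (Y paternal-only; SA and EPI alleles at frequency 0.25), runs
a 10,000-generation burn-in, introduces A or W at frequency 1e-4 across
all genotypes, runs to 200,000 generations, and classifies the outcome by
the rounded frequency of the novel SD allele on the relevant
parent-of-origin copies (paternal A in males / maternal W in females).

## Worked example

Dominance epistasis between the ancestral SA^Y and the autosome can
rescue the Y: with the same SA coefficients, the novel male determiner A
invades when epistasis is absent but fails when it is strong. The `desk`
profile (2,000 burn-in / 20,000 total generations) is a reduced-horizon
preset used throughout the examples and tests.

```r
library(sdturnover)

spec0 <- scenario_spec("Y_to_A", epi_type = "dominance", epi_partner = "SAY",
                       s_Y = 0.02, s_new = 0.025, epsilon = 0,
                       profile = "desk")
run_transition(spec0)
#> <sd_transition> Y_to_A, dominance epistasis on SAY
#>   s_Y = 0.02, s_new = 0.025, epsilon = 0
#>   outcome: turnover (read frequency 1 after 20000 generations)

spec5 <- scenario_spec("Y_to_A", epi_type = "dominance", epi_partner = "SAY",
                       s_Y = 0.02, s_new = 0.025, epsilon = 0.05,
                       profile = "desk")
run_transition(spec5)
#> <sd_transition> Y_to_A, dominance epistasis on SAY
#>   s_Y = 0.02, s_new = 0.025, epsilon = 0.05
#>   outcome: ancestral SD maintained (read frequency 8.849e-12 after 20000 generations)
```

The read frequency is the focal SD allele's frequency among the
paternally inherited copies of males: 1 means every male now inherits A
from his father (complete turnover); ~1e-11 means A is numerically
extinct and Y is retained. Per-locus end states come from `tidy()`:

```r
tidy(run_transition(spec0))
#> # A tibble: 7 × 3
#>   locus linkage_group final_frequency
#>   <chr> <chr>                   <dbl>
#> 1 Y     XY                 0.00000913
#> 2 SAY   XY                 0.476
#> 3 A     IA                 0.250
#> 4 SAA   IA                 0.444
#> 5 W     IIW                0
#> 6 SAW   IIW                0
#> 7 EPI   EPI                0.250
```

(after turnover A is fixed paternally in males, i.e. at overall frequency
0.25, exactly as Y was before). `glance()` gives a one-row summary,
`autoplot()` plots a recorded trajectory, and the sweep layer maps
turnover boundaries:

```r
cfg <- sweep_config("Y_to_A", "dominance", "SAY", n_replicates = 1000,
                    seed = 1, profile = "desk")
records <- run_sweep(cfg)
boundary <- estimate_boundary(records, epsilon_slices = c(0, 0.025, 0.05))
autoplot(boundary)
```

A thin command-line wrapper with `simulate`, `sweep`, `boundary` and
`validate` subcommands is installed at
`system.file("cli", "sdturnover.R", package = "sdturnover")`.

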