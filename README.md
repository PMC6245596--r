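# fluxpen

Frequency-penalized, LP-based extraction of pathways and Elementary Flux
Modes (EFMs) from stoichiometric metabolic models.

## The problem

Constraint-based analysis represents a metabolism by its stoichiometric
matrix *S* (metabolites × reactions); a flux vector *v* is biologically
admissible at steady state when

```
S v = 0,   v ≥ 0      (after splitting reversible reactions)
```

A *pathway* is a nonzero admissible flux vector, identified with its
*support* (the reactions carrying flux); an *EFM* is a pathway whose
support strictly contains no other pathway's support. Enumerating all EFMs
of a genome-scale network is hopeless, so practical tools sample them: per
iteration, solve the linear program

```
min Σᵢ wᵢ vᵢ    s.t.  S v = 0,  v ≥ 0,  vⱼ ≥ c for j in a random seed
```

whose optimal vertex is a support-minimal pathway through the seeded
reactions. The catch: deterministic solvers keep returning the same
vertices, so the sampled set is repetitive and unrepresentative. `fluxpen`
implements the remedy of penalizing over-used reactions in the objective,

```
wᵢ = 1 + p · Fᵢ,        Fᵢ = Oᵢ / N
```

where `Fᵢ` is the running frequency of reaction *i* in the solutions
collected so far and `p ≥ 0` is the penalization. Frequent reactions
become expensive but never forbidden — unlike negative seed constraints,
a weight can never cause infeasibility — and the extracted set becomes
markedly more diverse.

The package is aimed at systems-biology users who want (1) a reproducible
random-seed EFM sampler with tunable penalization, (2) the statistical
machinery to compare extraction experiments (Wilcoxon signed-rank on
paired frequencies; the chi-bar-squared divergence
`χ̄² = Σ (F′ᵢ−Fᵢ)²/Fᵢ`), and (3) exact small-network ground truth (a
brute-force EFM oracle and a rank-based elementarity test) to validate
any extraction method against.

## Worked example

Five exchangeable branches between a source and a sink — exactly 5 EFMs.
An unpenalized deterministic extraction over-uses one branch; `p = 20`
spreads the solutions:

```r
library(fluxpen)
net <- make_parallel(5)

res0  <- run_extraction(net, N_target = 200, p = 0,  k = 1, rng_seed = 11)
res20 <- run_extraction(net, N_target = 200, p = 20, k = 1, rng_seed = 11)

frequency_table(res0)[2:6, 1:3]    # unpenalized: B1 dominates
#>   reaction_id occurrences frequency
#> 2          B1          78     0.390
#> 3          B2          31     0.155
#> 4          B3          30     0.150
#> 5          B4          33     0.165
#> 6          B5          28     0.140

frequency_table(res20)[2:6, 1:3]   # p = 20: branches equalized
#>   reaction_id occurrences frequency
#> 2          B1          39     0.195
#> 3          B2          39     0.195
#> 4          B3          40     0.200
#> 5          B4          43     0.215
#> 6          B5          39     0.195

compare_frequency_tables(frequency_table(res0), frequency_table(res20))[, 1:2]
#>   wilcoxon_p   chi_bar
#> 1      0.625 0.1612479

length(brute_force_efms(net))                       # oracle ground truth
#> [1] 5
is_elementary(res20$split_net, res20$solutions[[1]]$support)
#> [1] TRUE
```

Branch B1's frequency drops from 0.39 to 0.195 (≈ 1/5, the fair share);
every reported solution is a steady-state pathway containing its seed, and
here each is an exact EFM of the network. The `chi_bar` value of 0.16
quantifies how far the penalized frequency profile moved from the
unpenalized one (0 would mean identical).

## Command line

A thin `fluxpen` script (installed to `exec/`) drives the same functions:

```sh
fluxpen synth    --kind random --m 8 --n 20 --density 0.3 --out toy.tsv
fluxpen extract  --model toy.tsv --iterations 5000 --penalization 5 \
                 --rng-seed 1 --out-solutions sols.tsv --out-frequencies freq5.tsv
fluxpen compare  --a freq0.tsv --b freq5.tsv --out cmp.tsv --plot diff.png
fluxpen validate --solutions sols.tsv --model toy.tsv --out report.tsv
```

Exit codes: 0 success, 2 partial results after an infeasible-seed drought,
64 usage error, 65 data mismatch. Every output TSV starts with `#`
metadata lines (package version, full configuration, RNG seed) sufficient
to re-run bit-identically.

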