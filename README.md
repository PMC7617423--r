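# coalbin

Coalescent theory of taxonomic binning accuracy.

## What this is for

Metagenomic, environmental DNA and ancient DNA studies assign individual
sequencing reads to reference taxa by comparing them against a reference
database ("taxonomic binning"). When a read aligns to more than one
reference, similarity-based assignment can pick the wrong taxon: because
of population variation and gene-tree discordance, a more distant
species' reference is sometimes genuinely closer to the read. `coalbin`
computes how often that happens, exactly, in the two-reference-species
setting, for people who need to choose reference databases, filtering
thresholds or assignment rules — and who want to know which parameters
(reference completeness, divergence times, read length, population size,
sample age) actually move the error rate.

## The model

A query read q is compared against its closest reference species t
("true") and the next closest f ("false"), under a coalescent model with
divergence times `T_qt < T_tf` (generations), effective population size
`N` (pairwise coalescence rate `1/2N`), per-read mutation rate
`μ = k·μ_site`, sample ages `A_q, A_t, A_f`, and reference completenesses
`C_t, C_f`. Mutation counts on genealogy branches are Poisson; the
**least-mismatch** rule assigns q to the reference with the smaller count
(`P(K_t < K_f)` = correct, `P(K_t > K_f)` = incorrect, tie = unassigned),
the **exact-match** rule assigns only on a unique zero-mismatch match.

Four genealogies contribute. With probability `1 − e^{−(T_tf−T_qt)/2N}`
the q and t lineages coalesce before the t–f split (Case 1); otherwise
three lineages reach the ancestral population and each pair coalesces
first with probability 1/3, including the discordant
incomplete-lineage-sorting topology. Each case contributes an integral of
the Poisson comparison probability over its coalescence-time density,
e.g. Case 1:

    P_CA(T, μ, N; t1 < T < t2) =
      ∫_T^∞ ∫_0^T  (e^{−t1/2N}/2N)(e^{−t2/2N}/2N)
        Σ_k Σ_{l>k} (μ(2t2−t1))^l (μt1)^k e^{−2μt2} / (l! k!)  dt1 dt2
      / (e^{−T/2N}(1 − e^{−T/2N}))

Incomplete references mix in single-alignment reads with weights
proportional to `C_t(1−C_f)` and `(1−C_t)C_f`. The same model is
implemented three independent ways — analytic quadrature, a Monte Carlo
genealogy oracle, and a sequence-level read simulator with FASTA output
and an ancient-DNA deamination model — and the three are cross-checked
against each other in the test suite.

## Worked example

```r
library(coalbin)

p <- model_params(T_tf = 400000, T_qt = 0, N = 10000,
                  mu_site = 1e-8, read_length = 96)
ap <- assignment_probabilities(p, "least_mismatch")
ap
#> Assignment probabilities (least_mismatch rule)
#>   correct:   0.538
#>   incorrect: 0.00887
#>   none:      0.453
#>   correct per incorrect: 60.6
```

At this baseline (a 96-bp read, mutation rate 1e-8/site/generation,
N = 10,000, query drawn from the true reference's own population, a
400,000-generation true–false split, complete references) a read that
aligns to both references is assigned correctly 53.8% of the time,
incorrectly 0.9% and left unassigned 45.3% — about 60.6 correct
assignments for every incorrect one. Diverging the query from its
reference by 50,000 generations drops that ratio below 16; shrinking the
true reference's completeness converts missing regions directly into
incorrect assignments:

```r
correct_per_incorrect(assignment_probabilities(
  model_params(T_tf = 400000, T_qt = 50000), "least_mismatch"))
#> [1] 15.61025
sweep_parameter(p, "C_t", c(1, 0.8, 0.5))[, c("value", "p_correct", "p_incorrect")]
#>   value p_correct p_incorrect
#> 1   1.0 0.5377217 0.008872423
#> 2   0.8 0.4301774 0.207097938
#> 3   0.5 0.2688608 0.504436211
```

Cross-checks by simulation:

```r
estimate_probs(p, "least_mismatch", n_draws = 1e6, seed = 1)   # genealogy MC
ds <- simulate_dataset(p, genome_length = 1e7, recomb_rate = 1e-8,
                       n_reads = 10000, seed = 1)               # sequences
score_assignments(ds, "least_mismatch")
write_dataset_fasta(ds, "simdata")                              # FASTA out
```

A command line covers the same operations
(`analytic | oracle | simulate | sweep | scenario`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","coalbin.R",package="coalbin"))')" \
    analytic --T_tf 400000 --read_length 96
#>            rule p_correct p_incorrect p_none ratio
#>  least_mismatch     0.538     0.00887  0.453  60.6
```

The `scenario` subcommand ships an `ursid` preset (ancient-eDNA bear
study: giant short-faced bear reads against spectacled / black bear
references, 5 My and 13.4 My splits at 6 years/generation, query age
14 ky) including read-length and deamination arms.

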