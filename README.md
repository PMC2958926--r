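# ebca — expert-based cooperative analysis

`ebca` is an R toolkit for analyses in which **formalised expert knowledge
steers the algorithm** and anomalies in the results steer the experts. It was
built for two recurring problems in health-system research:

1. **Benchmarking comparable care units** (e.g. small mental-health catchment
   areas) by *technical efficiency* when the inputs and outputs are only known
   through expert-elicited probability models — solved by Monte-Carlo
   stochastic **Data Envelopment Analysis** (DEA).
2. **Case-mix discovery** in mixed numeric/categorical patient data under
   semantic constraints — solved by **Clustering Based on Rules** (ClBR):
   records satisfying an if-then rule are condensed into a mass-weighted
   prototype before Ward agglomeration, so each rule class survives intact in
   the final partition.

Both engines are driven by a **prior knowledge base** (PKB) of if-then rules
with a small formal grammar, three-valued (Kleene) evaluation over missing
data, versioning and diffing. Interpretation-support tools (per-variable
significance tests, class panel graphs with marked characteristic cells,
bimodality/variance-inflation inconsistency detection) and agreement
statistics (sensitivity/specificity/PPV/NPV/likelihood ratios, Cohen's kappa,
consistency ICC) close the iterative elicitation loop.

## The statistics at the core

**DEA.** For unit *k* with input matrix *X* and output matrix *Y*, the
input-oriented envelopment programme is

    min θ   s.t.  Σⱼ λⱼ xⱼ ≤ θ x_k ,   Σⱼ λⱼ yⱼ ≥ y_k ,   λ ≥ 0
                  (+ Σⱼ λⱼ = 1 under variable returns to scale)

solved per Monte-Carlo draw of the stochastic inputs/outputs; "non-standard"
variables (whose direction contradicts the usual more-input-less-efficient
reading) are first reflected by `x' = max(x) + 0.1·range(x) − x`. Scores are
pooled until the per-unit block means stabilise, then classified into
efficient / nearly-efficient / uncertain / inefficient tiers.

**ClBR.** Entities are compared with a mixed squared dissimilarity

    d²(a,b) = α·(1/n_Q) Σ ((a_k−b_k)/s_k)² + β·(1/n_C) Σ δ_k(a,b)

(δ = 0/1 mismatch between categories, half-L1 between frequency
distributions), agglomerated by reciprocal-nearest-neighbour Ward using the
mass-weighted cost ΔW(A,B) = m_A m_B/(m_A+m_B)·d²(Ā,B̄) with Lance–Williams
updates, and cut where the Calinski–Harabasz pseudo-F
`CH(k) = (B/(k−1))/(W/(n−k))` peaks.

## Worked example: rule-guided case-mix

```r
library(ebca)
g  <- generate_patients(patient_config(n = 306, k = 3, separation = 6, seed = 7))
kb <- example_patient_kb(g$table)
print(kb)
#> Knowledge base (clbr mode), version 1, 2 rule(s)
#>   r1: if (((GAFCLA < 40) or (GAFSOCIAL < 40)) and ((MAXECFOS_A > 15) and
#>       (MAXECFOS_B = Every_Day))) then severely-ill
#>   r2: if ((INGRESE = WORK) and ((GAFCLA > 70) or (GAFSOCIAL > 70))) then good-condition

res <- clbr_cluster(g$table, kb, kmax = 8)
print(res)
#> Rule-guided clustering: 3 classes over 306 records
#>   class 1: 83 record(s) [data-driven]
#>   class 2: 114 record(s) [rule-seeded]
#>   class 3: 109 record(s) [rule-seeded]
print(res$ch)
#> Calinski-Harabasz curve (k* = 3 ):
#>  k      ch
#>  2  688.46
#>  3 1695.56
#>  4 1451.90
#>  ...
adjusted_rand_index(res$partition, g$truth)
#> [1] 1
```

The Calinski curve peaks at the planted k = 3; the two rule-seeded classes are
exactly the severely-ill and good-condition profiles the rules describe, and
the partition recovers the planted truth perfectly (ARI 1).

## Worked example: Monte-Carlo DEA benchmarking

```r
g    <- generate_sha(sha_config(), seed = 7)        # 12 synthetic areas
b    <- bmhcc_bounds()                              # expert-model ranges
scen <- scenario("bmhcc", b$variable[b$role == "dea-input"],
                          b$variable[b$role == "dea-output"])
pool <- run_monte_carlo(g$spec, config = dea_config(), scen = scen,
                        seed = 11, control = mc_control(block_size = 250))
print(pool)
#> Monte-Carlo DEA pool: 500 run(s), 12 DMU(s), converged (seed 11)
#>    unit   mean        sd frac_efficient
#>  area01 1.0000 0.000e+00          1.000
#>  ...
#>  area10 0.8759 6.631e-02          0.048
tiers  <- classify_tiers(pool)
expert <- setNames(ifelse(g$truth, "inefficient-group", "efficient-group"),
                   names(g$truth))
compare_with_expert(tiers, expert)$diagnostics
#>   sensitivity: 1 [0.676, 1]
#>   specificity: 0.25 [0.0456, 0.699]
#>   PPV:         0.7273 [0.434, 0.903]
#>   ...
```

With 8 inputs and 4 outputs over only 12 units, most units touch the frontier
in most draws — the classic discrimination limit of DEA at small n, and the
kind of model-vs-expert disagreement the interpretation loop is meant to
surface.

## Command line

```sh
Rscript inst/cli/ebca.R synth patients --seed 3 --out data/
Rscript inst/cli/ebca.R clbr --table data/patients.csv \
        --meta data/patients_meta.yaml --kb rules.txt --seed 4 --out results/
Rscript inst/cli/ebca.R dea  --table sha.csv --meta sha_meta.yaml \
        --spec stochastic.yaml --orientation input --rts constant \
        --seed 4 --out results/
```

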