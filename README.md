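# illnessdeath

Forward and inverse modelling of chronic-disease epidemiology in the
irreversible three-state **illness-death model**: Healthy → Diseased → Dead,
with a direct Healthy → Dead transition. The transition hazards are the
incidence `i(t, a)`, the mortality `m0(t, a)` of the healthy and the
mortality `m1(t, a, d)` of the diseased, on the three time scales calendar
time `t`, age `a` and disease duration `d`.

The package is for epidemiologists and biostatisticians who want to

* compute the **age-specific prevalence** `p(t, a)` implied by a set of
  incidence and mortality hazards (scenario planning, burden projections), or
* estimate the **age-specific incidence** of a chronic disease from **two
  cross-sectional prevalence surveys**, avoiding a longitudinal follow-up
  study.

## The model

With `S(t, a)` the healthy and `C(t, a, d)` the duration-resolved diseased
population of a birth cohort, the balance equations are

    (∂t + ∂a) S        = -(m0 + i) S
    (∂t + ∂a + ∂d) C   = -m1 C,         C(t, a, 0) = i(t, a) S(t, a)

and the prevalence is `p = C*/(S + C*)` with `C*(t, a) = ∫ C(t, a, δ) dδ`.
Three equivalent computational routes are implemented:

1. **Duration integral** (`prevalence_keiding()`): the explicit solution

       p(t,a) = N / (M(a) + N),
       N = ∫₀ᵃ i(t-δ, a-δ) M(a-δ) exp(-M₁(t,a,δ)) dδ,

   where `M(y) = exp(-∫₀ʸ (m0 + i))` and `M₁` is the cumulative diseased
   mortality along the disease spell, integrated by Romberg quadrature with
   prescribed accuracy.

2. **Prevalence PDE** (`solve_prevalence_pde()`):

       (∂t + ∂a) p = (1 - p) (i - p (m1* - m0)),   p(t, 0) = 0,

   integrated by fixed-step RK4 along characteristic lines `t - a = const`,
   where `m1*` is the duration-averaged mortality of the diseased.

3. **General-mortality form** (`solve_prevalence_general()`), for the common
   situation where only the whole-population mortality `m` and the relative
   mortality `R = m1*/m0` are known:

       (∂t + ∂a) p = (1 - p) (i - m · p(R-1)/(p(R-1)+1)),

   the fraction being the population attributable fraction of mortality.

The inverse problem (`estimate_incidence()`) solves the PDE for `i`,

    i = (∂t + ∂a)p / (1 - p) + p (m1* - m0),

with the prevalence and its cohort-direction derivative approximated from
two surveys at `t0` and `t0 + Δ` by midpoint averaging and central
differencing along cohorts.

## Worked example: dementia in German males

The packaged benchmark simulates two dementia prevalence surveys (2010 and
2015) from known rates — incidence `i(a) = exp(-12.8 + 0.11 a)` for ages 50+,
healthy mortality `m0(t, a) = exp(-9.0 + 0.085 a - t ln 1.01)` with `t` in
years since 1960, and diseased mortality `m1 = 2.63 m0` — then recovers the
incidence from the two surveys alone and compares with the truth:

```r
library(illnessdeath)
rates <- dementia_rates()
prevalence_keiding(rates, t = to_model_time(rates, 2010), a = 80)
#> [1] 0.09397229

tab <- reproduce_table1()
print(tab)
#>   Age True incidence Calculated incidence Relative error (%)
#>  62.5      0.0026718            0.0027048               1.24
#>  65.0      0.0035175            0.0035598               1.20
#>  67.5      0.0046309            0.0046843               1.15
#>  70.0      0.0060967            0.0061633               1.09
#>  72.5      0.0080266            0.0081078               1.01
#>  75.0      0.0105672            0.0106640               0.92
#>  77.5      0.0139120            0.0140243               0.81
#>  80.0      0.0183156            0.0184417               0.69
#>  82.5      0.0241131            0.0242508               0.57
#>  85.0      0.0317456            0.0318934               0.47
#>  87.5      0.0417941            0.0419538               0.38
#>  90.0      0.0550232            0.0552035               0.33
#>  92.5      0.0724398            0.0726590               0.30
#>  95.0      0.0953692            0.0956573               0.30
#>  97.5      0.1255564            0.1259532               0.32
max(abs(tab$relative_error))
#> [1] 1.236234
```

Reading the table: at age 80 the true dementia prevalence in 2010 is about
9.4%; the two-survey estimator recovers the generating incidence at every
age between 62.5 and 97.5 with an absolute relative error below 2% (at most
1.24%), entirely from cross-sectional data plus the assumed mortalities.
The residual error is the linearization error of the two finite-difference
approximation steps; it would vanish for a prevalence surface linear in
`(t, a)`.

The same study can be run with duration-dependent diseased mortality
(`run_duration_experiment()` with a `duration_profile()`), which shows how a
misspecified constant relative mortality biases the estimates at high ages.

Equivalent shell interface:

```sh
Rscript inst/cli/illnessdeath.R reproduce-table1 --out table1.csv
Rscript inst/cli/illnessdeath.R forward --rates inst/extdata/dementia_germany.yaml \
    --year 2010 --year2 2015 --ages 60:100:2.5 --out surface.csv
```

## File formats

* Rate configuration (YAML): blocks `incidence`, `mortality_healthy`
  (`beta0`, `beta_age`, `beta_time`, optional `min_age`),
  `relative_mortality` (`constant:` or `breakpoints`/`values`/`default`),
  `time_origin`. See `inst/extdata/dementia_germany.yaml`.
* Cross-section CSV: header `age,prevalence`.
* Prevalence surface CSV: header `time,age,prevalence`.
* Estimate CSV: header `age,incidence,midpoint_prevalence,directional_derivative`.
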