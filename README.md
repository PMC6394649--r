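# cwresbias

Structural model diagnostics for nonlinear mixed-effects (NLME) models by
parametric modeling of conditional weighted residuals (CWRES), with
back-correction of the induced conditional-prediction bias.

## Who this is for

Pharmacometricians and biostatisticians evaluating population models of
longitudinal data (PK, glucose-insulin dynamics, ...) who want more than a
residual plot: a likelihood-ratio quantification of how much a structural
misspecification costs in objective function value, and an estimate of how
far — absolutely and in percent — the model's conditional predictions are
displaced from the truth.

## The method

For subject *i*, FOCE linearization around the empirical Bayes estimates
η̂ᵢ gives the conditional moments and CWRES:

    E(Yᵢ)   = f(θ, η̂ᵢ) − (df/dη)|η̂ᵢ · η̂ᵢ
    COV(Yᵢ) = (df/dη)|η̂ᵢ · Ω · (df/dη)'|η̂ᵢ + diag((dh/dε)|₀ · Σ · (dh/dε)'|₀)
    r       = COV(Yᵢ)^(−1/2) (yᵢ − E(Yᵢ))

Under a correct model r ~ N(0, 1). CWRES of one dependent variable are then
fitted with a base mixed model `ỹᵢⱼ = Θ₁ + ηᵢ + εᵢⱼ` and an extension that
frees one mean per bin of an independent variable (time, or any DV's
population prediction). The improvement

    ΔOFV_Bias = OFV_Base − OFV_Extended   ~  χ²(N) under the null

quantifies the misspecification; the estimated bin means **b** are mapped
back to prediction scale through the same covariance root,

    δᵢ = −COV(Yᵢ)^(1/2) · b̀,

so `E(Yᵢ) − δᵢ` is the bias-corrected conditional prediction and
%δ = 100·δ/E(Yᵢ) its relative size. Both the fitting of the CWRES mixed
model (exact profiled maximum likelihood via the compound-symmetry closed
form) and the FOCE engine are implemented in the package; quantile and
randomized binning (with a 500-replicate envelope study) are included.

## Worked example

The bundled scenario simulates 100 subjects from a two-compartment IV-bolus
model on a standard IVGTT sampling design (0.33 g/kg, 32 samples over
240 min) and analyzes them with a one-compartment model, refitted by FOCE:

```r
library(cwresbias)
sc <- make_pk_scenario(seed = 101, n_subjects = 100)
qa <- run_qa(sc$mis_model, sc$dataset, true_model = sc$true_model,
             refit = TRUE, seed = 101)
qa
#> <cwres_qa> seed 101; dOFV_bias per (DV x IDV):
#>    dv       idv n_bins delta_ofv_bias df critical_value significant
#>  conc      TIME     10           3680 10          18.31        TRUE
#>  conc PRED_conc     5           2891  5          11.07        TRUE
```

The missing distribution phase is detected overwhelmingly against both
IDVs (ΔOFV_Bias 3680 and 2891 versus critical values 18.3 and 11.1). The
binned view shows where and how large the prediction bias is:

```r
cbind(round(qa$cells[["conc.TIME"]]$correction$binned, 2),
      pct_known = round(qa$cells[["conc.TIME"]]$known$binned$pct_known, 2))
#>    bin   n     b   delta pct_delta pct_known
#> 1    1 300  1.61 -625.14    -35.59     25.03
#> 2    2 300  0.85 -335.72    -19.74     16.14
#> 3    3 400  0.03  -40.46     -2.52      2.51
#> 4    4 300 -0.61  163.63     11.12    -10.14
#> 5    5 300 -0.76  203.64     14.67    -14.51
#> 6    6 300 -0.82  210.52     16.55    -16.76
#> 7    7 300 -0.73  174.59     15.88    -15.89
#> 8    8 400 -0.45  101.96     12.15     -9.91
#> 9    9 300  0.32   -2.30     -0.42      4.17
#> 10  10 300  1.14  -39.81    -17.24     18.02
```

Reading the first row: in the earliest time bin the CWRES mean is +1.61
(the data sit above the one-compartment predictions), the conditional
predictions are estimated to be displaced by δ ≈ −625 concentration units,
i.e. under-predicted by ≈36%; the reference computed from the known truth
(`pct_known`, displacement relative to the true conditional prediction,
hence the opposite sign — see `?known_bias`) puts it at 25%. In mid bins
the one-compartment model over-predicts by 10–17%, in close agreement with
the reference. Because the true model generated the data, `run_qa` could
compute that reference; on real data you get `b`, `delta` and `pct_delta`.

A thin command-line front-end is provided:

```sh
Rscript inst/cli/cwres-qa.R --demo --seed 1 --out qa-out       # exit 2 = bias detected
Rscript inst/cli/cwres-qa.R --dataset data.csv --config cfg.yaml --out qa-out
```

## Documentation

The methods vignette (`vignettes/cwres-bias-diagnostics.Rmd`) describes the
model chain, the tunable parameters, numerical choices, what the bundled
synthetic scenarios do and do not demonstrate, and known limitations.
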