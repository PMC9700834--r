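# stcarmap

Bayesian spatio-temporal disease mapping for zone-level count data from
repeated survey rounds, built around the BYM-style conditional
autoregressive (CAR) Poisson model used in small-area epidemiology. The
motivating application is mapping childhood anemia risk across a country's
administrative zones over several national survey rounds, but the machinery
is generic to any areal count outcome with denominators.

For zone *i* and period *k* the package fits

    O_ik ~ Poisson(mu_ik)
    log(mu_ik) = log(E_ik) + alpha + u_i + v_i + beta1 * t_k + x_ik' beta

where `E_ik` is the internally standardized expected count
(`E = n * pooled rate`, so `sum(E) = sum(O)`), `u` is a spatially structured
intrinsic-CAR (ICAR) random effect on the queen-contiguity graph, `v` an
unstructured exchangeable effect, `beta1` a linear time trend, and `x_ik`
zone-level quartile covariates (maternal education, socio-economic status,
maternal anemia; quartile 1 reference). Estimation is adaptive
Metropolis-within-Gibbs MCMC with conjugate Gibbs updates for the two
precisions, implemented in C++.

The pipeline covers, end to end:

1. **Geometry & adjacency** — read zone polygons from GeoJSON, build and
   validate the binary queen-contiguity weight matrix
   (`read_geojson()`, `queen_adjacency()`, `validate_adjacency()`).
2. **Tabulation** — individual records to zone×period counts, descriptive
   frequency tables, and quartile zone covariates
   (`tabulate_counts()`, `descriptive_table()`, `quartile_covariates()`).
3. **Expected counts & crude risk** — internal direct standardization and
   the SMR surface (`expected_counts()`, `crude_rr()`).
4. **Model fitting** — `car_model_spec()`, `sampler_config()`, `run_mcmc()`.
5. **Diagnostics** — Gelman–Rubin, autocorrelation, batch-means MC error,
   DIC model comparison, overdispersion check (`diagnostics_report()`,
   `dic()`).
6. **Risk surfaces** — smoothed RR with 95% credible intervals, exceedance
   probabilities `P(RR > 1 | data)`, map classes, coefficient RR tables,
   GeoJSON export (`risk_surface()`, `fixed_effect_table()`).
7. **Synthetic data** — a first-class generator (`simulate_dataset()`) that
   emulates the restricted survey microdata on a 72-zone lattice with known
   true parameters, plus `table1_fixture()`, a descriptive fixture whose
   margins reproduce the published survey tabulation exactly.

`run_pipeline()` wires all stages together from one (optionally YAML)
config, writing every stage artifact plus a hash manifest; identical configs
reproduce identical files.

## Worked example

A full synthetic run on the default 8×9 zone lattice (72 zones, 3 survey
periods, ~85 children per zone-period):

```r
library(stcarmap)

res <- run_pipeline(pipeline_config(
  out_dir = "demo_run", seed = 1,
  simulate = list(rows = 8, cols = 9),
  sampler = list(n_chains = 2, n_burnin = 5000, n_iter = 20000, thin = 10)))

unlist(res$dic)
#>       Dbar       Dhat         pD        DIC
#> 1486.05442 1426.32178   59.73264 1545.78707

head(res$fixed_effects[, c("parameter","mean","sd","rr","rr_lo","rr_hi","significant")], 5)
#>     parameter    mean     sd   rr rr_lo rr_hi significant
#> 1       alpha -0.4296 0.0528 0.65  0.59  0.72        TRUE
#> 2       beta1  0.0206 0.0111 1.02  1.00  1.04       FALSE
#> 3 beta_edu_q2  0.1276 0.0392 1.14  1.05  1.23        TRUE
#> 4 beta_edu_q3  0.2285 0.0403 1.26  1.16  1.36        TRUE
#> 5 beta_edu_q4  0.1791 0.0428 1.20  1.10  1.30        TRUE

head(res$surface, 4)
#>   zone_id period crude_rr rr_med rr_lo rr_hi exc_prob rr_class prob_class
#> 1   Z_1_1   2005    1.433  1.468 1.284 1.664  1.00000     high      0.8-1
#> 2   Z_1_2   2005    1.125  1.128 0.993 1.271  0.96750     high      0.8-1
#> 3   Z_1_3   2005    0.955  1.022 0.881 1.171  0.61650   middle    0.5-0.8
#> 4   Z_1_4   2005    0.888  0.786 0.675 0.914  0.00075      low     0-0.25
```

Reading the output: `beta1` is the per-period log-RR trend
(`rr` exponentiates it); the `beta_*` rows estimate the quartile covariate
effects — here the data were generated with true effects of 0.05–0.2, and
the fitted RRs of 1.14–1.26 recover them (`alpha` absorbs the re-basing done
by internal standardization). In the surface, zone `Z_1_1` in 2005 has a
smoothed RR of 1.47 (95% CrI 1.28–1.66) and exceedance probability 1.00:
a zone the probability map would flag as high-risk (`prob_class` 0.8-1),
while `Z_1_4` is credibly below-average risk.

The crude RR column is the unsmoothed SMR `O/E`; comparing it with `rr_med`
shows the CAR smoothing: extreme SMRs in small cells get pulled toward their
neighbours while well-supported elevations survive.

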