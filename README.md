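# siteharm

Harmonization of structural connectome network measures across MRI
acquisition sites, via a conditional variational autoencoder whose latent
space is trained to be uninformative of site while staying predictive of
age, sex, and the network's connectivity profile.

## The problem

Structural connectomes — weighted undirected graphs whose nodes are atlas
regions and whose edge weights count tractography streamlines — are
estimated through acquisition- and software-sensitive pipelines. Pooling
connectomes from several scanners introduces systematic "site effects" that
propagate into every graph-theoretic summary (modularity, efficiency,
strength, ...) and confound multi-site studies of aging and
neurodegeneration.

## The method

Each connectome's upper triangle `x` (length `n(n-1)/2`) is encoded by a
two-layer ReLU network into a Gaussian posterior `q(z|x) = N(mu_z,
diag(sigma_z^2))`. A decoder conditioned on a one-hot site code `c`
reconstructs `x` in the domain of site `c`; prediction heads read age and
sex from `z` alone and the twelve network measures from `(z, c)`. Training
minimizes

    l_total = l_recon(c) + l_kl + l_age + l_sex + l_B(c)

where `l_kl = KL[q(z|x) || N(0, I)]`. Because the decoder receives the site
label for free, any site information inside `z` is redundant, and the KL
penalty — which together with conditional reconstruction bounds the mutual
information `I(z, c)` — prunes it away, while the heads hold age, sex and
connectivity information in place. At test time the site code is simply set
to a chosen target domain: every subject's connectome and measures are
rendered "as if acquired" at that site, with `z = mu_z` (deterministic, no
sampling).

The package also provides: readers/writers for delimited connectome
matrices (MRtrix `tck2connectome`-compatible) and cohort metadata; a
weighted network-measure toolbox (12 measures, Brain Connectivity Toolbox
conventions, enumeration-oracle-tested); maximum-cardinality demographic
matching (same sex, ±1 year); effect-size benchmarks (Cohen's D,
Mann–Whitney U); bootstrap stability analysis; and a synthetic two-site
cohort generator with known ground-truth age, sex and site effects.

## Worked example

```r
library(siteharm)

# A two-site synthetic cohort with designed site/age/sex effects
gcfg <- generator_config(n_per_site = 150)      # 84-node connectomes
gen  <- generate_cohort(gcfg)
test <- generate_matched_testset(gcfg, 60)      # 60 matched pairs

# Site-biased network measures are the training targets
meas <- measures_table(gen$cohort)

# Train the co-learning model
cfg   <- vae_config(input_dim = 3486, n_sites = 2, seed = 1)
model <- vae_train(gen$cohort, meas, cfg)

# Project the matched test set into the SITE1 domain
proj   <- project_cohort(test, model, "SITE1")
before <- measures_table(test)
after  <- proj$measures[proj$measures$route == "recomputed", ]
report <- harmonization_report(before, after)
subset(report, measure == "modularity")
#>      measure  phase cohens_d    U        p n1 n2 significant success_flag
#> 1 modularity before  -2.1994  181 1.98e-17 60 60        TRUE           NA
#> 2 modularity  after  -0.0965 1713 6.50e-01 60 60       FALSE         TRUE

unlist(biology_report(model, test)[c("sex_accuracy", "age_mae", "age_r2")])
#> sex_accuracy      age_mae       age_r2
#>     1.000000     3.504934     0.814317
```

The modularity row reads: before harmonization the two sites differ by a
very large standardized effect (Cohen's D = -2.2, Mann-Whitney p = 2e-17);
after projecting every test subject into the SITE1 domain and recomputing
modularity on the reconstructions, the effect is small (|D| = 0.097) and no
longer significant (p = 0.65) — while the latent space still recovers
held-out sex perfectly and explains 81% of age variance (MAE 3.5 years).

`harmonization_report()` prints, per measure and phase, the between-site
Cohen's D, the Mann–Whitney U and p, and a success flag: harmonization of a
measure succeeds when the post-harmonization |D| is below 0.2 and any
significant (p < 0.05) median difference present before is gone after.
`biology_report()` checks that the latent space still predicts held-out sex
(accuracy) and age (MAE in years, R²).

A thin command-line wrapper over these functions ships in
`inst/cli/siteharm` with `simulate`, `measures`, `train`, `harmonize`,
`evaluate` and `match` subcommands.

## See also

The methods vignette (`vignettes/connectome-harmonization.Rmd`) documents
the model, the measure conventions, the generator design, all numerical
choices, and known limitations.
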