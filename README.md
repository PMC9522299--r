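# idprel — multi-site reliability analysis for imaging-derived phenotypes

`idprel` is an R package for scientists running **travelling-heads**
studies: designs in which the same subjects are scanned at several MRI
sites so that between-site variance can be separated from between-subject
variance before a multi-site study is scaled up. It takes long-format
tables of imaging-derived phenotypes (IDPs) — regional volumes, cortical
thicknesses, tract FA values, and so on — and answers three questions per
IDP:

1. **Does site shift the mean?** Repeated-measures ANOVA
   (`F = MS_sessions / MS_error`) with Shapiro–Wilk normality and Mauchly
   sphericity diagnostics, Greenhouse–Geisser correction when sphericity
   fails, a Friedman rank cross-check, and Benjamini–Hochberg FDR control
   at 5% *within each IDP class*.
2. **Is the subject ranking preserved across sites?** The consistency
   intra-class correlation ICC(3,1) from the two-way variance-component
   decomposition,

   ```
   ICC(3,1) = (MS_subjects − MS_error) / (MS_subjects + (k−1)·MS_error)
            = σ²_subject / (σ²_subject + σ²_error),
   ```

   which ignores additive site offsets (site is a fixed effect) but is
   sensitive to site scale changes. Closed-form ANOVA and REML estimators
   are provided, plus pairwise-site ICCs and Pearson/Spearman site
   correlation matrices.
3. **Is that reliability good by single-scanner standards?** The observed
   ICC is benchmarked against the distribution of ICCs the same estimator
   produces on matched-size subsamples (default 1000 draws of 8 subjects)
   of a large test-retest reference cohort, with an empirical two-sided
   p-value.

A synthetic-cohort generator (`generate_travelling_heads()`,
`generate_reference_cohort()`) simulates both designs from known variance
components `y_ij = μ + b_j + s_j(a_i + e_ij)`, so every statistic can be
validated against ground truth. `rm_anova_power()` gives the analytic
power of the site-effect test via the noncentral F distribution.

## Worked example

Simulate a 4-site travelling-heads cohort (8 subjects, 3 Siemens sites +
1 GE-like site with an injected offset and scale change) and a 2,817-subject
test-retest reference, then run the full battery over the all-sites and
Siemens-only subsets:

```r
library(idprel)

specs <- idp_specs_from_icc(40, 0.8, class_label = rep(c("volumes", "thickness"), 20))
study <- generate_travelling_heads(
  sessions = travelling_sessions(ge_offset = 0.8, ge_scale = 1.4),
  specs = specs, seed = 1
)
reference <- generate_reference_cohort(2817, specs, seed = 2)

report <- run_pipeline(study, reference, n_resamples = 1000, seed = 3)
glance(report)
#> # A tibble: 2 × 5
#>   subset  n_idps n_significant mean_icc sd_icc
#>   <chr>    <int>         <int>    <dbl>  <dbl>
#> 1 all         40            20    0.760  0.118
#> 2 siemens     40             0    0.776  0.133
```

With the GE-like session included, half of the 40 IDPs show an
FDR-significant mean site effect and the mean ICC drops; restricted to the
three null Siemens sites, no mean effects survive FDR and reliability
matches the generating truth (ICC 0.8, estimated with the known ~0.04
small-sample downward bias at n = 8). Per-class summaries mirror the same
contrast:

```r
report$per_class
#> # A tibble: 4 × 9
#>   subset  class_label mean_icc sd_icc n_idps n_skipped prop_mean_effect
#>   <chr>   <chr>          <dbl>  <dbl>  <int>     <int>            <dbl>
#> 1 all     thickness      0.728 0.140      20         0             0.45
#> 2 all     volumes        0.791 0.0820     20         0             0.55
#> 3 siemens thickness      0.733 0.162      20         0             0
#> 4 siemens volumes        0.818 0.0807     20         0             0
```

`tidy(report)` returns the per-IDP table (F, Greenhouse–Geisser-corrected
p, Mauchly W/p, ε, Shapiro p, Friedman p, FDR flag, ICC, reference
quantiles and empirical p); `autoplot(report, "pvalues")` and
`autoplot(report, "icc")` draw the corresponding class panels.

The design power calculation that motivates n = 8:

```r
rm_anova_power(8, 4, eta_squared = 0.2)   # "large" site effect
#> [1] 0.8774639
rm_anova_power(8, 4, eta_squared = 0.1)   # "medium" site effect
#> [1] 0.5117059
```

A thin command-line front end (`inst/exec/idprel`) exposes the same
functionality as subcommands
(`simulate | site-effects | icc | benchmark | power | run`) for use on TSV
files from a shell.

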