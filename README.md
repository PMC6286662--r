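# ednacomp

Tools for comparing **composite** and **grab** water sampling schemes in
environmental DNA (eDNA) metabarcoding surveys of streams.

eDNA from macroorganisms travels as patchily distributed particles, so a
single bottle of water ("grab" sample) can badly misrepresent the local eDNA
pool at the moment it is filled. An autosampler can instead *composite* many
small aliquots over a time interval (here 12 × 45 mL over 3 h = 540 mL),
trading equipment cost for temporal averaging. `ednacomp` provides the full
analysis stack needed to quantify what that averaging buys:

* **Taxonomic assignment** (`assign_otu`, `assign_all`,
  `constrained_reassign`, `apply_taxon_adjustments`): a modified
  lowest-common-ancestor classifier over BLAST-style hit tables. For OTU
  hits with bit scores *b*, only HSPs with *b* ≥ floor and
  *b* ≥ (1 − *w*)·max *b* vote (per-locus presets: COI/euk-16S floor 250,
  *w* = 0.05; 12S floor 200, *w* = 0.02); the assignment is the LCA of the
  voting taxa. Species- and genus-level results whose mean percent identity
  falls below 95% / 90% are demoted one rank rather than discarded, never
  past family. For low-resolution loci, hits can be restricted to a
  watershed-specific expected-taxon list before re-assignment.
* **Count-table filtering** (`filter_min_run_count`, `censor_crosstalk`,
  `filter_length`, `collapse_rank`, `to_cpm`): run-wide minimum of 10
  reads, cross-talk censoring (total ≥ 10 *and* not exclusively
  singletons), per-locus amplicon length windows, genus/family collapsing
  with *incertae sedis* operational labels, counts-per-million.
* **Community metrics** (`morisita_dissimilarity`, `rarefy_richness`,
  `accumulation_curve`, `dispersion_to_centroid`, `detection_rates`,
  `time_match_pairs`): Morisita dissimilarity
  1 − 2Σxᵢyᵢ/((λₓ+λᵧ)NₓNᵧ) (near-independent of sequencing depth),
  hypergeometric rarefaction with exact standard errors, permutation
  t-test and Mann–Whitney test on distances to group centroids in a
  principal-coordinates embedding, and detection rates at matched effort
  (the longer composite series is parity-trimmed from both ends: 22→15
  drops 3+4, 22→18 drops 2+2).
* **Relative-abundance precision** (`compute_fractions`, `center_by_site`,
  `variance_f_test`, `two_way_anova`, `time_correlations`): per-sample
  fractions S/(S+C) of two focal genera per locus (retained when
  S+C ≥ 20), a two-sided variance-ratio F-test on site-centered values,
  Type II (default) or Type I two-way ANOVA by site and method, and
  fraction-versus-time correlations.
* **Ordination** (`logratio_transform`, `correlation_pca`,
  `spearman_matrix`, `within_family_profiles`): log-ratio transform with a
  single global pseudocount (half the smallest non-zero proportion),
  correlation PCA with a deterministic sign convention, Spearman matrices,
  unit-scaled within-family OTU profiles.
* **A synthetic deployment generator** (`default_study_scenario`,
  `simulate_counts`, `generate_toy_taxonomy_and_hits`): compound-Poisson
  particle capture with geometric clusters (clumping parameter *k*; mean
  cluster size 1 + 1/*k*, *k* = ∞ is Poisson), lognormal AR(1) flux
  patches, differential between-site retention, storage-time bacterial
  bloom and eukaryotic decay, fixed-size multinomial libraries, and
  sequencer cross-talk — plus toy taxonomies with known-truth hit tables
  for validating the classifier.

## Worked example

Simulate the default two-site deployment (22 composite bottles plus
triplicate grab events per site, 95 samples, 184 taxa) and run the full
comparison:

```r
library(ednacomp)
x <- simulate_counts(default_study_scenario(seed = 1))
x
#> <count_matrix> 95 samples x 184 taxa; total counts 1,900,000
#>   loci: 12S (2), 16S-bact (150), 16S-euk (5), COI (27)

res <- run_pipeline(x, pipeline_config(nperm = 9999, seed = 1))

round(res$site_means, 3)
#> downstream   upstream
#>      0.633      0.783
```

The *Salmo* fraction S/(S+C) drops from 0.783 upstream to 0.633 downstream
— the two genera enter premixed from the same upstream source, so the drop
measures differential particle settling over the 100-m reach, not source
change. The two-way ANOVA attributes the difference to site, not sampling
method:

```r
round(res$anova, 4)
#>                 SS  df     MS        F      P
#> Site        0.6275   1 0.6275 189.7655 0.0000
#> Method      0.0005   1 0.0005   0.1557 0.6939
#> Interaction 0.0031   1 0.0031   0.9384 0.3348
#> Within      0.3604 109 0.0033       NA     NA
#> Total       1.0007 112     NA       NA     NA
```

Eukaryotic community profiles, by contrast, are visibly more repeatable
under compositing: the mean Morisita distance to the method centroid is
0.105 for composite samples versus 0.186 for pooled grab triplicates
(permutation t-test p = 0.0289), while the well-mixed, near-Poisson
bacterial families show no method effect. The storage bloom diagnostic
(`res$bloom_time_spearman`, here −0.93) flags the psychrophilic family
whose growth in stored bottles displaces other reads.

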