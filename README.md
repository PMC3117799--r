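# mircalib

Calibration of circulating miRNA signatures for hematopoietic-cell
contamination in fractionated blood plasma.

Cell-free miRNAs in plasma are promising minimally invasive biomarkers,
but plasma preparations carry miRNA signal from red blood cells, white
blood cells and leukocytes (cell carryover and lysis during
centrifugation), which can mask or mimic truly circulating species.
`mircalib` implements, for probe-level miRNA microarray data from
fractionated blood, the full calibration workflow:

* **Preprocessing** — one-sided Wilcoxon rank-sum detection calls of each
  probe set against GC-matched anti-genomic background probes (exact by
  enumeration for combined n ≤ 20, tie-corrected normal approximation
  above), GC-stratified median background subtraction with clamping at 0,
  `log2(x + 16)` transform, rank-mean quantile normalization (cohort mode
  only) and median probe-set summarization.
* **Contaminant cataloguing** — features detected in 100% of each
  cellular class's samples (RBC, WBC, LEU), unioned into a catalogue, and
  set/matrix filtering against it.
* **Concordance & variability** — intensity-stratified Spearman rank
  correlation between fractions and against the pooled cellular ("LWR")
  profile, paired intensity tests, pairwise replicate stability per
  stratum, and coefficient-of-variation (sd/mean of linear intensity)
  comparisons, including the partition of cohort-detected features into
  `+S/+L` (also in contaminants) and `+S/-L` (circulation only).
* **Differential expression** — a from-scratch two-class unpaired SAM:
  modified t-scores `d = (mean_F − mean_M)/(s + s0)` with Tusher-style
  `s0` tuning, permutation expected order statistics, delta-sweep FDR
  estimation (estimated FDR = mean permuted exceedance count / observed
  call count; exactly 0 only when a call is more extreme than the entire
  permutation null), SAM-style q-values, linear fold changes,
  detection-call filtering and complete-linkage clustering.
* **Synthetic data** — a fractionation/cohort simulator with planted
  contaminant, circulating and differential feature sets plus truth
  records, so the whole pipeline is testable without array downloads.

## Worked example

```r
library(mircalib)

params <- sim_params(seed = 1)          # 847 probe sets, 313 contaminants,
run <- run_pipeline(tempdir(), params)  # 8M/10F cohort, full two-arm run

run$catalog
#> Contaminant catalogue: 313 probe sets (RBC 313, WBC 313, LEU 313)

length(run$retained)
#> [1] 534

run$partition
#> Detected-in-circulation partition (rate 0.5):
#>   +S/+L (also in contaminants): 286
#>   +S/-L (circulation only):     507

run$sam
#> SAM (two-class unpaired): 534 features, 1000 permutations, s0 = 0.01896
#>   delta = 0.8643  estimated FDR = 0.038
#>   significant at FDR 0.05 : 2 feature(s)
#>     mir-0282, mir-0659
```

Reading the output: the catalogue recovered all 313 planted cellular
features from the simulated RBC/WBC/LEU fractions; removing them from the
847 human probe sets leaves 534 for the cohort analyses. Of the features
detected in at least 9 of the 18 cohort samples, 286 also map to the
contaminant catalogue (`+S/+L`) and 507 are specific to circulation. SAM
on the 534 calibrated features called 2 features up-regulated in females
at a 5% FDR target for this seed — both are planted effects (the other
two planted features fell below the threshold at this seed; power at
8-vs-10 subjects is marginal for 1.8-fold effects).

The methods vignette
(`vignettes/calibrating-circulating-mirnas.Rmd`) documents the model, the
tunable parameters, the simulator and the package's design choices.

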