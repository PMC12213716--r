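# fieldbridge

Benchmarking super-resolution harmonization of paired low-field (1.5T-like)
and high-field (3T-like) brain MRI, end to end and fully reproducible from a
single seed.

Mixed-field cohorts are common in longitudinal neuroimaging: the same
subject may carry both a 1.5T and a 3T T1-weighted scan, and the
field-strength gap (SNR, contrast, effective resolution) confounds pooled
analyses. One harmonization route is computational — super-resolve the
low-field image and measure how close it lands to the subject's own
high-field scan. `fieldbridge` packages that entire evaluation loop for
methodologists who want to compare SR methods under controlled conditions:

- **synthetic paired cohorts** — multi-tissue brain-like phantoms per
  subject with a degraded low-field counterpart (reduced contrast, blur,
  bias field, Gaussian noise with magnitude reconstruction, vendor gain,
  rigid misalignment), three vendor strata, same-vendor pairs only, plus
  same-session repeat scans;
- **rigid registration** — symmetric (halfway-space) MSE, coarse-to-fine,
  with a grid-seeded multi-start and an NCC-based automated alignment check
  with seeded restarts;
- **five SR methods** — bicubic (Catmull-Rom) and Lanczos-3 interpolation,
  plus ESPCN, SRGAN, and a transformer-CNN hybrid GAN (TCGAN) with a
  patch-level discriminator, all running on a small deterministic
  neural-network engine implemented in the package (im2col convolutions,
  manual reverse-mode gradients, Adam) and validated against finite
  differences;
- **full-reference metrics** — PSNR (canonical and as-printed variants),
  SSIM (reference constants, oracle-validated), a deterministic perceptual
  feature distance, and IDP;
- **paired-design evaluation** — slice → subject → cohort averaging, vendor
  stratification, baseline and repeat-scan anchors, and pairwise paired
  t / cluster-robust comparisons with 95% CIs and Holm adjustment.

## The IDP metric

The headline metric is **Intensity Differences in Pixels (IDP)**: the
fraction of pixels whose relative intensity difference from the reference
strictly exceeds a threshold ψ,

    Q(i,j) = 1  if  |P_ref(i,j) − P_syn(i,j)| / P_ref(i,j) > ψ
    IDP     = Σ Q(i,j) / N,    ψ ∈ {0, 10, 20, 25, 50, 75}%

computed on 8-bit quantized images, so IDP(ψ=0) counts pixels with at least
one gray level of difference. Pixels with zero reference are handled by an
explicit documented policy (hallucinated signal counts; a masking
alternative is available). Two anchors give IDP values context: the
original low-vs-high baseline (a method must be significantly better to
matter) and the IDP between two repeated low-field scans (the
measurement-variability floor).

## Worked example

```r
library(fieldbridge)
config <- pipeline_config(
  subjects = c(A = 2, B = 1), n_slices = 4, size_px = 64,
  methods = c("bicubic", "lanczos"), metrics = c("psnr", "ssim", "idp"),
  seed = 7)
report <- run_pipeline(config)
print(report)
#> evaluation_report: 3 subjects, 288 slice records, methods: bicubic_vs_3, lanczos_vs_3
#> ranking by IDP(psi=0):
#>    comparison     value rank  tied
#>  bicubic_vs_3 0.9919230    1 FALSE
#>  lanczos_vs_3 0.9922485    2 FALSE
#>  orig1.5_vs_3 0.9942830    3 FALSE
```

Reading this: with noise at 3% of the intensity range, almost every pixel
differs from the reference by ≥ 1 gray level (IDP(0) ≈ 0.99), and
interpolation barely moves that needle — classical upsampling cannot remove
noise. PSNR tells the same story from the other side:

```r
report$rankings$psnr
#>    comparison    value rank  tied
#>  lanczos_vs_3 23.89563    1 FALSE
#>  bicubic_vs_3 23.82221    2 FALSE
#>  orig1.5_vs_3 23.19827    3 FALSE

report$anchors$repeat_scan_idp
#> [1] 0.9424
```

The learned methods are where the gap opens: in the full benchmark (see
below) ESPCN/SRGAN/TCGAN cut cohort IDP(0) from ≈ 0.99 to 0.63–0.73 while
interpolation stays at the baseline — the qualitative pattern this kind of
paired-design study is built to detect. Pairwise uncertainty comes from the
same report:

```r
report$pairwise$idp_psi0[["bicubic_vs_3|lanczos_vs_3"]]
#> bicubic_vs_3 vs lanczos_vs_3 [idp, psi=0]: diff=-0.00032552,
#>   95% CI (-0.0013576, 0.00070653), p=0.308 (paired_t, n=3)
```

A thin CLI over the same functions lives at `inst/cli/fieldbridge.R`
(`run`, `generate`, `metrics` subcommands).

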