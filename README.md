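# retinapair

Multi-modal contrastive pre-training for paired retinal imaging in R: a 2D
fundus-image encoder $h^x$ and a 3D OCT-volume encoder $h^y$ are trained so
that scans of the same eye map to nearby points of a shared d-dimensional
embedding space. Two objectives are implemented on row-normalized
embeddings with cosine similarities $S_{ij} = u_i \cdot v_j$:

* **CLIP / InfoNCE** — symmetric cross-entropy of softmax($S/\tau$) against
  the matched diagonal;
* **CLOOB / InfoLOOB with modern Hopfield retrieval** — batches are passed
  through a continuous Hopfield memory
  $H_M(q) = \mathrm{normalize}(M^\top \mathrm{softmax}(\beta M q))$ and
  scored by the leave-one-out bound
  $-s_{ii}/\tau + \log\sum_{j\neq i} e^{s_{ij}/\tau}$, which has no
  saturation floor.

Around that core the package provides the uni-modal self-supervised
baselines (SimCLR, BYOL, VICReg) with a discardable 128-d projection head,
the preprocessing stack for both modalities (grayscale, bilinear resize to
224x224, ordered uniform subsampling of 20 B-scans, image/volume-wise
normalization, SimCLR-style view augmentations), patient-level stratified
partitioning (80/15/5 pre-training, 80/10/10 downstream), cross-modal
top-k retrieval evaluation with exact Clopper-Pearson 95% intervals,
linear probing and fine-tuning with bootstrap variance, and the
modality-interchange evaluation (fundus embeddings fed to an OCT-trained
prediction head). A synthetic paired-cohort generator with shared latent
factors and clinical-style labels (visual acuity, central band thickness,
fluid presence, disease class, treatment need from injection counts,
conversion) makes every stage runnable on one CPU with no data download.
Training runs on an in-package reverse-mode autodiff over dense matrices
with AdamW; every loss is validated against brute-force oracles and
finite-difference gradients.

Who it is for: researchers studying contrastive multi-modal representation
learning for ophthalmic imaging who need a tested, deterministic,
desk-scale reference implementation of the full pipeline.

## Worked example

```r
library(retinapair)

config <- demo_config(seed = 1)    # 250 patients, 2-4 visits, tiny encoders
bundle <- run_demo(config, out_dir = "demo_out")

r <- bundle$retrieval_clip$one_per_patient
r$fundus_to_oct$topk
#>      top1      top5     top10
#> 0.7027027 1.0000000 1.0000000
r$oct_to_fundus$topk
#>      top1      top5     top10
#> 0.8108108 0.9459459 1.0000000
bundle$retrieval_clip$one_per_patient_avg  # averaged over 20 visit draws
#> $top1_fundus_to_oct 0.776   $top1_oct_to_fundus 0.728   $n 37
round(chance_topk(37, 1), 3)
#> [1] 0.027

bundle$probe_bcva$pretrained$metrics$r2    # acuity probe on OCT embeddings
#> [1] 0.6535585
bundle$probe_bcva$random_init$r2_mean      # random-initialization control
#> [1] 0.06488897
bundle$interchange_fluid
#> $metric   "auroc_weighted"
#> $source   0.786   $swapped 0.694   $decay 0.116
```

Reading: on the held-out test pool of 37 patients, CLIP pre-training ranks
the matching OCT volume first for 70-81% of queries (chance is
1/37 = 0.027) and within the top 5 almost always; CLOOB lands at 0.61/0.65
on the same pool. A linear probe on frozen OCT embeddings explains ~65% of
the visual-acuity variance (bootstrap 0.649 +/- 0.067) while the same
probe on random-initialization encoders explains ~6%; and fundus
embeddings pushed through the head that was trained on OCT embeddings
lose ~12% of the fluid-detection AUROC. On the harder all-samples pool
(110 scans, every visit a candidate), top-1 is 0.25 and 82% of retrievals
come from the query's own patient — repeat visits of an eye map close
together. Numbers above are from this exact run (`demo_config(seed = 1)`);
other seeds vary by several points (the methods vignette quantifies this).
`run_demo()` also writes all reports as JSON plus per-epoch loss histories
to `out_dir`.

A thin command-line wrapper with `synth`, `demo` and `eval-retrieval`
subcommands is installed at `inst/cli/retinapair.R`.

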