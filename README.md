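# bgnet

Patient-level benign/malignant tumor classification from multi-plane MRI,
built around three fusion stages: a **complete bipartite graph** pairing a
patient's axial and sagittal tumor images, **input/feature-layer fusion**
of each pair through a hybrid convolution + shifted-window-attention
backbone (*ResNetST*), and an **age-prior-weighted, top-k-screened
decision vote** that turns the per-pair probabilities into one diagnosis
per patient.

## Who this is for

Researchers studying multi-view / multiple-instance aggregation in medical
image classification who want a fully inspectable, CPU-reproducible
reference implementation of the bipartite multi-plane fusion framework —
including a seeded synthetic tumor-phantom generator, so every stage runs
and is testable without any clinical data. The neural backbone is written
in plain R with explicit forward/backward passes; there is no GPU or
deep-learning-framework dependency.

## The method in brief

For a patient with axial set $A$ ($n$ images) and sagittal set $B$
($m$ images), every pair $e(i,j)$, $i \in A$, $j \in B$ is a matching edge
of the complete bipartite graph $G(A \cup B, E)$. Each edge's two tumor
crops (box + 40–60 px margin) are spliced vertically (axial above,
sagittal below), resized to a square 3-channel input, standardized, and
scored by ResNetST — conv stem, residual stages at 1/4 and 1/8
resolution, shifted-window attention stages, global average pooling, 2-way
softmax. At test time the $n \times m$ edge probabilities form the set
$C$; with an age prior $K$ learned from training prevalences,

$$C'_i = \lambda_1 C_i + \lambda_2 K(\text{age}), \qquad
  topk = \max(300, \lfloor |C|/2 \rfloor),$$

the $topk$ most confident elements are partitioned at $T = 0.5$ into $w$
malignant and $q$ benign votes ($= T$ discarded), and the patient is
called malignant iff $q/(q+w) \le w/(q+w)$. Metrics are patient-level
ACC / SE / SP (malignant positive), rank-statistic AUC, and Wald 95%
intervals $z\sqrt{p(1-p)/N}$ with $N$ the total case count.

## Worked example

```r
library(bgnet)

# 40 synthetic patients, strongly class-separable appearance
ph  <- phantom_config(n_patients = 40, texture_contrast = 3, seed = 11)
cfg <- experiment_config(
  mode = "bg", use_age = TRUE, phantom = ph, n_test_patients = 20,
  model = model_config(tiny_preset = TRUE),
  train = train_config(learning_rate = 0.005, epochs = 20, batch_size = 16),
  seed = 101)
res <- run_experiment(cfg)
res$metrics
#> <metrics_report> N=20 (threshold 0.50)
#>   AUC: 100.0 +/- 0.0 %
#>   ACC: 100.0 +/- 0.0 %
#>   SE:  100.0 +/- 0.0 %
#>   SP:  100.0 +/- 0.0 %
```

All 20 held-out phantom patients are classified correctly — the phantoms
here are deliberately high-contrast, so the ceiling is reachable: the
model was trained on bipartite edge draws, each test patient's
$n \times m$ edges were scored, and the decision vote produced the
patient-level labels summarized above (the ± values are the total-N Wald
half-widths). Individual pieces compose the same way by hand:

```r
p <- generate_dataset(ph)$patients[[1]]
enumerate_edges(p)
#> <edge_set> patient P001: 4 matching edges
fuse_patient(c(.6, .6, .4, .4, .3))
#> <patient_prediction> NA: benign (q=3, w=2, pb=0.600, pm=0.400, |S|=5)
compute_metrics(confusion_counts(TP = 45, FP = 23, TN = 61, FN = 4))
#>       ACC        SE        SP
#> 0.7969925 0.9183673 0.7261905
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/bgnet.R` (`phantom`, `run`, `fuse`, `evaluate` subcommands).

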