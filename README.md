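# pcsanet

Attention-augmented residual image classifiers for recognising small
objects — crop pests, lesions — that occupy only a few percent of a
cluttered frame. The package is aimed at researchers who want a fully
inspectable, dependency-light R implementation of the *parallel
channel-spatial attention* (PCSA) design together with everything needed to
exercise it end to end: offline dataset augmentation with leakage-free
stratified splitting, SGDM training with a plateau learning-rate schedule,
multi-class evaluation metrics, and a seeded synthetic-image generator so
that no external data are required.

## The model

A PCSA module applies two gates to the same feature map
$F \in \mathbb{R}^{C\times H\times W}$:

* **channel branch** — squeeze $z_c = \frac{1}{HW}\sum_{i,j} u_c(i,j)$,
  excite $s = \sigma(W_2\,\mathrm{ReLU}(W_1 z))$ with bottleneck ratio $r$,
  scale $Q = s \cdot F$;
* **spatial branch** — channelwise average and max maps combined
  elementwise, fused by a $7\times7$ convolution, gated by a sigmoid into
  $M \in (0,1)^{H\times W}$, giving $P = M \cdot F$;
* **fusion** — $G = \mathrm{ReLU}(Q \odot P)$.

The module is embedded after the trunk of every bottleneck residual block
(1×1 reduce → 3×3 → 1×1 expand, batch norm throughout), before the identity
addition. The default classifier uses stage depths 3, 6, 6, 3 (18 blocks),
a 7×7/2 stem with 3×3/2 max pooling, global average pooling and a dense
softmax head — 10 classes and 224-pixel inputs by default. `"se"`, `"cbam"`
and `"none"` block variants support ablation studies. Training uses SGD
with momentum in the previous-iterate form
$\theta_{i+1} = \theta_i - \alpha \nabla L(\theta_i) + m(\theta_i - \theta_{i-1})$
with L2 weight decay, per-epoch reshuffling, best-checkpoint selection, and
a plateau schedule that multiplies the learning rate by 0.1 after 2 epochs
without validation improvement.

See the methods vignette (`vignettes/pcsa-attention-networks.Rmd`) for the
full model description and design decisions.

## Worked example

Generate a small synthetic dataset, expand it five-fold with the offline
transforms, split it 8:2, train the reduced benchmark network, and
evaluate:

```r
library(pcsanet)

## 3 classes, 40 originals each, 32-pixel images
spec <- toy_dataset_spec(n_classes = 3, n_per_class = 40, side = 32, seed = 1)
ds   <- generate_toy_dataset(spec)

## offline augmentation + stratified split (counts: 5x per class, 8:2)
manifest <- split_dataset(expand_dataset(ds$manifest), 0.8, seed = 1)
manifest_report(manifest)
#>   class origin_images augmented_total train validation
#>       0            40             200   160         40
#>       1            40             200   160         40
#>       2            40             200   160         40
#>      NA           120             600   480        120

## train the reduced attention network (training set = originals + their
## four augmentation copies; held-out set = 45 fresh images)
data  <- toy_benchmark_data(seed = 1)
run   <- toy_benchmark(seed = 1, attention = "pcsa", data = data)
run$val_accuracy
#> [1] 1

## evaluate the returned checkpoint
ev <- evaluate_model(run$model, data$val)
round(c(P = ev$metrics$precision, R = ev$metrics$recall,
        F1 = ev$metrics$f1, acc = ev$metrics$accuracy), 4)
#>   P   R  F1 acc
#>   1   1   1   1
```

The printed numbers are what the code produces for seed 1: the per-class
count table shows the exact five-fold expansion and 8:2 split, and
`val_accuracy` is the best held-out accuracy over the 5 training epochs —
the synthetic task is designed to be fully learnable at this scale, and
seed 1 reaches a perfect held-out confusion matrix (other seeds land
between 0.93 and 1.00).

A thin command-line wrapper over the same functions is installed at
`inst/cli/pcsanet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pcsanet.R", package="pcsanet"))')" \
    synth --classes 3 --per-class 10 --side 32 --seed 7 --out data/
```

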