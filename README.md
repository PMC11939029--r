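# rhetclass

Sentence-level classification of medical abstracts into their four
rhetorical sections — **objective**, **methods**, **results**,
**conclusion** — aimed at the common situation in (especially Chinese)
medical text mining where no labeled sentence corpus exists: models must be
developed against synthetic, pseudolabeled corpora and evaluated by their
ability to recover rhetorical structure.

The package implements two routes over fixed sentence embeddings
$V \in \mathbb{R}^d$:

**Unsupervised (SBERT-DocSCAN style).** Mine each sentence's $k$ nearest
cosine neighbours $N_x$, then train a softmax cluster head $f(\cdot)$ by the
SCAN loss

```math
L \;=\; -\frac{1}{|D|} \sum_{x \in D} \sum_{k \in N_x}
\log\big(f(x)\cdot f(k)\big) \;+\; \lambda \sum_{i\in C} p_i \log p_i ,
```

where $p$ is the mean cluster-assignment probability: neighbours should
share a cluster, and the entropy term ($\lambda = 2$) prevents the collapse
of all sentences into one cluster. Clusterings are scored against labels by
optimal (Hungarian) cluster-to-class matching. A seeded k-means baseline is
included, and a label-supervised linear adapter (`finetune_encoder()`)
provides the fine-tuning step that re-orients embeddings from literal
content toward rhetorical function.

**Supervised (SBERT-MEC style).** A multi-encoder cascade augments each
embedding through three parallel encoders — a constant shift $V + n$ with
$n \sim U(-0.01, 0.01)$, an autoencoder $AE(V)$ trained on duplicate pairs,
and a denoising autoencoder trained on $V_N = V + \epsilon$,
$\epsilon \sim N(0, \sigma^2 I)$ — cross-supervised through
dynamic-convolution layers (attention over K = 4 candidate kernel banks,
sizes 2/3/4, 256 filters); the three convolution outputs are concatenated
with $V$ and classified by a softmax layer.

Because the motivating corpora are unreleased, a first-class synthetic
module (`generate_abstract_corpus()`, `simulate_embeddings()`) generates
labeled Chinese or English template abstracts with class-typical discourse
cues, and unit-sphere embedding mixtures with a controllable class
separation, so the entire pipeline runs offline, seeded and byte-reproducibly.

## Worked example

```r
library(rhetclass)

## a 2,000-sentence synthetic Chinese corpus, balanced across sections
corp <- generate_abstract_corpus(c(500, 500, 500, 500),
                                 language = "zh", seed = 11)
E <- encode(corp, encoder_config(dim = 256, seed = 3))

## clustering on raw embeddings vs after label-supervised fine-tuning
evaluate_clustering(corp$label,
                    kmeans_baseline(E, 4, seed = 1))$report$accuracy
#> [1] 0.822
ad <- finetune_encoder(E, corp$label, epochs = 30, seed = 5)
ad
#> Encoder adapter: 256 x 256 linear map, 30 epochs (seed 5)
#>   probe cross-entropy 1.2341 -> 0.0011; probe accuracy 1.000
E2 <- apply_adapter(ad, E)
evaluate_clustering(corp$label,
                    kmeans_baseline(E2, 4, seed = 1))$report$accuracy
#> [1] 1
```

Raw character-n-gram embeddings cluster at 0.822 accuracy (clusters follow
lexical overlap); after the adapter re-orients the space toward rhetorical
function, k-means recovers the four sections exactly — the fine-tuning
effect the clustering route depends on.

The SCAN head on simulated embeddings:

```r
sim <- simulate_embeddings(c(500, 500, 500, 500), dim = 64,
                           within_class_spread = 0.05,
                           class_separation = 4, seed = 1)
nb <- mine_neighbors(sim$values, k = 5)
fit <- train_scan(sim$values, nb, seed = 1)
fit
#> SCAN cluster head: 64 -> 128 -> 4, lambda = 2, k = 5, 30 epochs
#>   loss -1.5332 -> -2.7280
evaluate_clustering(sim$labels, predict(fit, sim$values))$report$accuracy
#> [1] 1
```

The final loss approaches $-\lambda \ln 4 \approx -2.77$, i.e. perfect
neighbour consistency with uniform cluster usage; Hungarian-matched
accuracy is 1.0.

Metric formulas are validated against published confusion matrices shipped
with the package:

```r
metrics(reference_confusions()$pseudolabel, decimals = 4)$accuracy
#> [1] 0.8983
```

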