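# sentmatch

Species identification as document retrieval: given free-text **layperson
descriptions** of an image ("this bird has a blue wing and a red head") and
an **expert corpus** with exactly one article per species, `sentmatch`
ranks the articles by how well their sentences match the descriptions and
labels the image with the top article's class — **without any expert class
labels during training**.

## The method

The core is a fine-grained sentence matching (FGSM) comparator, a Siamese
model over a frozen sentence encoder `T`:

    f(c1, c2) = h([ phi1 ; phi2 ; |phi1 - phi2| ]),   phi_i = phi(T(c_i))

with `phi` a small tanh MLP and `h` a linear head. Training pairs are
synthesized automatically: two captions of the same image are a *positive*
pair, captions of different images a *negative* pair, and (stage 2) a
caption plus a sentence sharing no nouns with it a *neutral* pair. Stage 1
trains on balanced positives/negatives with cross entropy; stage 2
retrains from scratch with the neutral class and a batch-level
score-distribution regularizer

    R(B) = sum_x [ -<p(D|x), p(D|x)> + sum_{x' != x} <p(D|x), p(D|x')> ]

(weight `lambda = 10`) that pushes each image's document posterior towards
one-hot and different images' posteriors towards orthogonality. A document
score is the mean comparator score over all caption x sentence pairs,

    z_ij = mean over (c, s) in C_i x D_j of f(c, s),

posteriors are the row softmax of `z`, and the top-ranked document's class
labels the image. TF-IDF (word 2–3-grams, cosine), Okapi BM25 and mean
embedding-cosine ranking are included as drop-in baselines, and the
package ships a synthetic attribute-world generator (species = color
assignments to body parts; noisy captions; jargon- and filler-rich expert
documents with maskable species names) so the whole pipeline runs and is
tested fully offline. See the methods vignette
(`vignettes/fine-grained-matching.Rmd`) for the model, the design choices
and known limitations.

## A worked example

```r
library(sentmatch)

world <- generate_benchmark(synth_config(K = 10, seed = 1))
spec  <- encoder_spec(dim = 512)
cap_cache <- precompute_cache(world$caption_sets, spec)
doc_cache <- precompute_cache(world$corpus, spec)

pairs3 <- build_pair_dataset(world$caption_sets, world$corpus,
                             mode = "3-class", size_per_label = 400,
                             seed = 2, both_orders = TRUE)
model <- train_stage2(pairs3, world$caption_sets, world$corpus,
                      comparator_config(stage = 2, lr = 1e-3, epochs = 20),
                      cap_cache, doc_cache)

ranking <- rank_documents(score_corpus(world$caption_sets, world$corpus,
                                       model,
                                       cache = list(cap_cache, doc_cache)))
evaluate_ranking(ranking, world$truth)
#> <eval_report (fgsm, macro): top1 48.0%, top5 94.0% | MR 2.32 | 50 images, K=10>
```

The report reads: over 50 images of 10 species, the true species' article
was ranked first for 48% of images (random guessing: 10%), was in the top
five for 94%, and sat at mean rank 2.32 of 10. `ranking_table(ranking)`
exports the per-image ranked lists; `score_pair()` scores individual
sentence pairs; `tfidf_rank()`, `bm25_rank()` and
`cosine_embedding_rank()` produce comparable rankings from the baselines.

A thin command-line wrapper with `synth` / `pairs` / `train` / `rank` /
`evaluate` subcommands is installed at `inst/scripts/sentmatch`.

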