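# comention

Context-aware co-occurrence scoring of entity co-mentions mined from the
scientific literature.

Association networks (gene–disease, gene–tissue, protein–protein) are
commonly extracted from text by counting sentence-level co-mentions of
entity pairs. Counting is robust but context-blind: a sentence denying an
association counts the same as one asserting it. `comention` combines
counting with a distantly supervised sentence classifier — no manually
annotated sentences required — and is aimed at anyone building scored
association networks from a co-mention corpus (or studying
distant-supervision behaviour on synthetic benchmarks).

## Method

1. **Distant supervision.** Each sentence co-mentioning an entity pair is
   weakly labeled against a gold standard of known pairs: *positive* if
   the pair is in the gold standard, *negative* if both entities are known
   but the pair is not, excluded if the pair is grey-listed or an entity
   is unknown. Gold standards can be enlarged by ontology propagation
   (descendant terms inherit their ancestors' associations). Entity names
   are blanked with class placeholders (`GENE_`, `DISEASE_`, ...) so the
   model is entity-agnostic.
2. **Sentence scoring.** A logistic classifier over averaged unigram and
   hashed-bigram word embeddings (trainable from scratch or warm-started
   from skipgram-pretrained vectors) maps each blanked sentence to the
   probability that it states an association.
3. **Aggregation.** Per document the maximal sentence score of a pair is
   taken; maxima are summed into a soft count *C(i,j)*; the final score is

   *S(i,j) = C(i,j)^α · ( C(i,j)·C(·,·) / (C(i,·)·C(·,j)) )^(1−α)*,

   weighing the count against its observed-over-expected enrichment
   (α = 0.65 by default; a constant-score baseline with α = 0.55
   reproduces classical counting approaches).
4. **Evaluation.** Pair-level 80/20 train/test splitting, per-pair
   training caps, cross-validation over α, class-prior-adjusted
   precision–recall analysis and bootstrap model comparison.

A synthetic corpus generator with a planted, tunable context signal
(trigger tokens appearing preferentially in sentences about truly
associated pairs) makes the whole pipeline testable end to end without
external data. See the methods vignette
(`vignettes/context-aware-cooccurrence.Rmd`) for the full model
description and design rationale.

## Worked example

```r
library(comention)

cfg    <- generator_config(n_documents = 2000, seed = 42)  # synthetic benchmark
world  <- generate_world(cfg)
corpus <- generate_corpus(world)

hp  <- hyperparams(dim = 50, epochs = 20, learning_rate = 0.1,
                   n_buckets = 10000, seed = 42)
run <- run_pipeline(corpus, world$gold, hp = hp, seed = 42)
run
#> comention_run
#>   test pairs evaluated: 120 (65 positive)
#>   context model  (alpha = 0.65): adjusted AUPRC 0.7633, AUROC 0.9597
#>   baseline model (alpha = 0.55): adjusted AUPRC 0.3292, AUROC 0.8284

head(run$context_scores$pairs, 3)
#>       ns1   id1  ns2   id2     count    score
#> 1 disease D0004 gene G0016  8.827683 16.54598
#> 2 disease D0011 gene G0005 13.568594 11.89978
#> 3 disease D0003 gene G0010  9.879247 11.56257

predict(run$classifier,
        c("DISEASE_ w0007 causes w0013 GENE_",   # trigger word present
          "DISEASE_ w0007 w0020 w0013 GENE_"))   # background only
#> [1] 0.996 0.172
```

The run labels the corpus (2671 positive / 1134 negative / 54 grey
co-mentions here), holds out 20% of pairs, trains the sentence classifier
on the rest, and evaluates both models on the held-out pairs: the
context-aware model clearly outranks the count-only baseline because the
generator planted trigger words in associated pairs' sentences, and the
classifier's two predictions above show it keying on exactly that signal.
A bootstrap comparison on the same run gives a mean adjusted-AUPRC
difference of 0.396 (p ≈ 0 by paired t-test over 1000 replicates):

```r
keep <- run$test_pair_scores$label %in% c("positive", "negative")
bootstrap_compare(run$test_pair_scores$context_score[keep],
                  run$test_pair_scores$baseline_score[keep],
                  run$test_pair_scores$label[keep] == "positive",
                  n_boot = 1000, seed = 45)
```

A command-line interface wrapping the same functions (subcommands
`simulate`, `label`, `train`, `score`, `evaluate`, `run`) is installed at
`system.file("cli", "comention", package = "comention")`.

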