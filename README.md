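# regiprobe

Does one speech register support the learning of semantic roles better
than another? Child-directed speech (CDS) differs from adult-directed
speech (ADS) in word-order variability, in how often the same words recur
in the same roles, and — in richly inflected languages — in the diversity
of case marking. `regiprobe` implements a complete probing methodology for
asking whether those statistical differences make the agent/patient
distinction easier to learn from one register than from the other, for
researchers in language acquisition and computational psycholinguistics.

## The method

The unit of analysis is an **argument instance**: a span of tokens filling
the most agent-like (A) or most patient-like (P) role of a bivalent verb,
in the sense of proto-role theory. The pipeline asks how accurately A can
be told from P using only information a statistical learner can extract
from raw utterances, and whether that accuracy differs by register:

1. **Register corpora.** Either user-supplied role-annotated corpora
   (JSONL, or CoNLL-U plus a verb case-frame table) or corpora produced by
   the built-in generator, whose registers are described by a word-order
   distribution over {A, P, V} strings, role-conditional lexical
   concentration (calibrated in bits of Shannon entropy), a case paradigm
   with declension-class syncretism, argument omission, number marking and
   pronoun rates. Corpora are size-matched by token budget and filtered
   (verbs with < 10 utterances removed, clauses with both arguments
   omitted excluded).
2. **Four argument representations.** Contextualised embeddings from a
   small masked-language-model transformer encoder trained per register
   (subword BPE tokenizer fit on the training register; span embeddings
   average the final-layer subword vectors); context-independent static
   embeddings composed from character n-grams (PPMI-weighted co-occurrence
   counts reduced by SVD); a three-feature argument-position vector
   (utterance-initial? preverbal? other argument present?); and a
   multi-hot possible-case vector over the paradigm's (case, number)
   cells, where more than one set bit marks a syncretic form.
3. **Verb-disjoint probing.** Ten train/validation/test splits with
   exactly 100 balanced training instances (50 A, 50 P) and no verb shared
   between the training and evaluation sides, so probes cannot rely on
   verb-specific shortcuts. Embedding representations are probed with a
   perceptron (hidden width 100, at most 20 epochs, lowest-validation-loss
   state kept); feature representations with an RBF-kernel SVM.
4. **Hierarchical Bayesian analysis.** Per-argument correctness is
   modelled as Bernoulli with logit link: register, role and their
   interaction as fixed effects (Normal(0, 1) or Normal(0, 2) priors),
   random intercepts for split and sentence id with random role slopes
   (Exponential(1) priors on the scales), sampled with JAGS and checked
   with split-Rhat, effective sample size and posterior predictive checks.
   The headline quantity is the counterfactual register contrast

   &Delta;P = P(correct | CDS) &minus; P(correct | ADS),

   computed per sentence id under both register levels and averaged, with
   a 95% credible interval. &Delta;P &gt; 0 means roles are easier to
   classify from CDS.
5. **Controlled generalisation (Study 2 style).** A template-generated
   minimal-pair test set (animacy flips, fronting, relative clauses,
   passives in the English-like mode; case-syncretism conditions crossed
   with all six word orders in the Russian-like mode) with a fixed test
   composition, scored under the encoders of both registers to ask which
   register supports generalisation to rare structures.

## Worked example

Build a register pair that differs only in role-conditional lexical
entropy (the CDS-like member 0.79 bits lower for A, 0.55 for P), generate
corpora, and inspect the descriptives:

```r
library(regiprobe)
pair <- make_register_pair(
  default_register_spec("russian_like", label = "ADS"),
  deltas = list(entropy = c(A = -0.79, P = -0.55)))
cds <- generate_corpus(pair$cds, 2000, seed = 1)
ads <- generate_corpus(pair$ads, 2000, seed = 2)
cds
#> <rp_role_dataset> 2000 utterances, 3097 argument instances, 12 verbs
#>   roles: A=1677, P=1420
#>   registers: CDS=2000
describe_dataset(cds)$entropy
#>         type    role      bits
#> 1   argument       A 4.4556561
#> 2   argument       P 5.7329884
#> 3 word order A and P 2.8368088
#> 4       case       A 0.0000000
#> 5       case       P 0.8762303
describe_dataset(ads)$entropy
#>         type    role     bits
#> 1   argument       A 4.926092
#> 2   argument       P 6.115754
#> 3 word order A and P 2.852265
#> 4       case       A 0.000000
#> 5       case       P 0.770480
```

The argument-form entropy is lower in the CDS-like register for both
roles (4.46 vs 4.93 bits for A), while word-order variability is shared —
exactly the designed contrast. A probing run on a register whose word
order is degenerately AVP shows the position features solving the task on
held-out verbs:

```r
sp <- register_spec(default_lexicon("russian_like"), default_paradigm("russian_like"),
                    c(AVP = 1.0), omission_prob = c(A = 0, P = 0), label = "demo")
d  <- generate_corpus(sp, 1200, seed = 7)
s  <- make_verb_disjoint_splits(d, n_versions = 1, train_size = 100, seed = 1)[[1]]
X  <- encode_positions(d)
meta <- d$instances; meta$register <- "demo"
probe <- train_probe(X[s$train, ], meta$role[s$train], config = probe_config("svm"))
accuracy_table(evaluate_probe(probe, X[s$test, ], meta[s$test, ], "position", 1))
#>   register representation role   n accuracy
#> 1     demo       position    A 950        1
#> 2     demo       position    P 976        1
```

The full experiment — encoder training, all representations, ten splits,
hierarchical fits and &Delta;P — is one call per study:

```r
cfg    <- run_config(seed = 101, mode = "russian_like")
study1 <- run_study1(cfg)                       # register contrast
study2 <- run_study2(cfg, study1$encoders)      # controlled generalisation
```

On the default synthetic conditions (two ~50K-token registers separated
by the entropy deltas above), `run_study1` yields a positive register
contrast for the contextualised representation: &Delta;P = 0.070 with
95% CI [0.047, 0.091] at one seed, and comparable positive intervals
(0.057 [0.031, 0.084]; 0.047 [0.024, 0.069]) at others — a directional
analogue of the published register effect.

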