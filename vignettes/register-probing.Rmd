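---
title: "Probing semantic-role learnability across speech registers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing semantic-role learnability across speech registers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and procedures:
what is being estimated, under which assumptions, which knobs matter, and
what the synthetic experiments can and cannot show about real speech.

## The scientific question and its formalisation

Children must learn how their language maps the proto-agent (A) and
proto-patient (P) of a bivalent verb onto word order, case and agreement.
The package operationalises "how learnable are the roles from register X"
as the accuracy of a small classifier (*probe*) that sees only a
representation of the argument derivable from raw text, trained and
evaluated under a verb-disjoint protocol so that verb identity cannot
serve as a shortcut. Register comparisons are then statements about
probe accuracy differences, estimated with a hierarchical Bayesian model
rather than raw means so that sentence- and split-level idiosyncrasies
are controlled.

Two stances are deliberate here. First, each argument is classified
independently; nothing forces the two arguments of a clause to receive
different predicted roles, so the probe's errors can be asymmetric in
exactly the way comprehension errors are (e.g. P misread as A in
passives). Second, contextual embeddings are the representation of
primary interest — they are what a statistical learner could actually
extract — while position, case and static-embedding probes serve as
interpretable controls that isolate single cue families.

## The synthetic register generator

Real child-directed corpora are licensed resources; the package instead
generates register pairs whose *measurable statistics* emulate the
contrasts reported for natural registers. A register specification fixes:

* **Word-order distribution** over overt-order strings (`AVP`, `APV`,
  `AV`, `VP`, ...). Strings missing an argument encode omission. The
  russian-like default is flexible and omission-rich (A-initial orders
  dominant, all six two-argument orders attested); the english-like
  default is near-degenerate on `AVP`. The generator's empirical order
  frequencies converge on the specification (checked by chi-square
  goodness of fit in the test suite).
* **Role-conditional lexical concentration.** Noun lemmas carry base
  weights and per-role biases; sampling weights are
  `(base x bias_role)^gamma`. The exponent `gamma` sweeps the Shannon
  entropy of the role-conditional lemma distribution continuously and
  monotonically, so a register pair can be calibrated to a stated entropy
  *gap* in bits (`calibrate_role_entropy()` bisects on `gamma`; 60
  bisection steps, i.e. to numerical precision). The default pipeline gap
  — CDS 0.79 bits lower for A and 0.55 for P — mirrors the direction and
  magnitude of the argument-variability differences reported for Russian
  registers. Calibration targets the *lemma* distribution; measured
  surface-form entropy also reflects inflection and pronouns and is
  therefore somewhat higher, with the gap compressed but preserved.
  One subtlety matters for the validity of the manipulation: if role
  biases were correlated with declension class (all patient-leaning nouns
  syncretic, say), concentrating the lemma distribution would also shift
  the case-form distribution, confounding "lower lexical entropy" with
  "different case marking". The built-in lexicon therefore places
  A-biased, neutral and P-biased members *within every declension class*
  and balances the top role-biased nouns across classes, so the entropy
  knob moves lexical variability alone.
* **Case paradigm.** Six cases by two numbers over three declension
  classes: `animate` (distinct NOM/ACC everywhere), `inanimate`
  (NOM = ACC in both numbers) and `feminine` (distinct in the singular,
  syncretic in the plural) — reproducing the contrast between forms that
  are unambiguous and forms that are case-syncretic. `possible_cases()`
  is defined as the exact preimage of the realisation table over the
  bound lexicon, so "syncretic" is a derived property, never an
  annotation that could drift out of sync.
* **Omission, number, pronouns, fillers.** Free parameters with
  documented defaults (e.g. 75/25 SG/PL, pronoun rate 0.35, filler rate
  0.2); no quantitative claims about natural corpora are attached to
  them. Verb agreement follows the underlying A number even when A is
  omitted.

What the generator does **not** emulate: discourse coherence, repetition
structure across utterances (variation sets), morphophonology, age
conditioning, or plausibility. A passing end-to-end test therefore shows
that the pipeline detects a register contrast *when the designed lexical
statistics differ*; it does not show that natural CDS differs from ADS —
that question needs real corpora fed through the same interfaces.

## Representations

**Contextual encoder.** A pre-norm transformer with tied input/output
embeddings, trained with the masked-token objective (15% of subwords
replaced by `<mask>`; at least one per sequence). The default desk-scale
profile is width 32, 2 layers, 2 heads, feed-forward multiplier 4, BPE
vocabulary of 128, Adam at 2e-3, 16 epochs — sized so that training a
register encoder on a ~50K-token corpus takes two to three minutes on
one CPU. The vocabulary budget deserves a note: a synthetic language has
only a few hundred word forms, and a generous budget would make BPE
memorise forms whole, hiding the case suffixes from the encoder
entirely. At 128 the segmentation is morphological (drug|a, mam|u,
sok|om), which both matches how subword models behave on natural
morphology-rich text and makes probe behaviour far less sensitive to the
training run. The epoch count is likewise chosen so the masked loss has
substantially flattened; probing a mid-training encoder yields unstable
embedding geometry.
All gradients are hand-derived and verified against finite differences in
the test suite; there is no dropout, so a frozen encoder is exactly
deterministic. Three choices were genuinely open and are fixed as
follows: probes read the **final layer**; span embeddings use
**single-level averaging** over all subwords in the span (a two-level
per-word-first variant sits behind `two_level = TRUE`); and the BPE
tokenizer is fit on the training register only, with character fallback
for unseen material.

**Static embeddings.** A deliberate design decision: rather than a
stochastic skip-gram trainer, the package uses a deterministic, closed-form
construction — character n-grams (3–5, boundary-marked, plus the whole
word) inherit the windowed co-occurrence counts of the words containing
them; the n-gram-by-context matrix is PPMI-weighted and reduced by
truncated SVD; a word vector is the mean of its n-gram vectors. This
keeps the defining properties that matter for the probing contrast —
context invariance, subword compositionality, out-of-vocabulary coverage
— while being exactly reproducible (SVD sign indeterminacy is fixed by
forcing the largest-magnitude loading positive).

**Position and case vectors.** Three binary features (utterance-initial,
preverbal, co-argument present) and the multi-hot (case, number) vector.
"First position" counts every token, including interjections — so in
*why did he bite the horse*, *he* is non-initial. Note that the
combinations (initial, not-preverbal, \*) are logically unattainable: an
utterance-initial argument is necessarily preverbal. Adpositions heading
oblique arguments are inside the argument span by default.

## Probing protocol

Splits are drawn by shuffling verbs and greedily assigning them to the
training side until 50 A and 50 P instances are reachable, sampling the
balanced training set from that side, and giving all other verbs'
instances to validation (capped at 300, at least 100) and test. When the
two registers share a verb inventory — always true for generated pairs —
the same shuffled verb ordering drives each split version in both
registers, so version *k* trains on (nearly) the same verbs in CDS and
ADS. This pairs the register comparison: which verbs land in training is
a large source of variance, and matching partitions removes it from the
register contrast instead of leaving it to the split random effects
alone.
Train-side instances beyond the quota are *dropped*: with exact training
sizes and verb disjointness they can belong to no set. Ten split versions
with different verb partitions are the default, matching the protocol's
sensitivity to which verbs land in training.

The perceptron probe (one hidden layer of width 100, ReLU, full-batch
Adam, at most 20 epochs) keeps the parameter state with the lowest
**validation** loss — the validation set otherwise plays no role, which
is why validation loss rather than training loss is the default selector
(a `best_on = "train"` switch exists). The SVM probe is used for the
feature-based representations, where it performs equivalently at lower
cost. Unstated perceptron details (activation, optimiser, batch policy)
are package defaults recorded in `probe_config()`, not claims about any
external reference.

## The hierarchical model and the register contrast

Correctness is Bernoulli with logit link. Study-1 structure: fixed
effects register, role, register x role; random intercepts for split and
sentence id, each with a random role slope. Study-2 structure: the fixed
part gains condition (english mode) or syncretism and word order
(russian mode), and the sentence intercept varies by register. Priors:
Normal(0, 1) on fixed effects — automatically retried at Normal(0, 2) if
any split-Rhat exceeds 1.01 — and Exponential(1) on random-effect scales.

Sampling uses JAGS with the `glm` module and a non-centered
parameterisation of the random effects (scales multiply standard-normal
deviates); both choices are purely computational and leave the model's
substance unchanged, but they are what makes split-Rhat of at most 1.01
reachable with 2 chains of 1000 retained draws on ~4000 records. Every
reported parameter carries split-Rhat and effective sample size, and each
fit stores a posterior predictive check comparing observed against
replicated accuracy per register-by-role cell.

The headline estimand is the counterfactual contrast
Delta-P = P(correct | CDS) - P(correct | ADS): for every sentence id, its
linear predictor is evaluated under both register levels while *keeping
the sentence's own random effects*, differences are taken per draw,
averaged within sentence id and then across sentences. Sentences observed
in only one register still receive predictions for both levels — their
random intercept is simply held fixed; a fully marginalised variant was
considered and rejected because per-sentence prediction is the quantity
of interest. Delta-P is antisymmetric under register relabelling by
construction (verified exactly in the tests). When the statistical stage
receives more records than `stat_max_records` (default 4000), records are
thinned in two steps that maximise information per record: an argument's
records across split versions are highly correlated (the same span scored
by slightly different probes), so at most two per argument are kept, and
any remaining excess is removed by subsampling whole sentences stratified
by register, so both registers keep equal sentence counts and the
random-effect structure stays intact.

## Controlled generalisation sets

English-mode templates realise five conditions — basic and
animacy-flipped `AVP`, fronted and relativised `PAV` (the relative clause
is introduced by an overt complementizer and followed by a two-word
matrix continuation), and passive `PVA` with the agent in a *by*-phrase —
crossed with number (so subject-verb agreement is a cue in exactly the
number-mismatched half) and pronoun variants including the role-ambiguous
*you*. Russian-mode templates cross the four syncretism conditions with
all six word orders; the doubly syncretic condition keeps only
agreement-cued variants because it would otherwise be globally ambiguous.
Syncretism labels are computed from the paradigm, not asserted.
Implausible or metaphorical pairings are admitted by design: the sets
probe grammatical knowledge, not plausibility. The fixed test
composition — each English special condition exactly four arguments (two
per role), Russian word orders at 52/24/18/2/2/2 sentences — is exact for
every seed, and the training split contains every condition at least
once. The generator reproduces this combinatorial scheme, not any
particular published inventory size, since those depend on unpublished
lexica.

## Numerical choices, sizes and limitations

* Entropy is always plug-in (maximum likelihood) and always in **bits**;
  plug-in estimates are biased downward at small samples, which is why
  calibration checks use closed-form spec entropies plus large probe
  corpora.
* Default problem sizes — 13K utterances (~50K tokens) per register, the
  2-layer width-32 encoder, ten splits, fits on at most 3000–4000 records
  with 2 x 1000 draws — were chosen as the smallest configuration at
  which the designed register contrast is reliably resolved; they are the
  package's reference conditions, stated here so results are read at the
  right scale.
* The register contrast detected end-to-end (Delta-P around +0.05 to
  +0.07 with a CI excluding zero at the reference conditions) is a
  *directional* result on synthetic data. Its value depends on the
  lexicon size and the chosen gap, and at some corpus realisations the
  overall interval can touch zero even when per-role contrasts are
  clearly positive — encoder training runs and 100-item probes are noisy
  instruments, which is exactly why the protocol averages ten splits and
  models split and sentence variation explicitly. It is not an estimate
  of any natural-language quantity.
* Known limitations: the CoNLL-U reader is minimal (no multiword-token
  expansion beyond skipping, first frame verb per sentence); the
  perceptron has no mini-batching (training sets are 100 rows); JAGS
  random-effect vectors are monitored in full, which is memory-heavy for
  corpora far larger than the defaults; and pretrained web-scale static
  embeddings are out of scope — `embed_arguments_static()` accepts any
  table with the same interface if one is built externally.
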