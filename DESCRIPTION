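Package: regiprobe
Title: Probing Semantic-Role Learnability Across Speech Registers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether one speech register (for example
    child-directed versus adult-directed speech) supports the learning of
    semantic proto-roles (agent versus patient) better than another.
    Provides a generator for synthetic register corpora with controllable
    word-order distributions, role-conditional lexical entropy, case
    syncretism and argument omission; four argument representations
    (contextualised embeddings from a small trainable masked-language-model
    encoder, subword character n-gram static embeddings, a three-feature
    argument-position vector and a multi-hot possible-case vector);
    verb-disjoint balanced probing splits with perceptron and RBF-SVM
    probes; controlled minimal-pair generalisation test sets; maximum
    likelihood entropy descriptives; and a Bayesian hierarchical Bernoulli
    model of classification outcomes with a counterfactual register
    contrast (delta-P) computed from posterior predictions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    rjags,
    coda
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
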