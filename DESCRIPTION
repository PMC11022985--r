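Package: soluq
Title: Aqueous Solubility Prediction with Deep-Ensemble Uncertainty from Molecular Strings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts aqueous solubility (log10 molar, log S) directly from SMILES or
    SELFIES molecular strings using a deep ensemble of small recurrent neural networks,
    each emitting a heteroscedastic Gaussian (mean and variance) so that predictions
    carry both aleatoric and epistemic uncertainty. Provides SMILES canonicalization and
    randomized-SMILES data augmentation, a SELFIES tokenizer and vocabulary tools,
    Gaussian negative log-likelihood training with optional adversarial perturbation of
    the embedded input, evaluation metrics (RMSE, MAE, Pearson r, percentage within
    0.5 log S), an ablation-grid runner, a synthetic heteroscedastic benchmark
    generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    optparse,
    ChemmineR,
    ChemmineOB
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
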