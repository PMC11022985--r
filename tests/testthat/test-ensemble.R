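# Fitting interface, prediction paths and the model bundle.

small_fit <- function() memo("small_fit", function() {
  rec <- fx_synth200()$records
  do.call(soluq, c(list(formula = log_s ~ smiles, data = rec,
                        ensemble_size = 2L, member_seeds = c(301L, 402L),
                        seed = 8, verbose = FALSE),
                   modifyList(fx_model_args(), list(epochs = 6L))))
})

test_that("the fitted object carries the standard modelling surface", {
  fit <- small_fit()
  expect_s3_class(fit, "soluq")
  expect_output(print(fit), "Deep-ensemble")
  expect_length(fitted(fit), length(fit$y))
  expect_equal(residuals(fit), fit$y - fitted(fit))
  s <- summary(fit)
  expect_s3_class(s, "summary.soluq")
  expect_output(print(s), "RMSE")
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(dim(sims), c(length(fit$y), 2L))
  expect_identical(sims, simulate(fit, nsim = 2, seed = 5))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path); plot(fit); grDevices::dev.off()
  expect_true(file.exists(path))
})

test_that("prediction with one member equals the raw member forward pass", {
  rec <- fx_synth200()$records
  fit1 <- do.call(soluq, c(list(formula = log_s ~ smiles, data = rec,
                                ensemble_size = 1L, member_seeds = 77L,
                                seed = 8, verbose = FALSE),
                           modifyList(fx_model_args(), list(epochs = 2L))))
  smiles <- rec$smiles[5]
  pred <- predict(fit1, smiles)
  enc <- encode_selfies_ids(to_selfies(smiles), fit1$vocab,
                            max_len = fit1$mconf$max_len)
  fwd <- soluq:::nn_forward(fit1$members[[1]]$params, fit1$mconf,
                            matrix(enc$ids[seq_len(enc$length)], 1),
                            enc$length, training = FALSE)
  expect_equal(pred$mu, fwd$mu, tolerance = 1e-12)
  expect_equal(pred$sigma2_ale, fwd$sigma2, tolerance = 1e-12)
  expect_equal(pred$sigma2_epi, 0)
})

test_that("batch prediction equals per-molecule prediction", {
  fit <- small_fit()
  smiles <- fx_synth200()$records$smiles[21:25]
  batch <- predict(fit, smiles)
  singles <- do.call(rbind, lapply(smiles, function(s) predict(fit, s)))
  expect_equal(batch$mu, singles$mu, tolerance = 1e-12)
  expect_equal(batch$sigma2_ale, singles$sigma2_ale, tolerance = 1e-12)
  expect_equal(batch$sigma2_epi, singles$sigma2_epi, tolerance = 1e-12)
})

test_that("prediction is not invariant to the input representation", {
  fit <- small_fit()
  s <- fx_synth200()$records$smiles[3]
  alt <- randomize_smiles(s, max_new = 1, seed = 2)
  p1 <- predict(fit, s)
  p2 <- predict(fit, alt)
  expect_false(isTRUE(all.equal(p1$mu, p2$mu)))  # same molecule, new string
})

test_that("out-of-vocabulary tokens are counted and warned about", {
  fit <- small_fit()
  # nitrogen never occurs in the carbon/oxygen training corpus
  expect_warning(p <- predict(fit, "CNC"), "out-of-vocabulary")
  expect_gt(p$n_unknown_tokens, 0)
  expect_true(is.finite(p$mu))
})

test_that("a saved bundle reloads to identical predictions", {
  fit <- small_fit()
  dir <- withr::local_tempdir()
  save_soluq(fit, dir)
  expect_true(file.exists(file.path(dir, "vocab.tsv")))
  expect_true(file.exists(file.path(dir, "config.json")))
  expect_true(file.exists(file.path(dir, "member_001.txt")))
  back <- load_soluq(dir)
  smiles <- fx_synth200()$records$smiles[1:10]
  expect_equal(predict(back, smiles)$mu, predict(fit, smiles)$mu,
               tolerance = 1e-14)
  # tampering with the vocabulary manifest is caught
  vpath <- file.path(dir, "vocab.tsv")
  writeLines(readLines(vpath)[1:3], vpath)
  expect_error(load_soluq(dir), "mismatch")
})

test_that("ensembles disagree on held-out inputs (positive epistemic)", {
  fit <- small_fit()
  held <- synth_corpus(synth_spec(n_molecules = 30, seed = 555))
  pred <- predict(fit, held$records$smiles)
  expect_gt(mean(pred$sigma2_epi), 0)
  expect_true(all(pred$sigma2_ale > 0))
})
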