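test_that("mse_loss computes the mean squared error", {
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse_loss(c(0, 0), c(1, 1)), 1)
  expect_equal(mse_loss(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  expect_error(mse_loss(1:3, 1:2), class = "motifconv_dim_error")
  expect_error(mse_loss(numeric(0), numeric(0)), class = "motifconv_dim_error")
})

test_that("pooled feature is the max over 2(N-L+1) activated LLR values", {
  cfg <- model_config(n_filters = 1L, filter_length = 4L, alpha = 1,
                      dropout_rate = 0, seed = 3)
  m <- build_multinom_cnn(cfg)
  s <- random_dna(1, 15)
  # reference: scan both strands with the model's kernel, relu, take the max
  k <- multinomial_transform(raw_convolution(m$params$X[, , 1]), m$params$alpha)
  enc <- one_hot_encode(s)
  vals <- c(scan_llr(k, enc), scan_llr(k, reverse_complement(enc)))
  expect_length(vals, 2 * (15 - 4 + 1))
  expect_equal(pooled_features(m, s)[1, 1], max(pmax(vals, 0)), tolerance = 1e-9)
})

test_that("sum and average pooling agree with direct summation", {
  for (pool in c("sum", "average")) {
    cfg <- model_config(n_filters = 1L, filter_length = 3L, alpha = 1,
                        pooling = pool, dropout_rate = 0, seed = 6)
    m <- build_multinom_cnn(cfg)
    s <- random_dna(1, 12)
    k <- multinomial_transform(raw_convolution(m$params$X[, , 1]), m$params$alpha)
    enc <- one_hot_encode(s)
    vals <- pmax(c(scan_llr(k, enc), scan_llr(k, reverse_complement(enc))), 0)
    ref <- if (pool == "sum") sum(vals) else mean(vals)
    expect_equal(pooled_features(m, s)[1, 1], ref, tolerance = 1e-9)
  }
})

test_that("background-equal kernels give pooled feature 0 and intercept prediction", {
  cfg <- model_config(n_filters = 3L, filter_length = 5L, alpha = 2,
                      dropout_rate = 0, seed = 1)
  m <- build_multinom_cnn(cfg)
  bg_w <- matrix(rep(log(background_distribution()$probs) / cfg$alpha, each = 5L), 5L, 4L)
  for (f in 1:3) m$params$X[, , f] <- bg_w
  m$params$b <- 1.25
  seqs <- random_dna(4, 20)
  expect_equal(pooled_features(m, seqs), matrix(0, 4, 3), tolerance = 1e-9)
  expect_equal(predict(m, seqs), rep(1.25, 4), tolerance = 1e-9)
})

test_that("untrained forward passes are finite (both architectures, both heads)", {
  set.seed(8)
  seqs <- random_dna(6, 30)
  for (ndense in c(1L, 2L)) {
    m <- build_multinom_cnn(model_config(n_filters = 4L, filter_length = 6L,
                                         n_dense_layers = ndense, seed = 2))
    expect_true(all(is.finite(predict(m, seqs))))
  }
  cc <- build_conventional_cnn(conventional_cnn_config(
    conv_filters = c(8L, 4L), conv_lengths = 5L, seed = 2))
  expect_true(all(is.finite(predict(cc, seqs))))
})

test_that("conventional CNN default is a five-layer stack; one layer degenerates cleanly", {
  cfg <- conventional_cnn_config()
  expect_equal(cfg$conv_filters, c(512L, 256L, 64L, 64L, 64L))
  expect_equal(cfg$conv_lengths, rep(5L, 5))
  expect_equal(cfg$dropout_rate, 0.5)
  expect_equal(cfg$batch_size, 32L)
  m1 <- build_conventional_cnn(conventional_cnn_config(conv_filters = 3L,
                                                       conv_lengths = 4L, seed = 9))
  expect_named(m1$params, c("convW1", "convb1", "w", "b"))
  expect_true(all(is.finite(predict(m1, random_dna(3, 12)))))
})

test_that("configuration validation rejects invalid values", {
  expect_error(model_config(n_filters = 0), class = "motifconv_config_error")
  expect_error(model_config(dropout_rate = 1), class = "motifconv_config_error")
  expect_error(model_config(activation = "swish"))
  expect_error(model_config(n_dense_layers = 3), class = "motifconv_config_error")
  expect_error(build_multinom_cnn(conventional_cnn_config()),
               class = "motifconv_config_error")
  expect_error(build_conventional_cnn(model_config()),
               class = "motifconv_config_error")
})

test_that("predictions are deterministic, order-equivariant, and finite on all-N input", {
  m <- build_multinom_cnn(model_config(n_filters = 3L, filter_length = 4L,
                                       dropout_rate = 0.5, seed = 4))
  seqs <- random_dna(5, 16)
  p1 <- predict(m, seqs)
  p2 <- predict(m, seqs)
  expect_identical(p1, p2)           # dropout disabled at inference
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(predict(m, seqs[perm]), p1[perm])
  pn <- predict(m, strrep("N", 16))
  expect_true(is.finite(pn))
})

test_that("strand symmetry: a sequence and its reverse complement predict alike", {
  m <- build_multinom_cnn(model_config(n_filters = 5L, filter_length = 6L, seed = 10))
  seqs <- random_dna(10, 25)
  rc <- vapply(seqs, function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }, "")
  expect_equal(predict(m, unname(rc)), predict(m, seqs), tolerance = 1e-8)
})

test_that("zero-epoch training returns the initialization", {
  cfg <- tiny_config(max_epochs = 0L)
  m <- build_multinom_cnn(cfg)
  sim <- tiny_sim(n = 20)
  fit <- train_model(m, sim$data)
  expect_identical(fit$params, m$params)
  expect_true(fit$trained)
  expect_equal(nrow(fit$history), 0L)
})

test_that("training MSE decreases over the first epochs on noiseless linear data", {
  ok <- 0L
  for (s in 1:10) {
    sim <- simulate_mpra(simulation_spec(
      n_sequences = 60, seq_length = 30, noise_sd = 0, plant_probability = 0.7,
      planted_motifs = list(list(motif = consensus_motif("TGACTC"), weight = 1)),
      seed = 100 + s))
    cfg <- model_config(n_filters = 2L, filter_length = 6L, max_epochs = 5L,
                        dropout_rate = 0, batch_size = 16L,
                        early_stopping_patience = 0L, seed = 200 + s)
    fit <- train_model(build_multinom_cnn(cfg), sim$data)
    if (all(diff(fit$history$train_mse) < 0)) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("training on constant activities converges toward the constant", {
  seqs <- random_dna(40, 25)
  data <- mpra_dataset(seqs, rep(3, 40))
  cfg <- model_config(n_filters = 2L, filter_length = 5L, max_epochs = 40L,
                      dropout_rate = 0, batch_size = 20L,
                      early_stopping_patience = 0L, seed = 5)
  init <- build_multinom_cnn(cfg)
  mse_init <- mse_loss(rep(3, 40), predict(init, seqs))
  fit <- train_model(init, data)
  mse_fit <- mse_loss(rep(3, 40), predict(fit, seqs))
  expect_lt(mse_fit, mse_init)
  expect_lt(mse_fit, 0.5)
})

test_that("training errors are informative", {
  sim <- tiny_sim(n = 20)
  expect_error(train_model(build_multinom_cnn(tiny_config()), list()),
               class = "motifconv_data_error")
  # a non-finite parameter makes the loss NaN; the guard names the epoch
  m <- build_multinom_cnn(tiny_config())
  m$params$b <- NaN
  err <- expect_error(train_model(m, sim$data),
                      class = "motifconv_divergence_error")
  expect_match(conditionMessage(err), "epoch 1")
})

test_that("training with identical seed is reproducible", {
  sim <- tiny_sim(n = 30)
  cfg <- tiny_config(max_epochs = 3L, dropout_rate = 0.2)
  f1 <- train_model(build_multinom_cnn(cfg), sim$data)
  f2 <- train_model(build_multinom_cnn(cfg), sim$data)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("L2 penalty is exactly zero at l2_factor = 0", {
  m0 <- build_multinom_cnn(tiny_config(l2_factor = 0))
  expect_identical(motifconv:::l2_penalty(m0), 0)
  m1 <- build_multinom_cnn(tiny_config(l2_factor = 0.01))
  expect_gt(motifconv:::l2_penalty(m1), 0)
})

test_that("conventional CNN trains end to end on a small dataset", {
  sim <- tiny_sim(n = 40)
  cfg <- conventional_cnn_config(conv_filters = c(4L, 3L), conv_lengths = 4L,
                                 dropout_rate = 0, batch_size = 20L,
                                 max_epochs = 3L, seed = 3)
  fit <- train_model(build_conventional_cnn(cfg), sim$data)
  expect_equal(nrow(fit$history), 3L)
  expect_true(all(is.finite(fit$history$train_mse)))
  expect_true(all(is.finite(predict(fit, sim$data))))
})

test_that("two-dense-layer variant trains and keeps role extraction unassigned", {
  sim <- tiny_sim(n = 30)
  cfg <- tiny_config(n_dense_layers = 2L, max_epochs = 2L)
  fit <- train_model(build_multinom_cnn(cfg), sim$data)
  motifs <- extract_motifs(fit)
  expect_length(motifs, cfg$n_filters)
  expect_true(all(vapply(motifs, `[[`, "", "role") == "unassigned"))
})

test_that("trainable alpha moves alpha during optimization", {
  sim <- tiny_sim(n = 40)
  cfg <- tiny_config(alpha_trainable = TRUE, max_epochs = 5L)
  fit <- train_model(build_multinom_cnn(cfg), sim$data)
  expect_false(identical(fit$params$alpha, cfg$alpha))
  expect_gt(fit$params$alpha, 0)
})

test_that("validation monitoring restores the best weights", {
  sim <- tiny_sim(n = 60)
  ids <- sim$data$ids
  tr <- motifconv:::subset_dataset(sim$data, ids[1:45])
  va <- motifconv:::subset_dataset(sim$data, ids[46:60])
  cfg <- tiny_config(max_epochs = 12L, early_stopping_patience = 3L)
  fit <- train_model(build_multinom_cnn(cfg), tr, va)
  best <- min(fit$history$monitor_mse)
  expect_equal(mse_loss(va$activities, predict(fit, va)), best, tolerance = 1e-9)
})
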