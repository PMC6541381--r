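test_that("the activation maps zero to the positive class", {
  expect_identical(sign_fn(0), 1L)
  expect_identical(sign_fn(-1), -1L)
  expect_identical(sign_fn(1e8), 1L)
})

test_that("plaintext training reproduces the hand-traced mistake-driven rule", {
  # single sample x = (1, 1), O = +1, w0 = (-1, -1), eta = 1:
  # epoch 1 scores -2 -> update to (0, 0); epoch 2 scores 0 -> sign +1, done
  s <- clinical_samples(matrix(c(1, 1), 1), 1L)
  m <- train_plain(s, train_config(eta = 1), init_w = c(-1, -1))
  expect_identical(m$w, c(0, 0))
  expect_identical(m$updates, 1L)
  expect_true(m$converged)
  expect_identical(m$trained_epochs, 2L)
})

test_that("a separating initialization is a fixed point", {
  set.seed(81)
  ds <- generate_samples(synth_spec(n_samples = 40, d = 4, seed = 5))
  # the planted separator itself classifies everything correctly
  m <- train_plain(ds$train, train_config(), init_w = ds$planted_w)
  expect_identical(m$updates, 0L)
  expect_identical(m$w, as.numeric(ds$planted_w))
  expect_true(m$converged)
})

test_that("one encrypted update shifts each weight by eta * O * x exactly", {
  keys <- test_keys()
  cloud <- mpc_party("Cloud", pub = keys$pub, seed = 11)
  hosp <- mpc_party("Hospital", pub = keys$pub, priv = keys$priv, seed = 12)
  for (lab in c(1L, -1L)) {
    # initial weights force a mismatch on the single sample for this label
    w0 <- if (lab == 1L) c(-3, -4) else c(3, 4)
    x <- c(2, 5)
    eta <- 3L
    enc <- encrypt_samples(clinical_samples(matrix(x, 1), lab), keys$pub)
    fit <- train_encrypted(cloud, hosp, enc,
                           train_config(eta = eta, iteration_max = 1),
                           init_w = w0)
    w1 <- decrypt_model(fit$model, keys$priv, keys$pub)
    expect_identical(w1 - w0, eta * lab * x)
  }
})

test_that("encrypted training tracks the plaintext perceptron epoch by epoch", {
  keys <- test_keys()
  ds <- generate_samples(synth_spec(n_samples = 30, d = 4, seed = 9))
  enc <- encrypt_samples(ds$train, keys$pub)
  for (ord in c("sequential", "shuffle")) {
    cfg <- train_config(seed = 13, order = ord)
    cloud <- mpc_party("Cloud", pub = keys$pub, seed = 21)
    hosp <- mpc_party("Hospital", pub = keys$pub, priv = keys$priv, seed = 22)
    fit <- train_encrypted(cloud, hosp, enc, cfg, snapshot = TRUE)
    ref <- train_plain(ds$train, cfg, init_w = fit$init_w, record_epochs = TRUE)
    expect_identical(fit$model$trained_epochs, ref$trained_epochs)
    expect_identical(fit$model$converged, ref$converged)
    for (e in seq_len(ref$trained_epochs)) {
      w_ed <- vapply(fit$epoch_cw[[e]], function(ct)
        signed_value(paillier_decrypt(keys$priv, keys$pub, ct), keys$pub$n), 0)
      expect_identical(w_ed, ref$epoch_w[[e]])
    }
  }
})

test_that("the hospital only ever receives ciphertext payloads during training", {
  keys <- test_keys()
  ds <- generate_samples(synth_spec(n_samples = 12, d = 3, seed = 15))
  enc <- encrypt_samples(ds$train, keys$pub)
  cloud <- mpc_party("Cloud", pub = keys$pub, seed = 31)
  hosp <- mpc_party("Hospital", pub = keys$pub, priv = keys$priv, seed = 32)
  fit <- train_encrypted(cloud, hosp, enc, train_config(seed = 3))
  to_hospital <- Filter(function(m) m$receiver == "Hospital",
                        fit$transcript$messages)
  expect_gt(length(to_hospital), 0L)
  for (m in to_hospital)
    for (p in m$payload)
      expect_s3_class(p, "paillier_ciphertext")
})

test_that("per-disease training matches each disease's own plaintext oracle", {
  keys <- test_keys()
  d1 <- generate_samples(synth_spec(n_samples = 20, d = 3, seed = 17,
                                    balance = 0.5))
  d2 <- generate_samples(synth_spec(n_samples = 20, d = 3, seed = 18,
                                    balance = 0.5))
  x <- rbind(d1$train$x, d2$train$x)
  y <- c(d1$train$y, d2$train$y)
  idx <- rep(c(1L, 2L), c(length(d1$train$y), length(d2$train$y)))
  enc <- encrypt_samples(clinical_samples(x, y, idx), keys$pub)
  cloud <- mpc_party("Cloud", pub = keys$pub, seed = 41)
  hosp <- mpc_party("Hospital", pub = keys$pub, priv = keys$priv, seed = 42)
  cfg <- train_config(seed = 19)
  fits <- train_all_diseases(cloud, hosp, enc, cfg = cfg)
  expect_named(fits, c("1", "2"))
  for (k in 1:2) {
    sub <- clinical_samples(x[idx == k, ], y[idx == k], k)
    ref <- train_plain(sub, cfg, init_w = fits[[as.character(k)]]$init_w)
    expect_identical(decrypt_model(fits[[as.character(k)]]$model,
                                   keys$priv, keys$pub), ref$w)
  }
  # a disease's model is independent of the other disease's samples
  solo <- train_all_diseases(cloud, hosp, enc, disease_indices = 1L, cfg = cfg)
  expect_identical(decrypt_model(solo[["1"]]$model, keys$priv, keys$pub),
                   decrypt_model(fits[["1"]]$model, keys$priv, keys$pub))
  expect_warning(train_all_diseases(cloud, hosp, enc, disease_indices = 99L,
                                    cfg = cfg), "no samples")
})

test_that("the range guard refuses keys too small for the worst-case weights", {
  kp <- paillier_from_primes(13, 17)  # n = 221
  cloud <- mpc_party("Cloud", pub = kp$pub, seed = 1)
  hosp <- mpc_party("Hospital", pub = kp$pub, priv = kp$priv, seed = 2)
  enc <- encrypt_samples(clinical_samples(matrix(c(9, 9), 1), 1L), kp$pub)
  expect_error(train_encrypted(cloud, hosp, enc, train_config(), init_w = c(8, 8)),
               "range guard|larger key")
})

test_that("training converges on separable data across seeds", {
  for (s in 1:5) {
    ds <- generate_samples(synth_spec(n_samples = 60, d = 6, seed = s + 100))
    m <- train_plain(ds$train, train_config(seed = s))
    expect_true(m$converged)
    pred <- apply(ds$train$x, 1, function(x) sign_fn(sum(m$w * x)))
    expect_identical(mean(pred == ds$train$y), 1)  # 100% training accuracy
  }
})

test_that("models survive a JSON round trip in both plain and encrypted form", {
  keys <- test_keys()
  ds <- generate_samples(synth_spec(n_samples = 12, d = 3, seed = 23))
  pm <- train_plain(ds$train, train_config(seed = 2))
  f <- tempfile(fileext = ".json")
  write_model_json(pm, f)
  back <- read_model_json(f)
  expect_identical(back$w, pm$w)
  expect_identical(back$converged, pm$converged)
  enc <- encrypt_samples(ds$train, keys$pub)
  cloud <- mpc_party("Cloud", pub = keys$pub, seed = 1)
  hosp <- mpc_party("Hospital", pub = keys$pub, priv = keys$priv, seed = 2)
  fit <- train_encrypted(cloud, hosp, enc, train_config(seed = 2))
  write_model_json(fit$model, f)
  back2 <- read_model_json(f)
  expect_s3_class(back2, "encrypted_model")
  expect_identical(decrypt_model(back2, keys$priv, keys$pub),
                   decrypt_model(fit$model, keys$priv, keys$pub))
  unlink(f)
})
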