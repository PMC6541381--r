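test_that("generation is fully deterministic given the spec", {
  a <- generate_samples(synth_spec(n_samples = 40, d = 5, seed = 3))
  b <- generate_samples(synth_spec(n_samples = 40, d = 5, seed = 3))
  expect_identical(a, b)
  c2 <- generate_samples(synth_spec(n_samples = 40, d = 5, seed = 4))
  expect_false(identical(a$train$x, c2$train$x))
})

test_that("every noise-free sample respects the planted margin", {
  spec <- synth_spec(n_samples = 50, d = 6, margin = 5, seed = 7)
  ds <- generate_samples(spec)
  for (part in list(ds$train, ds$test)) {
    score <- drop(part$x %*% ds$planted_w) - ds$threshold
    expect_true(all(part$y * score >= spec$margin |
                      (score == 0 & part$y == 1)))
    expect_true(all(abs(score) >= spec$margin))
    expect_true(all(part$x >= 1 & part$x <= 10))
  }
  expect_identical(sort(unique(c(ds$train$y, ds$test$y))), c(-1L, 1L))
})

test_that("the split honors the 7:3 ratio after shuffling", {
  ds <- generate_samples(synth_spec(n_samples = 100, seed = 11))
  expect_identical(length(ds$train$y), 70L)
  expect_identical(length(ds$test$y), 30L)
  ds2 <- generate_samples(synth_spec(n_samples = 40, split_ratio = c(1, 1), seed = 11))
  expect_identical(length(ds2$train$y), 20L)
})

test_that("requested class balance is realized within binomial tolerance", {
  n <- 200
  ds <- generate_samples(synth_spec(n_samples = n, balance = 0.5, seed = 13))
  pos <- sum(c(ds$train$y, ds$test$y) == 1)
  expect_lte(abs(pos - n / 2), 1)  # quota sampling is near-exact
  ds2 <- generate_samples(synth_spec(n_samples = n, balance = 0.25, seed = 13))
  expect_lte(abs(sum(c(ds2$train$y, ds2$test$y) == 1) - n / 4), 1)
})

test_that("degenerate specs error out", {
  expect_error(synth_spec(n_samples = 0), "n_samples")
  expect_error(synth_spec(n_samples = 10, d = 0), "d >= 1")
  # an unachievable margin exhausts the rejection budget
  expect_error(generate_samples(synth_spec(n_samples = 10, d = 2,
                                           margin = 10^6, seed = 1),
                                max_tries = 50L),
               "budget")
})

test_that("CSV files round-trip losslessly and validate labels", {
  ds <- generate_samples(synth_spec(n_samples = 20, d = 3, seed = 17))
  f <- tempfile(fileext = ".csv")
  write_samples_csv(ds$train, f)
  back <- read_samples_csv(f)
  expect_equal(unname(back$x), unname(ds$train$x))
  expect_identical(back$y, ds$train$y)
  unlink(f)

  lit <- tempfile(fileext = ".csv")
  writeLines(c("a,b,label", "1,2,1", "3,4,-1", "5,6,1"), lit)
  parsed <- read_samples_csv(lit)
  expect_equal(unname(parsed$x), matrix(c(1, 3, 5, 2, 4, 6), 3))
  expect_identical(parsed$y, c(1L, -1L, 1L))
  unlink(lit)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,label", "1,2", "3,1"), bad)
  expect_error(read_samples_csv(bad), "row 1")
  unlink(bad)

  bad2 <- tempfile(fileext = ".csv")
  writeLines(c("a,label", "x,1"), bad2)
  expect_error(read_samples_csv(bad2), "non-numeric")
  unlink(bad2)

  zo <- tempfile(fileext = ".csv")
  writeLines(c("a,label", "1,0", "2,1"), zo)
  expect_identical(read_samples_csv(zo, map01 = TRUE)$y, c(-1L, 1L))
  expect_error(read_samples_csv(zo), "labels must be -1 or \\+1")
  unlink(zo)
})

test_that("encrypted datasets decrypt back to the original values", {
  keys <- test_keys()
  ds <- generate_samples(synth_spec(n_samples = 15, d = 3, seed = 19))
  enc <- encrypt_samples(ds$train, keys$pub)
  back <- decrypt_samples(enc, keys$priv, keys$pub)
  expect_equal(unname(back$x), unname(ds$train$x))
  expect_identical(back$y, ds$train$y)
  # decimals at scale 4 survive too
  dec <- clinical_samples(matrix(c(1.5, -2.25, 0, 36.9), 2), c(1L, -1L),
                          scale_exp = 4L)
  enc4 <- encrypt_samples(dec, keys$pub)
  back4 <- decrypt_samples(enc4, keys$priv, keys$pub)
  expect_equal(unname(back4$x), unname(dec$x))
})

test_that("encrypted dataset files round-trip through JSONL", {
  keys <- test_keys()
  ds <- generate_samples(synth_spec(n_samples = 8, d = 2, seed = 21,
                                    balance = 0.5))
  enc <- encrypt_samples(ds$train, keys$pub)
  f <- tempfile(fileext = ".jsonl")
  write_encrypted_dataset(enc, f)
  lines <- readLines(f)
  expect_identical(length(lines), length(ds$train$y) + 1L)
  back <- read_encrypted_dataset(f)
  expect_identical(back$n, keys$pub$n)
  rec <- decrypt_samples(back, keys$priv, keys$pub)
  expect_equal(unname(rec$x), unname(ds$train$x))
  expect_identical(rec$y, ds$train$y)
  unlink(f)
})

test_that("re-encryption changes ciphertext bytes but not plaintexts", {
  keys <- test_keys()
  ds <- generate_samples(synth_spec(n_samples = 5, d = 2, seed = 23,
                                    balance = 0.5))
  set.seed(1); e1 <- encrypt_samples(ds$train, keys$pub)
  set.seed(2); e2 <- encrypt_samples(ds$train, keys$pub)
  expect_false(identical(e1$cx[[1]][[1]]$value, e2$cx[[1]][[1]]$value))
  expect_equal(decrypt_samples(e1, keys$priv, keys$pub)$x,
               decrypt_samples(e2, keys$priv, keys$pub)$x)
})
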