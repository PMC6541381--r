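test_that("toy key material matches hand arithmetic (p=5, q=7)", {
  kp <- toy_keys()
  expect_identical(bn_num(kp$pub$n), 35)
  expect_identical(bn_num(kp$priv$lambda), 12)   # lcm(4, 6)
  # mu = (L(36^12 mod 1225))^-1 mod 35, computed by the double oracle
  L <- (modpow_dbl(36, 12, 1225) - 1) / 35
  expect_identical((L * bn_num(kp$priv$mu)) %% 35, 1)
})

test_that("encryption with explicit blinding matches a direct modular oracle", {
  kp <- toy_keys()
  ct <- paillier_encrypt(kp$pub, 3, r = 2)
  expected <- (modpow_dbl(36, 3, 1225) * modpow_dbl(2, 35, 1225)) %% 1225
  expect_identical(bn_num(ct$value), expected)
  expect_identical(bn_num(paillier_decrypt(kp$priv, kp$pub, ct)), 3)
  # g = n + 1, m = 0, r = 1 gives the unit ciphertext
  kp1 <- paillier_from_primes(5, 7)
  expect_identical(bn_num(paillier_encrypt(kp1$pub, 0, r = 1)$value), 1)
})

test_that("encryption is probabilistic: fresh blinding, equal decryption", {
  keys <- test_keys()
  set.seed(31)
  vals <- replicate(100, paillier_encrypt(keys$pub, 12345)$value)
  expect_identical(length(unique(vals)), 100L)
  expect_true(all(vapply(vals, function(v)
    paillier_decrypt(keys$priv, keys$pub,
                     secureSLP:::new_ciphertext(v, keys$pub$key_id)) ==
      as_bn(12345), TRUE)))
})

test_that("decrypt is the left inverse of encrypt across the plaintext range", {
  keys <- test_keys()
  n <- keys$pub$n
  set.seed(37)
  for (i in 1:200) {
    m <- bn_rand_below(n)
    expect_identical(paillier_decrypt(keys$priv, keys$pub,
                                      paillier_encrypt(keys$pub, m)), m)
  }
  for (m in list("0", bn_sub(n, "1")))
    expect_identical(paillier_decrypt(keys$priv, keys$pub,
                                      paillier_encrypt(keys$pub, m)), m)
})

test_that("homomorphic identities hold exactly", {
  kp <- toy_keys()
  dec <- function(ct) bn_num(paillier_decrypt(kp$priv, kp$pub, ct))
  expect_identical(dec(hom_add(kp$pub, paillier_encrypt(kp$pub, 3),
                               paillier_encrypt(kp$pub, 4))), 7)
  expect_identical(dec(hom_add(kp$pub, paillier_encrypt(kp$pub, 34),
                               paillier_encrypt(kp$pub, 2))), 1)  # wraparound
  expect_identical(dec(hom_scalar(kp$pub, paillier_encrypt(kp$pub, 6), 3)), 18)
  expect_identical(dec(hom_scalar(kp$pub, paillier_encrypt(kp$pub, 7), 34)), 28)  # n - 7
  expect_identical(dec(hom_scalar(kp$pub, paillier_encrypt(kp$pub, 9), 1)), 9)
  expect_identical(dec(hom_add(kp$pub, paillier_encrypt(kp$pub, 0),
                               paillier_encrypt(kp$pub, 13))), 13)

  keys <- test_keys()
  n <- keys$pub$n
  set.seed(41)
  for (i in 1:50) {
    a <- bn_rand_below(n); b <- bn_rand_below(n); k <- bn_rand_below(n)
    s <- hom_add(keys$pub, paillier_encrypt(keys$pub, a),
                 paillier_encrypt(keys$pub, b))
    expect_identical(paillier_decrypt(keys$priv, keys$pub, s),
                     bn_mod(bn_add(a, b), n))
    p <- hom_scalar(keys$pub, paillier_encrypt(keys$pub, a), k)
    expect_identical(paillier_decrypt(keys$priv, keys$pub, p),
                     bn_mod(bn_mul(k, a), n))
  }
})

test_that("invalid inputs are rejected with informative errors", {
  kp <- toy_keys()
  expect_error(paillier_encrypt(kp$pub, 35), "out of range")
  expect_error(paillier_encrypt(kp$pub, -1), "out of range")
  expect_error(paillier_encrypt(kp$pub, 3, r = 5), "invalid blinding")
  expect_error(paillier_encrypt(kp$pub, 3, r = 0), "out of range")
  expect_error(hom_scalar(kp$pub, paillier_encrypt(kp$pub, 1), -2), "negative")
  other <- test_keys()
  expect_error(hom_add(kp$pub, paillier_encrypt(kp$pub, 1),
                       paillier_encrypt(other$pub, 1)), "mismatch")
  expect_error(paillier_decrypt(kp$priv, kp$pub,
                                secureSLP:::new_ciphertext(as_bn(10), kp$pub$key_id)),
               "malformed")
})

test_that("key generation is deterministic under a seed and validates sizes", {
  k1 <- paillier_keygen(128, seed = 7)
  k2 <- paillier_keygen(128, seed = 7)
  expect_identical(k1$pub$n, k2$pub$n)
  expect_identical(k1$priv$lambda, k2$priv$lambda)
  expect_identical(bn_nbits(k1$priv$p), 128L)
  expect_identical(bn_nbits(k1$priv$q), 128L)
  expect_identical(bn_nbits(k1$pub$n), 256L)
  expect_false(identical(paillier_keygen(128, seed = 8)$pub$n, k1$pub$n))
  expect_error(paillier_keygen(64), ">= 128")
})

test_that("keys round-trip through JSON files and still decrypt", {
  keys <- test_keys()
  pubf <- tempfile(fileext = ".json"); privf <- tempfile(fileext = ".json")
  write_paillier_keys(keys, pubf, privf)
  back <- read_paillier_keys(pubf, privf)
  expect_identical(back$pub$n, keys$pub$n)
  expect_identical(back$priv$mu, keys$priv$mu)
  m <- as_bn(987654321)
  expect_identical(paillier_decrypt(back$priv, back$pub,
                                    paillier_encrypt(back$pub, m)), m)
  pubonly <- read_paillier_keys(pubf)
  expect_null(pubonly$priv)
  unlink(c(pubf, privf))
})

test_that("a random generator g also yields a working cryptosystem", {
  kp <- paillier_keygen(128, seed = 55, g = "random")
  expect_false(kp$pub$g_is_n1)
  m <- as_bn(31415)
  expect_identical(paillier_decrypt(kp$priv, kp$pub,
                                    paillier_encrypt(kp$pub, m)), m)
})
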