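# Shared fixtures: keys are expensive, so cache them per test run.

.key_cache <- new.env(parent = emptyenv())

# 5 * 7 = 35 with the classic generator 36 = n + 1
toy_keys <- function() paillier_from_primes(5, 7, 36)

test_keys <- function(bits = 128, seed = 42) {
  id <- paste0("k", bits, "_", seed)
  if (is.null(.key_cache[[id]]))
    .key_cache[[id]] <- paillier_keygen(bits, seed = seed)
  .key_cache[[id]]
}

# Pure-double modular exponentiation: an oracle independent of the OpenSSL
# path, valid while m^2 stays below 2^53 (toy-key sized problems).
modpow_dbl <- function(b, e, m) {
  stopifnot(m^2 < 2^53)
  r <- 1; b <- b %% m
  while (e > 0) {
    if (e %% 2 == 1) r <- (r * b) %% m
    b <- (b * b) %% m
    e <- e %/% 2
  }
  r
}

enc_signed <- function(pk, v) paillier_encrypt(pk, fp_encode(v, 0L, pk$n)$residue)

dec_signed <- function(keys, ct)
  signed_value(paillier_decrypt(keys$priv, keys$pub, ct), keys$pub$n)

make_parties <- function(keys, seed1 = 101, seed2 = 202) {
  list(c1 = mpc_party("C1", pub = keys$pub, seed = seed1),
       c2 = mpc_party("C2", pub = keys$pub, priv = keys$priv, seed = seed2))
}
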