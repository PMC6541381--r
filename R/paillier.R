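# Paillier additively homomorphic cryptosystem.
#
# Plaintexts live in Z_n, ciphertexts in the multiplicative group mod n^2.
# Encryption is c = g^m * r^n mod n^2 with fresh blinding r coprime to n.
# (Some descriptions misprint the blinding factor as r^m; only r^n is
# compatible with the decryption equation and the homomorphic identities,
# and that is what is implemented here.)

key_id_of <- function(n) substr(n, 1L, 16L)

# evaluate expr under a locally seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

#' Generate a Paillier key pair
#'
#' Draws two distinct random primes \code{p}, \code{q} of exactly \code{bits}
#' bits each (so the modulus \code{n = p * q} has \code{2 * bits} bits),
#' checks \code{gcd(n, (p-1)(q-1)) = 1}, and derives
#' \code{lambda = lcm(p-1, q-1)} and \code{mu = L(g^lambda mod n^2)^{-1} mod n}
#' where \code{L(x) = (x-1)/n}. The generator defaults to \code{g = n + 1},
#' which is always valid and makes encryption cheap; \code{g = "random"} draws
#' a uniform valid generator instead.
#'
#' @param bits prime size in bits; 128 is the floor intended for tests,
#'   1024 or more is sensible for real use.
#' @param seed optional integer; when given, key generation is deterministic.
#' @param g \code{"n_plus_1"} (default) or \code{"random"}.
#' @param max_attempts retry budget for the prime search / gcd condition.
#' @return a list with elements \code{pub} (class \code{paillier_pubkey}:
#'   \code{n}, \code{g}, \code{n_sq}, \code{bits}, \code{key_id}) and
#'   \code{priv} (class \code{paillier_privkey}: \code{lambda}, \code{mu},
#'   \code{p}, \code{q} -- primes retained to support testing).
#' @examples
#' kp <- paillier_keygen(bits = 128, seed = 1)
#' m <- as_bn(42)
#' paillier_decrypt(kp$priv, kp$pub, paillier_encrypt(kp$pub, m)) == m
#' @export
paillier_keygen <- function(bits = 512, seed = NULL, g = c("n_plus_1", "random"),
                            max_attempts = 25L) {
  g <- match.arg(g)
  if (bits < 128) stop("bits must be >= 128 (use paillier_from_primes() for toy keys)")
  with_local_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      p <- bn_rand_prime(bits)
      q <- bn_rand_prime(bits)
      if (bn_cmp(p, q) == 0L) next
      n <- bn_mul(p, q)
      pre <- bn_mul(bn_sub(p, "1"), bn_sub(q, "1"))
      if (bn_gcd(n, pre) != "1") next
      g_val <- if (g == "n_plus_1") bn_add(n, "1") else sample_generator(n)
      key <- try(paillier_from_primes(p, q, g_val), silent = TRUE)
      if (!inherits(key, "try-error")) return(key)
    }
    stop("key generation failed within the attempt budget")
  })
}

# uniform g in Z*_{n^2} whose L(g^lambda) is invertible; resampled on failure
# by paillier_from_primes' caller
sample_generator <- function(n) {
  n_sq <- bn_mul(n, n)
  repeat {
    cand <- bn_rand_below(n_sq, lo = 2)
    if (bn_gcd(cand, n) == "1") return(cand)
  }
}

#' Build a Paillier key pair from given primes
#'
#' Mainly for tests and worked examples with tiny "toy" parameters
#' (e.g. \code{p = 5}, \code{q = 7}, \code{g = 36}). Validates the gcd
#' condition and that \code{mu} exists.
#'
#' @param p,q primes (numeric or hex strings).
#' @param g generator (numeric or hex); default \code{n + 1}.
#' @return as [paillier_keygen()].
#' @export
paillier_from_primes <- function(p, q, g = NULL) {
  p <- if (is.character(p)) p else as_bn(p)
  q <- if (is.character(q)) q else as_bn(q)
  if (!bn_is_prime(p) || !bn_is_prime(q)) stop("p and q must be prime")
  if (bn_cmp(p, q) == 0L) stop("p and q must differ")
  n <- bn_mul(p, q)
  pre <- bn_mul(bn_sub(p, "1"), bn_sub(q, "1"))
  if (bn_gcd(n, pre) != "1") stop("gcd(pq, (p-1)(q-1)) must be 1")
  if (is.null(g)) g <- bn_add(n, "1") else g <- if (is.character(g)) g else as_bn(g)
  n_sq <- bn_mul(n, n)
  if (bn_gcd(g, n) != "1") stop("g must be invertible mod n^2")
  lambda <- bn_lcm(bn_sub(p, "1"), bn_sub(q, "1"))
  lg <- bn_powm(g, lambda, n_sq)
  L <- bn_div(bn_sub(lg, "1"), n)
  mu <- tryCatch(bn_invm(bn_mod(L, n), n),
                 error = function(e) stop("invalid generator: L(g^lambda) not invertible mod n"))
  pub <- structure(
    list(n = n, g = g, n_sq = n_sq, bits = bn_nbits(p), key_id = key_id_of(n),
         g_is_n1 = bn_cmp(g, bn_add(n, "1")) == 0L),
    class = "paillier_pubkey")
  priv <- structure(
    list(lambda = lambda, mu = mu, p = p, q = q, key_id = key_id_of(n)),
    class = "paillier_privkey")
  list(pub = pub, priv = priv)
}

#' @export
print.paillier_pubkey <- function(x, ...) {
  cat("Paillier public key: |n| =", bn_nbits(x$n), "bits, key id", x$key_id,
      if (x$g_is_n1) "(g = n + 1)\n" else "(random g)\n")
  invisible(x)
}

#' @export
print.paillier_privkey <- function(x, ...) {
  cat("Paillier private key for key id", x$key_id, "\n")
  invisible(x)
}

new_ciphertext <- function(value, key_id) {
  structure(list(value = value, key_id = key_id), class = "paillier_ciphertext")
}

#' @export
print.paillier_ciphertext <- function(x, ...) {
  cat("Paillier ciphertext under key", x$key_id, ":",
      substr(x$value, 1L, 24L), "...\n")
  invisible(x)
}

is_ciphertext <- function(x) inherits(x, "paillier_ciphertext")

check_key <- function(pk, ct) {
  if (!is_ciphertext(ct)) stop("not a Paillier ciphertext")
  if (!identical(ct$key_id, pk$key_id))
    stop("ciphertext key mismatch: encrypted under a different public key")
}

coerce_plain <- function(m) if (is.character(m)) m else as_bn(m)

#' Encrypt a plaintext residue
#'
#' Computes \code{c = g^m * r^n mod n^2}. A fresh uniform blinding
#' \code{r in [1, n)} coprime to \code{n} is drawn from R's RNG when \code{r}
#' is omitted, so repeated encryptions of the same plaintext are distinct.
#'
#' @param pk a \code{paillier_pubkey}.
#' @param m plaintext in \code{[0, n)} (numeric or hex string).
#' @param r optional explicit blinding in \code{(0, n)}, coprime to \code{n}.
#' @return a \code{paillier_ciphertext}.
#' @export
paillier_encrypt <- function(pk, m, r = NULL) {
  m <- coerce_plain(m)
  if (bn_cmp(m, "0") < 0L || bn_cmp(m, pk$n) >= 0L)
    stop("plaintext out of range [0, n)")
  if (is.null(r)) {
    repeat {
      r <- bn_rand_below(pk$n, lo = 1)
      if (bn_gcd(r, pk$n) == "1") break
    }
  } else {
    r <- coerce_plain(r)
    if (bn_cmp(r, "0") <= 0L || bn_cmp(r, pk$n) >= 0L)
      stop("blinding r out of range (0, n)")
    if (bn_gcd(r, pk$n) != "1")
      stop("invalid blinding: r shares a factor with n")
  }
  if (pk$g_is_n1) {
    gm <- bn_mod(bn_add("1", bn_mul(m, pk$n)), pk$n_sq)  # (n+1)^m = 1 + m*n mod n^2
  } else {
    gm <- bn_powm(pk$g, m, pk$n_sq)
    ledger_tick("EXP")
  }
  rn <- bn_powm(r, pk$n, pk$n_sq)
  ledger_tick("EXP")
  val <- bn_mod(bn_mul(gm, rn), pk$n_sq)
  ledger_tick("MUL")
  new_ciphertext(val, pk$key_id)
}

#' Decrypt a ciphertext
#'
#' Computes \code{m = L(c^lambda mod n^2) * mu mod n}, \code{L(x) = (x-1)/n}.
#'
#' @param sk a \code{paillier_privkey}.
#' @param pk the matching \code{paillier_pubkey}.
#' @param ct a \code{paillier_ciphertext} under \code{pk}.
#' @return the plaintext residue as a hex string in \code{[0, n)}.
#' @export
paillier_decrypt <- function(sk, pk, ct) {
  check_key(pk, ct)
  if (!identical(sk$key_id, pk$key_id)) stop("private key does not match public key")
  if (bn_gcd(ct$value, pk$n) != "1")
    stop("malformed ciphertext: value shares a factor with n")
  u <- bn_powm(ct$value, sk$lambda, pk$n_sq)
  ledger_tick("EXP")
  L <- bn_div(bn_sub(u, "1"), pk$n)
  out <- bn_mod(bn_mul(L, sk$mu), pk$n)
  ledger_tick("MUL")
  ledger_tick("DIV")  # the modular inverse folded into mu
  out
}

#' Homomorphic operations on ciphertexts
#'
#' \code{hom_add} multiplies two ciphertexts mod \code{n^2}, which adds the
#' plaintexts mod \code{n}; \code{hom_scalar} raises a ciphertext to a
#' nonnegative integer power \code{k < n}, which multiplies the plaintext by
#' \code{k} mod \code{n}. Exponent \code{n - k} therefore realizes
#' subtraction of \code{k} times the plaintext, which the protocols use for
#' their correction terms.
#'
#' @param pk the shared \code{paillier_pubkey}.
#' @param c1,c2,ct ciphertexts under \code{pk}.
#' @param k scalar in \code{[0, n)} (numeric or hex). Negative values error;
#'   map \code{-k} to \code{n - k} first.
#' @return a \code{paillier_ciphertext}.
#' @export
hom_add <- function(pk, c1, c2) {
  check_key(pk, c1); check_key(pk, c2)
  ledger_tick("MUL")
  new_ciphertext(bn_mod(bn_mul(c1$value, c2$value), pk$n_sq), pk$key_id)
}

#' @rdname hom_add
#' @export
hom_scalar <- function(pk, ct, k) {
  check_key(pk, ct)
  k <- coerce_plain(k)
  if (bn_cmp(k, "0") < 0L)
    stop("negative scalar: use the additive inverse exponent n - k")
  if (bn_cmp(k, pk$n) >= 0L) stop("scalar out of range [0, n)")
  ledger_tick("EXP")
  new_ciphertext(bn_powm(ct$value, k, pk$n_sq), pk$key_id)
}

#' Read and write Paillier key files
#'
#' Keys are stored as JSON with hex-encoded big integers: the public file
#' holds \code{n} and \code{g}; the private file holds \code{lambda},
#' \code{mu}, \code{p} and \code{q}. The private file is written with mode
#' \code{0600}; keep it out of shared storage.
#'
#' @param keys a key pair as returned by [paillier_keygen()].
#' @param pub_path,priv_path file paths.
#' @return \code{read_paillier_keys} returns a key pair; if only
#'   \code{pub_path} is supplied, \code{priv} is \code{NULL}.
#' @export
write_paillier_keys <- function(keys, pub_path, priv_path = NULL) {
  jsonlite::write_json(list(n = keys$pub$n, g = keys$pub$g),
                       pub_path, auto_unbox = TRUE)
  if (!is.null(priv_path)) {
    jsonlite::write_json(list(lambda = keys$priv$lambda, mu = keys$priv$mu,
                              p = keys$priv$p, q = keys$priv$q),
                         priv_path, auto_unbox = TRUE)
    Sys.chmod(priv_path, mode = "0600")
  }
  invisible(NULL)
}

#' @rdname write_paillier_keys
#' @export
read_paillier_keys <- function(pub_path, priv_path = NULL) {
  pubj <- jsonlite::read_json(pub_path)
  n <- as_bn(pubj$n); g <- as_bn(pubj$g)
  pub <- structure(
    list(n = n, g = g, n_sq = bn_mul(n, n), bits = bn_nbits(n) %/% 2L,
         key_id = key_id_of(n), g_is_n1 = bn_cmp(g, bn_add(n, "1")) == 0L),
    class = "paillier_pubkey")
  priv <- NULL
  if (!is.null(priv_path)) {
    pj <- jsonlite::read_json(priv_path)
    priv <- structure(
      list(lambda = as_bn(pj$lambda), mu = as_bn(pj$mu),
           p = as_bn(pj$p), q = as_bn(pj$q), key_id = key_id_of(n)),
      class = "paillier_privkey")
  }
  list(pub = pub, priv = priv)
}
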