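#' @useDynLib secureSLP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Arbitrary-precision integers as hex strings
#'
#' The package represents big integers as lowercase hexadecimal strings
#' (optionally prefixed with \code{-}), backed by OpenSSL's BIGNUM arithmetic.
#' \code{as_bn()} coerces R numerics (exact up to 2^53) and decimal or hex
#' strings to this form; \code{bn_num()} converts back to double, erroring when
#' the value cannot be represented exactly.
#'
#' @param x a numeric scalar, a hex string, or (for \code{as_bn} with
#'   \code{decimal = TRUE}) a decimal string.
#' @param decimal interpret a character \code{x} as base 10 rather than base 16.
#' @return \code{as_bn}: a hex string; \code{bn_num}: a double.
#' @examples
#' as_bn(255)          # "ff"
#' bn_num(bn_mul(as_bn(12), as_bn(12)))
#' @export
as_bn <- function(x, decimal = FALSE) {
  if (is.character(x)) {
    if (decimal) return(.bn_dec2hex(x))
    return(.bn_dec2hex(.bn_hex2dec(x)))  # normalizes case / leading zeros
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("as_bn() expects a single non-missing numeric or string")
  if (abs(x) >= 2^53 || x != trunc(x))
    stop("numeric value cannot be represented exactly; pass a string instead")
  .bn_dec2hex(sprintf("%.0f", x))
}

#' @rdname as_bn
#' @export
bn_num <- function(x) {
  if (.bn_nbits(x) > 53L)
    stop("big integer exceeds exact double range (2^53); keep it as a string")
  as.numeric(.bn_hex2dec(x))
}

#' Big-integer arithmetic primitives
#'
#' Thin wrappers over OpenSSL BIGNUM: \code{bn_add}, \code{bn_sub},
#' \code{bn_mul}, \code{bn_div} (truncated quotient), \code{bn_mod}
#' (nonnegative residue), \code{bn_powm} (modular exponentiation,
#' nonnegative exponent), \code{bn_invm} (modular inverse), \code{bn_gcd},
#' \code{bn_lcm}, comparison \code{bn_cmp} (-1/0/1), bit length
#' \code{bn_nbits}, and the Miller-Rabin test \code{bn_is_prime}.
#' All arguments are hex strings as produced by [as_bn()].
#'
#' @param a,b,e,m hex-encoded integers.
#' @param nchecks minimum number of Miller-Rabin witnesses.
#' @name bn_arith
NULL

#' @rdname bn_arith
#' @export
bn_add <- function(a, b) .bn_add(a, b)
#' @rdname bn_arith
#' @export
bn_sub <- function(a, b) .bn_sub(a, b)
#' @rdname bn_arith
#' @export
bn_mul <- function(a, b) .bn_mul(a, b)
#' @rdname bn_arith
#' @export
bn_div <- function(a, b) .bn_div(a, b)
#' @rdname bn_arith
#' @export
bn_mod <- function(a, m) .bn_mod(a, m)
#' @rdname bn_arith
#' @export
bn_powm <- function(a, e, m) .bn_powm(a, e, m)
#' @rdname bn_arith
#' @export
bn_invm <- function(a, m) .bn_invm(a, m)
#' @rdname bn_arith
#' @export
bn_gcd <- function(a, b) .bn_gcd(a, b)
#' @rdname bn_arith
#' @export
bn_lcm <- function(a, b) .bn_div(.bn_mul(a, b), .bn_gcd(a, b))
#' @rdname bn_arith
#' @export
bn_cmp <- function(a, b) .bn_cmp(a, b)
#' @rdname bn_arith
#' @export
bn_nbits <- function(a) .bn_nbits(a)
#' @rdname bn_arith
#' @export
bn_is_prime <- function(a, nchecks = 64L) .bn_is_prime(a, nchecks)

bn_zero <- function() "0"
bn_one <- function() "1"
bn_is_zero <- function(a) .bn_cmp(a, "0") == 0L

#' Random big integers from R's RNG
#'
#' Draws uniform integers using R's random number stream (so results respect
#' \code{set.seed()}). \code{bn_rand_bits} returns an integer of exactly
#' \code{bits} bits (top bit set); \code{bn_rand_below} samples uniformly from
#' \code{[lo, m)} by rejection.
#'
#' @param bits number of bits (>= 2).
#' @param m exclusive upper bound, hex.
#' @param lo inclusive lower bound (numeric, small), default 0.
#' @return a hex string.
#' @export
bn_rand_bits <- function(bits) {
  stopifnot(bits >= 2)
  nbytes <- ceiling(bits / 8)
  bytes <- sample.int(256L, nbytes, replace = TRUE) - 1L
  # clear excess high bits, then force the top bit so the length is exact
  excess <- nbytes * 8L - bits
  bytes[1L] <- bytes[1L] %% bitwShiftL(1L, 8L - excess)
  bytes[1L] <- bitwOr(bytes[1L], bitwShiftL(1L, 7L - excess))
  paste(sprintf("%02x", bytes), collapse = "")
}

#' @rdname bn_rand_bits
#' @export
bn_rand_below <- function(m, lo = 0) {
  bits <- .bn_nbits(m)
  nbytes <- ceiling(bits / 8)
  excess <- nbytes * 8L - bits
  lo_bn <- as_bn(lo)
  repeat {
    bytes <- sample.int(256L, nbytes, replace = TRUE) - 1L
    bytes[1L] <- bytes[1L] %% bitwShiftL(1L, 8L - excess)
    cand <- paste(sprintf("%02x", bytes), collapse = "")
    if (.bn_cmp(cand, m) < 0L && .bn_cmp(cand, lo_bn) >= 0L) return(as_bn(cand))
  }
}

#' Random probable prime of a given bit length
#'
#' Draws a random odd integer of exactly \code{bits} bits (top two bits set so
#' that products of two such primes have exactly \code{2 * bits} bits) from R's
#' RNG, then searches upward in steps of 2 until a Miller-Rabin probable prime
#' is found.
#'
#' @param bits prime size in bits.
#' @param max_steps search budget (candidates examined) before erroring.
#' @return a hex string holding the prime.
#' @export
bn_rand_prime <- function(bits, max_steps = 50000L) {
  stopifnot(bits >= 8)
  cand <- bn_rand_bits(bits)                          # top bit set
  cand <- bn_or_bit(cand, bn_shift_pow2(bits - 2))    # second-highest bit set
  if (bn_mod(cand, "2") == "0") cand <- bn_add(cand, "1")
  for (i in seq_len(max_steps)) {
    if (.bn_is_prime(cand, 64L)) return(cand)
    cand <- bn_add(cand, "2")
  }
  stop("failed to find a prime within the attempt budget; increase max_steps")
}

# 2^k as hex
bn_shift_pow2 <- function(k) {
  stopifnot(k >= 0)
  q <- k %/% 4
  r <- k %% 4
  paste0(c("1", "2", "4", "8")[r + 1L], strrep("0", q))
}

# a | b for b a power of two (set one bit): a + b - (a mod 2b >= b ? b : 0)
bn_or_bit <- function(a, bit) {
  twob <- bn_mul(bit, "2")
  if (.bn_cmp(bn_mod(a, twob), bit) >= 0L) a else bn_add(a, bit)
}
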