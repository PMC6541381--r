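# Signed fixed-point encoding into the Paillier plaintext ring Z_n
# (the approximation-and-expansion convention: scale by a power of ten,
# round, and store negatives as n - |value|).

#' Signed fixed-point encoding in Z_n
#'
#' Real values are scaled by \code{10^scale_exp}, rounded to the nearest
#' integer, and embedded in \code{Z_n} with negatives represented as
#' \code{n - |value|}. The symmetric-range convention applies throughout:
#' residues at most \code{n/2} are nonnegative, residues above \code{n/2}
#' decode as negative. The default scale of 4 decimal digits matches common
#' practice for clinical attributes; integer-valued attributes can use
#' \code{scale_exp = 0}.
#'
#' Encoded magnitudes must stay below \code{n/2}, otherwise the sign of the
#' decoded value would be ambiguous; \code{fp_encode} errors on overflow.
#' The product of two scale-\code{s} encodings carries scale \code{2s} (an
#' inner product of scale-4 attributes and weights decodes at scale 8); the
#' sign of a decoded value is invariant to the positive scale factor.
#'
#' @param x a real number.
#' @param scale_exp nonnegative integer, the power-of-ten scale (default 4).
#' @param n the Paillier modulus (hex string).
#' @param m a residue in \code{[0, n)} (hex string or numeric).
#' @return \code{fp_encode}: a list of class \code{fp_scalar} with fields
#'   \code{residue} (hex), \code{scale_exp} and \code{key_id} of the modulus;
#'   \code{fp_decode}: a double; \code{signed_value}: the signed integer
#'   (double when representable, otherwise a hex string with sign).
#' @examples
#' kp <- paillier_from_primes(5, 7)   # n = 35, toy modulus
#' fp_encode(3, 0, kp$pub$n)$residue  # "3"
#' fp_decode(as_bn(33), 0, kp$pub$n)  # -2
#' @export
fp_encode <- function(x, scale_exp = 4L, n) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x),
            scale_exp >= 0L, scale_exp == trunc(scale_exp))
  mag <- round(abs(x) * 10^scale_exp)
  if (mag >= 2^53) stop("scaled magnitude exceeds exact double range")
  mag_bn <- as_bn(mag)
  # largest unambiguous magnitude is floor((n-1)/2), for either sign
  if (bn_cmp(mag_bn, bn_div(bn_sub(n, "1"), "2")) > 0L)
    stop("encoded magnitude reaches n/2: sign would be ambiguous (use a larger key)")
  residue <- if (x < 0 && mag > 0) bn_sub(n, mag_bn) else mag_bn
  structure(list(residue = residue, scale_exp = as.integer(scale_exp),
                 key_id = key_id_of(n)),
            class = "fp_scalar")
}

#' @rdname fp_encode
#' @export
fp_decode <- function(m, scale_exp = 4L, n) {
  v <- signed_value(m, n)
  if (is.character(v)) stop("decoded magnitude exceeds exact double range")
  v / 10^scale_exp
}

#' @rdname fp_encode
#' @export
signed_value <- function(m, n) {
  m <- coerce_plain(m)
  if (bn_cmp(m, "0") < 0L || bn_cmp(m, n) >= 0L) stop("residue out of range [0, n)")
  half <- bn_div(n, "2")
  signed <- if (bn_cmp(m, half) <= 0L) m else bn_sub(m, n)
  neg <- startsWith(signed, "-")
  mag <- if (neg) substring(signed, 2L) else signed
  if (bn_nbits(mag) <= 53L) {
    out <- as.numeric(.bn_hex2dec(mag))
    return(if (neg) -out else out)
  }
  signed
}

# encode a signed integer (no rescaling) into Z_n; inverse of signed_value
encode_signed_int <- function(v, n) {
  if (is.character(v)) {
    if (startsWith(v, "-")) return(bn_sub(n, substring(v, 2L)))
    return(v)
  }
  stopifnot(v == trunc(v), abs(v) < 2^53)
  if (v >= 0) as_bn(v) else bn_sub(n, as_bn(-v))
}
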