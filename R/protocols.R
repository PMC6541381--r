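# Two-party secure multiplication over Paillier ciphertexts.
#
# Party C1 (the cloud) holds ciphertexts under C2's public key; C2 (the
# hospital) holds the private key. C1 additively blinds each ciphertext with
# a secret residue before handing it over, so C2 only ever decrypts masked
# values; C1 then strips the blinding homomorphically with correction terms
# raised to additive-inverse exponents (n - r).

sample_blinding <- function(n) bn_rand_below(n, lo = 1)

#' Secure multiplication of two encrypted scalars
#'
#' Given \code{E(x)} and \code{E(y)} held by \code{c1} under \code{c2}'s
#' public key, returns \code{E(x * y)} without revealing \code{x} or \code{y}
#' to either party. \code{c1} sends the blinded pair
#' \code{E(x + r_x), E(y + r_y)}; \code{c2} decrypts, multiplies mod \code{n},
#' and returns \code{H = E((x + r_x)(y + r_y))}; \code{c1} removes the cross
#' terms via \code{H * E(x)^{n - r_y} * E(y)^{n - r_x} * E(r_x r_y)^{n - 1}}.
#' One request/response round.
#'
#' @param c1 the [mpc_party()] holding the input ciphertexts.
#' @param c2 the [mpc_party()] holding the private key.
#' @param cx,cy ciphertexts of the factors, under \code{c2}'s key.
#' @param transcript an optional [new_transcript()] that accumulates messages
#'   and operation counts.
#' @param reveal_blinding attach the blinding residues to the result as
#'   attribute \code{"blinding"} (for auditing/tests only).
#' @return a \code{paillier_ciphertext} of the product.
#' @export
sm_product <- function(c1, c2, cx, cy, transcript = NULL,
                       reveal_blinding = FALSE) {
  pk <- c2$pub
  if (is.null(pk)) stop("c2 must hold the public key")
  if (is.null(c2$priv)) stop("c2 must hold the private key")
  check_key(pk, cx); check_key(pk, cy)
  n <- pk$n

  # Step 1 (C1): blind both factors
  step1 <- as_party_step(transcript, c1, {
    r_x <- sample_blinding(n)
    r_y <- sample_blinding(n)
    x1 <- hom_add(pk, cx, paillier_encrypt(pk, r_x))
    y1 <- hom_add(pk, cy, paillier_encrypt(pk, r_y))
    list(r_x = r_x, r_y = r_y, x1 = x1, y1 = y1)
  })
  record_message(transcript, c1$name, c2$name, "SM.step1",
                 list(step1$x1, step1$y1))

  # Step 2 (C2): decrypt masked factors, return encrypted masked product
  H <- as_party_step(transcript, c2, {
    hx <- paillier_decrypt(c2$priv, pk, step1$x1)
    hy <- paillier_decrypt(c2$priv, pk, step1$y1)
    h1 <- bn_mod(bn_mul(hx, hy), n)
    ledger_tick("MUL")
    paillier_encrypt(pk, h1)
  })
  record_message(transcript, c2$name, c1$name, "SM.step2", list(H))

  # Step 3 (C1): strip the blinding
  out <- as_party_step(transcript, c1, {
    s1 <- hom_scalar(pk, cx, bn_sub(n, step1$r_y))
    s2 <- hom_scalar(pk, cy, bn_sub(n, step1$r_x))
    s3 <- hom_scalar(pk, paillier_encrypt(pk, bn_mod(bn_mul(step1$r_x, step1$r_y), n)),
                     bn_sub(n, "1"))
    hom_add(pk, hom_add(pk, hom_add(pk, H, s1), s2), s3)
  })
  if (reveal_blinding)
    attr(out, "blinding") <- list(r_x = step1$r_x, r_y = step1$r_y)
  out
}

#' One-round secure inner product of two encrypted vectors
#'
#' Computes \code{E(sum_j x_j * w_j)} from element-wise ciphertext vectors in a
#' single request/response round, for any dimension \code{d}: \code{c1} blinds
#' every coordinate of both vectors and sends all \code{2d} masked ciphertexts
#' in one flight; \code{c2} decrypts them, sums the \code{d} masked products
#' mod \code{n}, and returns a single \code{H = E(sum_j (x_j + r_xj)(w_j +
#' r_wj))}; \code{c1} then cancels the blinding with three aggregated
#' correction terms \code{T1 = prod_j E(r_xj r_wj)^{n-1}},
#' \code{T2 = prod_j E(x_j)^{n - r_wj}}, \code{T3 = prod_j E(w_j)^{n - r_xj}},
#' so that \code{R = H * T1 * T2 * T3}. Running element-wise secure
#' multiplication instead would take \code{d} rounds.
#'
#' Fresh blinding residues are drawn for every invocation.
#'
#' @inheritParams sm_product
#' @param cx,cw equal-length lists of ciphertexts under \code{c2}'s key.
#' @return a \code{paillier_ciphertext} of the inner product (mod \code{n};
#'   decode signed results with [signed_value()]).
#' @export
lsm_inner_product <- function(c1, c2, cx, cw, transcript = NULL,
                              reveal_blinding = FALSE) {
  pk <- c2$pub
  if (is.null(pk)) stop("c2 must hold the public key")
  if (is.null(c2$priv)) stop("c2 must hold the private key")
  d <- length(cx)
  if (d == 0L) stop("empty input: vectors must have length >= 1")
  if (length(cw) != d) stop("dimension mismatch: length(cx) != length(cw)")
  for (ct in c(cx, cw)) check_key(pk, ct)
  n <- pk$n

  # Step 1 (C1): blind every coordinate of both vectors, one flight to C2
  step1 <- as_party_step(transcript, c1, {
    r_x <- vapply(seq_len(d), function(j) sample_blinding(n), "")
    r_w <- vapply(seq_len(d), function(j) sample_blinding(n), "")
    X <- lapply(seq_len(d), function(j)
      hom_add(pk, cx[[j]], paillier_encrypt(pk, r_x[[j]])))
    W <- lapply(seq_len(d), function(j)
      hom_add(pk, cw[[j]], paillier_encrypt(pk, r_w[[j]])))
    list(r_x = r_x, r_w = r_w, X = X, W = W)
  })
  record_message(transcript, c1$name, c2$name, "LSM.step1",
                 c(step1$X, step1$W))

  # Step 2 (C2): decrypt masked pairs, sum the masked products, return one H
  H <- as_party_step(transcript, c2, {
    h <- "0"
    for (j in seq_len(d)) {
      xj <- paillier_decrypt(c2$priv, pk, step1$X[[j]])
      wj <- paillier_decrypt(c2$priv, pk, step1$W[[j]])
      h <- bn_mod(bn_add(h, bn_mul(xj, wj)), n)
      ledger_tick("MUL", 2L)
    }
    paillier_encrypt(pk, h)
  })
  record_message(transcript, c2$name, c1$name, "LSM.step2", list(H))

  # Step 3 (C1): aggregated correction terms cancel every blinding cross term
  out <- as_party_step(transcript, c1, {
    acc <- H
    for (j in seq_len(d)) {
      t1j <- hom_scalar(pk,
        paillier_encrypt(pk, bn_mod(bn_mul(step1$r_x[[j]], step1$r_w[[j]]), n)),
        bn_sub(n, "1"))
      t2j <- hom_scalar(pk, cx[[j]], bn_sub(n, step1$r_w[[j]]))
      t3j <- hom_scalar(pk, cw[[j]], bn_sub(n, step1$r_x[[j]]))
      acc <- hom_add(pk, hom_add(pk, hom_add(pk, acc, t1j), t2j), t3j)
    }
    acc
  })
  if (reveal_blinding)
    attr(out, "blinding") <- list(r_x = step1$r_x, r_w = step1$r_w)
  out
}

#' Protocol objects for [run_protocol()]
#'
#' Wrap the secure-multiplication and secure-inner-product protocols so they
#' can be executed by the generic runner with a named party list
#' \code{list(c1 =, c2 =)}.
#'
#' @return a list with \code{name} and \code{fn}.
#' @export
sm_protocol <- function() {
  list(name = "SM", fn = function(parties, t, cx, cy, ...)
    sm_product(parties$c1, parties$c2, cx, cy, transcript = t, ...))
}

#' @rdname sm_protocol
#' @export
lsm_protocol <- function() {
  list(name = "LSM", fn = function(parties, t, cx, cw, ...)
    lsm_inner_product(parties$c1, parties$c2, cx, cw, transcript = t, ...))
}
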