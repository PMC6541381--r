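# Disease prediction: the undiagnosed patient encrypts symptoms under the
# hospital's key; the hospital decrypts, scores with its plaintext model, and
# returns only the class, encrypted under the patient's own key.

#' Encrypt a symptom vector for prediction
#'
#' Convenience for the querying patient: encodes each attribute at the given
#' fixed-point scale and encrypts under the hospital's public key.
#'
#' @param x numeric symptom vector.
#' @param pk the hospital's \code{paillier_pubkey}.
#' @param scale_exp fixed-point scale (match the model's feature scale).
#' @return list of \code{paillier_ciphertext}.
#' @export
encrypt_symptoms <- function(x, pk, scale_exp = 0L) {
  lapply(x, function(v)
    paillier_encrypt(pk, fp_encode(v, scale_exp, pk$n)$residue))
}

#' Predict disease status from encrypted symptoms
#'
#' The hospital decrypts the symptom ciphertexts, computes the score
#' \code{s = sum_j x_j * w_j} against its plaintext model, classifies with
#' \code{sign_fn} (\code{s >= 0} means the patient suffers from the disease),
#' and encrypts the outcome under the patient's public key: plaintext \code{1}
#' for "suffers", \code{0} for "does not". Scoring is deliberately
#' plaintext-side at the hospital -- the model is the hospital's asset and
#' never leaves it; what is protected is the symptom vector in transit and
#' the result, which only the patient can decrypt. No plaintext symptom value
#' is retained in the returned object or the transcript.
#'
#' @param hospital [mpc_party()] with the hospital key pair.
#' @param model a plaintext model (from [train_plain()], or a decrypted
#'   encrypted-domain model: any list with integer \code{w},
#'   \code{disease_index}, \code{scale_exp}).
#' @param c_symptoms list of symptom ciphertexts under the hospital's key
#'   (include the constant bias feature if the model was trained with one).
#' @param up_pub the patient's \code{paillier_pubkey}.
#' @param transcript optional [new_transcript()].
#' @return an object of class \code{prediction_result}: \code{label} in
#'   \code{{-1, +1}}, \code{ciphertext_for_patient} under \code{up_pub},
#'   \code{disease_index}.
#' @export
predict_disease <- function(hospital, model, c_symptoms, up_pub,
                            transcript = NULL) {
  pk <- hospital$pub
  if (is.null(pk) || is.null(hospital$priv))
    stop("hospital must hold its key pair")
  if (length(c_symptoms) != length(model$w))
    stop("dimension mismatch: model has ", length(model$w), " weights, got ",
         length(c_symptoms), " symptom ciphertexts")
  record_message(transcript, "UP", hospital$name, "predict.symptoms",
                 c_symptoms)
  res <- as_party_step(transcript, hospital, {
    s <- 0
    for (j in seq_along(c_symptoms)) {
      xj <- signed_value(paillier_decrypt(hospital$priv, pk, c_symptoms[[j]]),
                         pk$n)
      if (is.character(xj)) stop("symptom magnitude exceeds double range")
      s <- s + xj * model$w[j]
      if (j > 1L) ledger_tick("MUL")
    }
    label <- sign_fn(s)
    ct <- paillier_encrypt(up_pub, if (label == 1L) "1" else "0")
    list(label = label, ct = ct)
  })
  record_message(transcript, hospital$name, "UP", "predict.result",
                 list(res$ct))
  structure(list(label = res$label, ciphertext_for_patient = res$ct,
                 disease_index = model$disease_index[1]),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("prediction_result: disease", x$disease_index, "->",
      if (x$label == 1L) "positive (+1)" else "negative (-1)",
      "(result ciphertext under patient key", x$ciphertext_for_patient$key_id,
      ")\n")
  invisible(x)
}

#' Decode a prediction result as the patient
#'
#' @param result a \code{prediction_result}.
#' @param up_priv,up_pub the patient's key pair.
#' @return \code{-1L} or \code{1L}.
#' @export
decode_prediction <- function(result, up_priv, up_pub) {
  m <- paillier_decrypt(up_priv, up_pub, result$ciphertext_for_patient)
  if (m == "1") 1L else -1L
}
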