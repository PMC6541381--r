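# Single-layer perceptron training, twice over: the classical plaintext
# mistake-driven rule (the exactness oracle), and the same rule executed
# between a Cloud holding only ciphertexts and a Hospital holding the private
# key. Because every encrypted update is an exact homomorphic image of the
# plaintext update, the two runs agree weight-for-weight at every epoch when
# started from the same initialization and visit order.

#' Perceptron activation
#'
#' \code{+1} when \code{z >= 0}, \code{-1} otherwise (zero maps to the
#' positive class, matching the prediction rule "score >= 0 means the patient
#' suffers from the disease"). Any threshold is folded into a bias weight
#' \code{w_0 = -theta} against a constant feature \code{x_0 = 1}.
#'
#' @param z a numeric scalar (signed integer score).
#' @return \code{-1L} or \code{1L}.
#' @export
sign_fn <- function(z) {
  stopifnot(is.numeric(z), length(z) == 1L, !is.na(z))
  if (z >= 0) 1L else -1L
}

#' Training configuration
#'
#' @param eta positive integer learning rate (default 1). Ciphertext
#'   exponents are integers, and perceptron decisions are invariant to a
#'   positive rescaling of \code{eta} and \code{w} together, so restricting
#'   to integers loses no generality.
#' @param iteration_max epoch cap (default 100).
#' @param order \code{"sequential"} (default) or \code{"shuffle"} (seeded
#'   reshuffle each epoch).
#' @param bias add a constant feature \code{x_0 = 1} at the working scale,
#'   realizing a learned threshold. Off by default.
#' @param seed seed controlling the default weight initialization and any
#'   shuffling; the same configuration therefore yields the same run in both
#'   the plaintext and encrypted domains.
#' @return an object of class \code{train_config}.
#' @export
train_config <- function(eta = 1L, iteration_max = 100L,
                         order = c("sequential", "shuffle"),
                         bias = FALSE, seed = 1L) {
  order <- match.arg(order)
  stopifnot(eta >= 1, eta == trunc(eta), iteration_max >= 1)
  structure(list(eta = as.integer(eta),
                 iteration_max = as.integer(iteration_max),
                 order = order, bias = isTRUE(bias), seed = as.integer(seed)),
            class = "train_config")
}

# deterministic visit orders for every epoch, shared by both training domains
epoch_orders <- function(cfg, n_samples) {
  if (cfg$order == "sequential")
    return(lapply(seq_len(cfg$iteration_max), function(e) seq_len(n_samples)))
  with_local_seed(cfg$seed + 1L,
    lapply(seq_len(cfg$iteration_max), function(e) sample.int(n_samples)))
}

# random not-all-zero integer initialization, as the hospital would draw it
random_init_w <- function(d, seed) {
  with_local_seed(seed, {
    repeat {
      w <- sample(-5:5, d, replace = TRUE)
      if (any(w != 0L)) return(w)
    }
  })
}

augment_bias <- function(xi, scale_exp) cbind(xi, 10^scale_exp)

#' Train a perceptron on plaintext integers
#'
#' The exact integer-arithmetic reference: per visited sample, if
#' \code{sign_fn(w . x) != O} then \code{w <- w + eta * O * x}. Training
#' stops at the first update-free epoch (convergence) or after
#' \code{iteration_max} epochs.
#'
#' @param samples a [clinical_samples()] object (one disease).
#' @param cfg a [train_config()].
#' @param init_w optional integer initial weights (length \code{d}, plus one
#'   if \code{cfg$bias}); drawn randomly from \code{cfg$seed} when omitted.
#' @param record_epochs keep the weight vector after every epoch
#'   (list \code{epoch_w} on the result).
#' @return a model: list with \code{w} (integer weights), \code{disease_index},
#'   \code{scale_exp} (weights live at the feature scale), \code{trained_epochs},
#'   \code{converged}, \code{updates}, \code{init_w} and optionally
#'   \code{epoch_w}.
#' @export
train_plain <- function(samples, cfg = train_config(), init_w = NULL,
                        record_epochs = FALSE) {
  stopifnot(inherits(samples, "clinical_samples"))
  xi <- int_features(samples)
  if (cfg$bias) xi <- augment_bias(xi, samples$scale_exp)
  d <- ncol(xi)
  if (is.null(init_w)) init_w <- random_init_w(d, cfg$seed)
  if (length(init_w) != d) stop("init_w has wrong length")
  w <- as.numeric(init_w)
  orders <- epoch_orders(cfg, nrow(xi))
  epoch_w <- if (record_epochs) vector("list", cfg$iteration_max) else NULL
  converged <- FALSE
  total_updates <- 0L
  epochs <- 0L
  for (e in seq_len(cfg$iteration_max)) {
    epochs <- e
    updates <- 0L
    for (i in orders[[e]]) {
      z <- sum(w * xi[i, ])
      if (sign_fn(z) != samples$y[i]) {
        w <- w + cfg$eta * samples$y[i] * xi[i, ]
        updates <- updates + 1L
      }
    }
    total_updates <- total_updates + updates
    if (record_epochs) epoch_w[[e]] <- w
    if (updates == 0L) { converged <- TRUE; break }
  }
  out <- list(w = w, disease_index = samples$disease_index[1],
              scale_exp = samples$scale_exp, trained_epochs = epochs,
              converged = converged, updates = total_updates,
              init_w = init_w)
  if (record_epochs) out$epoch_w <- epoch_w[seq_len(epochs)]
  out
}

# hard range guard: a plaintext wraparound past n/2 would silently corrupt
# signs, so bound d * max|w| * max|x| before each epoch using the worst-case
# weight growth (updates so far) rather than the secret weights themselves
check_range_guard <- function(d, max_abs_x, max_abs_w0, updates, eta, n) {
  bound_w <- max_abs_w0 + updates * eta * max_abs_x
  if (log2(d) + log2(max(bound_w, 1)) + log2(max(max_abs_x, 1)) >=
      bn_nbits(n) - 1)
    stop("range guard: accumulated weights may wrap around n/2; ",
         "use a larger key")
}

#' Privacy-preserving perceptron training
#'
#' Executes the mistake-driven rule with the Cloud holding only ciphertexts.
#' The Hospital draws the initial weights, encrypts them once, and sends
#' \code{Cw} to the Cloud, which keeps custody of the encrypted model. Per
#' visited sample the Cloud obtains \code{R = E(x_i . w)} through the
#' one-round secure inner product, the Hospital decrypts \code{R} and returns
#' only the sign \code{S}, and on a mismatch the Cloud updates every
#' coordinate homomorphically: exponent \code{eta} when \code{O_i = +1},
#' exponent \code{n - eta} (the additive inverse) when \code{O_i = -1}, so
#' that \code{Cw_j <- Cw_j * Cx_{i,j}^exp} decrypts to
#' \code{w_j + eta * O_i * x_{i,j}} exactly.
#'
#' @param cloud [mpc_party()] holding the encrypted samples (no private key).
#' @param hospital [mpc_party()] holding the key pair.
#' @param enc an \code{encrypted_samples} object (one disease) under the
#'   hospital's key.
#' @param cfg a [train_config()].
#' @param init_w optional explicit integer initial weights (otherwise the
#'   hospital draws them from its own RNG stream).
#' @param snapshot keep a copy of the encrypted weight vector after every
#'   epoch (decryptable by the key holder for audits).
#' @param transcript optional [new_transcript()] accumulating all messages.
#' @return list with \code{model} (fields \code{w_cipher}, \code{disease_index},
#'   \code{scale_exp}, \code{trained_epochs}, \code{converged},
#'   \code{updates}), \code{init_w}, \code{transcript}, and optionally
#'   \code{epoch_cw}.
#' @export
train_encrypted <- function(cloud, hospital, enc, cfg = train_config(),
                            init_w = NULL, snapshot = FALSE,
                            transcript = NULL) {
  stopifnot(inherits(enc, "encrypted_samples"))
  pk <- hospital$pub
  if (is.null(pk) || is.null(hospital$priv))
    stop("hospital must hold the Paillier key pair")
  if (!identical(key_id_of(enc$n), pk$key_id))
    stop("encrypted dataset is not under the hospital's key")
  if (is.null(transcript)) transcript <- new_transcript()
  d_data <- enc$d
  d <- if (cfg$bias) d_data + 1L else d_data
  cx <- enc$cx
  if (cfg$bias) {
    one <- encode_signed_int(10^enc$scale_exp, pk$n)
    cx <- lapply(cx, function(row) c(row, list(paillier_encrypt(pk, one))))
  }

  # Hospital: draw and encrypt the initial weights, upload once
  if (is.null(init_w)) init_w <- random_init_w(d, hospital$seed)
  if (length(init_w) != d) stop("init_w has wrong length")
  cw <- as_party_step(transcript, hospital, {
    lapply(init_w, function(wj)
      paillier_encrypt(pk, encode_signed_int(wj, pk$n)))
  })
  record_message(transcript, hospital$name, cloud$name, "train.init_w", cw)

  orders <- epoch_orders(cfg, length(cx))
  max_x <- max(enc$max_abs, if (cfg$bias) 10^enc$scale_exp else 1)
  max_w0 <- max(abs(init_w), 1)
  epoch_cw <- if (snapshot) vector("list", cfg$iteration_max) else NULL
  converged <- FALSE
  total_updates <- 0L
  epochs <- 0L
  for (e in seq_len(cfg$iteration_max)) {
    check_range_guard(d, max_x, max_w0, total_updates, cfg$eta, pk$n)
    epochs <- e
    updates <- 0L
    for (i in orders[[e]]) {
      R <- lsm_inner_product(cloud, hospital, cx[[i]], cw,
                             transcript = transcript)
      record_message(transcript, cloud$name, hospital$name, "train.score", list(R))
      S <- as_party_step(transcript, hospital, {
        z <- signed_value(paillier_decrypt(hospital$priv, pk, R), pk$n)
        if (is.character(z)) stop("decrypted score exceeds double range")
        sign_fn(z)
      })
      record_message(transcript, hospital$name, cloud$name, "train.sign",
                     list(as_bn(max(S, 0))))  # sign bit travels in plaintext
      if (S != enc$y[i]) {
        cw <- as_party_step(transcript, cloud, {
          ex <- if (enc$y[i] == 1L) as_bn(cfg$eta)
                else bn_sub(pk$n, as_bn(cfg$eta))
          lapply(seq_len(d), function(j)
            hom_add(pk, cw[[j]], hom_scalar(pk, cx[[i]][[j]], ex)))
        })
        updates <- updates + 1L
      }
    }
    total_updates <- total_updates + updates
    if (snapshot) epoch_cw[[e]] <- cw
    if (updates == 0L) { converged <- TRUE; break }
  }
  model <- structure(
    list(w_cipher = cw, disease_index = enc$disease_index[1],
         scale_exp = enc$scale_exp, trained_epochs = epochs,
         converged = converged, updates = total_updates),
    class = "encrypted_model")
  out <- list(model = model, init_w = init_w, transcript = transcript)
  if (snapshot) out$epoch_cw <- epoch_cw[seq_len(epochs)]
  out
}

#' Decrypt an encrypted model's weights
#'
#' @param model an \code{encrypted_model}.
#' @param sk,pk the hospital key pair.
#' @return the signed integer weight vector.
#' @export
decrypt_model <- function(model, sk, pk) {
  vapply(model$w_cipher, function(ct)
    signed_value(paillier_decrypt(sk, pk, ct), pk$n), 0)
}

#' Train one model per disease
#'
#' Partitions the encrypted dataset by disease index and trains an
#' independent encrypted-domain model for each requested disease.
#'
#' @inheritParams train_encrypted
#' @param disease_indices integer vector of disease indices to train; an
#'   index with no samples is skipped with a warning.
#' @return named list of [train_encrypted()] results, one per disease index.
#' @export
train_all_diseases <- function(cloud, hospital, enc, disease_indices = NULL,
                               cfg = train_config(), transcript = NULL) {
  if (is.null(disease_indices)) disease_indices <- unique(enc$disease_index)
  out <- list()
  for (k in disease_indices) {
    idx <- which(enc$disease_index == k)
    if (length(idx) == 0L) {
      warning("disease index ", k, " has no samples; skipped")
      next
    }
    sub <- enc
    sub$cx <- enc$cx[idx]
    sub$y <- enc$y[idx]
    sub$disease_index <- enc$disease_index[idx]
    out[[as.character(k)]] <-
      train_encrypted(cloud, hospital, sub, cfg, transcript = transcript)
  }
  out
}

#' Model files
#'
#' JSON with the disease index, the weights (signed integers for a plaintext
#' model, hex ciphertexts for an encrypted one), the weight scale, the epoch
#' count, and the convergence flag.
#'
#' @param model a plaintext model from [train_plain()] or an
#'   \code{encrypted_model}.
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "encrypted_model")) {
    jsonlite::write_json(
      list(type = "encrypted",
           disease_index = model$disease_index,
           weights = vapply(model$w_cipher, function(ct) ct$value, ""),
           key_id = model$w_cipher[[1]]$key_id,
           scale_exp = model$scale_exp,
           trained_epochs = model$trained_epochs,
           converged = model$converged),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(
      list(type = "plain",
           disease_index = model$disease_index,
           weights = model$w,
           scale_exp = model$scale_exp,
           trained_epochs = model$trained_epochs,
           converged = model$converged),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(j$type, "encrypted")) {
    structure(list(
      w_cipher = lapply(as.character(j$weights), new_ciphertext,
                        key_id = j$key_id),
      disease_index = j$disease_index, scale_exp = j$scale_exp,
      trained_epochs = j$trained_epochs, converged = j$converged),
      class = "encrypted_model")
  } else {
    list(w = as.numeric(j$weights), disease_index = j$disease_index,
         scale_exp = j$scale_exp, trained_epochs = j$trained_epochs,
         converged = j$converged)
  }
}
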