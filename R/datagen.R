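# Synthetic clinical datasets with a planted linear separator, plus CSV and
# encrypted-JSONL readers/writers. The generator emulates the structure of
# small-integer clinical benchmarks (attributes in [1, 10], 6-13 dimensions,
# two classes) so that the perceptron convergence guarantee gives crisp,
# testable behaviour on noise-free draws.

#' Labelled clinical samples
#'
#' A light container for a tabular dataset: an \code{n x d} numeric attribute
#' matrix, labels in \code{{-1, +1}}, a disease index per sample, and the
#' fixed-point scale at which attributes are to be encoded (0 for
#' integer-valued attributes).
#'
#' @param x numeric matrix, samples in rows.
#' @param y integer labels in \code{{-1, +1}}.
#' @param disease_index integer vector (recycled) tagging each sample's disease.
#' @param scale_exp fixed-point scale for encoding; attributes are multiplied
#'   by \code{10^scale_exp} and rounded when entering the integer pipeline.
#' @return an object of class \code{clinical_samples}.
#' @export
clinical_samples <- function(x, y, disease_index = 1L, scale_exp = 0L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (nrow(x) == 0L) stop("empty dataset")
  if (length(y) != nrow(x)) stop("label length does not match sample count")
  if (!all(y %in% c(-1L, 1L))) stop("labels must be in {-1, +1}")
  disease_index <- as.integer(rep_len(disease_index, nrow(x)))
  structure(list(x = x, y = y, disease_index = disease_index,
                 scale_exp = as.integer(scale_exp)),
            class = "clinical_samples")
}

#' @export
print.clinical_samples <- function(x, ...) {
  cat("clinical_samples:", nrow(x$x), "samples x", ncol(x$x), "attributes;",
      sum(x$y == 1L), "positive /", sum(x$y == -1L), "negative; scale 10^",
      x$scale_exp, "\n", sep = " ")
  invisible(x)
}

# integer feature matrix at the working scale
int_features <- function(samples) {
  m <- round(samples$x * 10^samples$scale_exp)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Specify a synthetic clinical dataset
#'
#' Samples are drawn with uniform integer attributes in \code{attr_range};
#' a planted integer weight vector \code{w*} labels each sample by
#' \code{sign(w* . x - threshold)}, draws with \code{|w* . x - threshold| <
#' margin} are rejected, and labels are then flipped independently with
#' probability \code{label_noise}. With \code{threshold = 0} (the default)
#' the separator passes through the origin, so a bias-free perceptron is
#' guaranteed to converge on noise-free draws. The train:test split (default
#' 7:3) is performed after shuffling with the spec seed.
#'
#' @param n_samples total number of samples (>= 2).
#' @param d number of attributes (>= 1).
#' @param attr_range inclusive integer attribute bounds, default \code{c(1, 10)}.
#' @param margin planted separation margin in raw score units (> 0 for
#'   guaranteed separability). The default 8 is set from the perceptron
#'   mistake bound \code{(R ||w*|| / margin)^2} (with attribute radius
#'   \code{R <= sqrt(d) * 10} and planted \code{||w*|| <= 3 sqrt(d)} at the
#'   default shapes this is about 1.1e3 updates), so that convergence is
#'   guaranteed well within the default 100-epoch cap; a margin of 1 keeps
#'   the classes separable but gives no such guarantee.
#' @param label_noise probability of flipping a label.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @param split_ratio two nonnegative weights, train:test.
#' @param threshold intercept of the planted separator (default 0).
#' @param balance optional positive-class fraction; when set, sampling fills
#'   per-class quotas by rejection.
#' @return an object of class \code{synth_spec}.
#' @export
synth_spec <- function(n_samples = 100L, d = 9L, attr_range = c(1L, 10L),
                       margin = 8, label_noise = 0, seed = 1L,
                       split_ratio = c(7, 3), threshold = 0, balance = NULL) {
  stopifnot(n_samples >= 2, d >= 1, length(attr_range) == 2,
            attr_range[1] <= attr_range[2], margin >= 0,
            label_noise >= 0, label_noise <= 1, length(split_ratio) == 2,
            all(split_ratio >= 0), sum(split_ratio) > 0)
  if (!is.null(balance)) stopifnot(balance > 0, balance < 1)
  structure(list(n_samples = as.integer(n_samples), d = as.integer(d),
                 attr_range = as.integer(attr_range), margin = margin,
                 label_noise = label_noise, seed = as.integer(seed),
                 split_ratio = split_ratio, threshold = threshold,
                 balance = balance),
            class = "synth_spec")
}

#' Generate a synthetic clinical dataset
#'
#' @param spec a [synth_spec()].
#' @param max_tries rejection budget per accepted sample.
#' @return a list with \code{train} and \code{test}
#'   (\code{clinical_samples}), the planted integer weight vector
#'   \code{planted_w}, and \code{threshold}.
#' @export
generate_samples <- function(spec, max_tries = 2000L) {
  stopifnot(inherits(spec, "synth_spec"))
  with_local_seed(spec$seed, {
    d <- spec$d
    # planted integer separator; near-zero entry sum keeps the two classes
    # roughly balanced when the separator passes through the origin
    repeat {
      w <- sample(c(-3:-1, 1:3), d, replace = TRUE)
      if (spec$threshold != 0 || abs(sum(w)) <= 1 || d == 1L) break
    }
    lo <- spec$attr_range[1]; hi <- spec$attr_range[2]
    quota_pos <- if (is.null(spec$balance)) NA_integer_
                 else as.integer(ceiling(spec$n_samples * spec$balance))
    xs <- matrix(0, spec$n_samples, d)
    ys <- integer(spec$n_samples)
    n_pos <- 0L; accepted <- 0L; tries <- 0L
    budget <- max_tries * spec$n_samples
    while (accepted < spec$n_samples) {
      tries <- tries + 1L
      if (tries > budget)
        stop("rejection budget exhausted: the margin/balance combination is ",
             "infeasible for this attribute range; reduce margin")
      x <- sample(lo:hi, d, replace = TRUE)
      score <- sum(w * x) - spec$threshold
      if (abs(score) < spec$margin) next
      lab <- sign_fn(score)
      if (!is.na(quota_pos)) {
        want_pos <- n_pos < quota_pos
        if ((lab == 1L) != want_pos) next
      }
      if (spec$label_noise > 0 && stats::runif(1) < spec$label_noise)
        lab <- -lab
      accepted <- accepted + 1L
      xs[accepted, ] <- x
      ys[accepted] <- lab
      if (lab == 1L) n_pos <- n_pos + 1L
    }
    if (length(unique(ys)) < 2L)
      stop("degenerate draw: only one class realized; change seed or margin")
    perm <- sample.int(spec$n_samples)
    xs <- xs[perm, , drop = FALSE]; ys <- ys[perm]
    n_train <- max(1L, round(spec$n_samples *
                               spec$split_ratio[1] / sum(spec$split_ratio)))
    n_train <- min(n_train, spec$n_samples - 1L)
    idx_tr <- seq_len(n_train)
    list(train = clinical_samples(xs[idx_tr, , drop = FALSE], ys[idx_tr]),
         test = clinical_samples(xs[-idx_tr, , drop = FALSE], ys[-idx_tr]),
         planted_w = w, threshold = spec$threshold)
  })
}

#' Read and write clinical samples as CSV
#'
#' Plain RFC-4180-style CSV with a header row; attribute columns are numeric
#' and the label column holds \code{-1}/\code{+1} (or \code{0}/\code{1} with
#' \code{map01 = TRUE}, as in some public benchmark encodings).
#'
#' @param samples a [clinical_samples()] object.
#' @param path file path.
#' @param label_col name of the label column (default \code{"label"}).
#' @param map01 map labels \code{{0, 1}} to \code{{-1, +1}} on read.
#' @param scale_exp fixed-point scale recorded on the returned object.
#' @return \code{read_samples_csv}: a \code{clinical_samples} object.
#' @export
write_samples_csv <- function(samples, path, label_col = "label") {
  df <- as.data.frame(samples$x)
  if (is.null(colnames(samples$x)))
    colnames(df) <- paste0("attr", seq_len(ncol(samples$x)))
  df[[label_col]] <- samples$y
  df$disease_index <- samples$disease_index
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples_csv
#' @export
read_samples_csv <- function(path, label_col = "label", map01 = FALSE,
                             scale_exp = 0L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!label_col %in% names(df))
    stop("missing label column '", label_col, "' in ", path)
  di <- if ("disease_index" %in% names(df)) df$disease_index else 1L
  df_attr <- df[setdiff(names(df), c(label_col, "disease_index"))]
  for (cn in names(df_attr)) {
    v <- suppressWarnings(as.numeric(df_attr[[cn]]))
    bad <- which(is.na(v) & !is.na(df_attr[[cn]]))
    if (length(bad) || anyNA(v))
      stop("non-numeric attribute value in column '", cn, "', row ",
           if (length(bad)) bad[1] else which(is.na(v))[1])
    df_attr[[cn]] <- v
  }
  y <- suppressWarnings(as.numeric(df[[label_col]]))
  if (anyNA(y)) stop("non-numeric label, row ", which(is.na(y))[1])
  if (map01) {
    if (!all(y %in% c(0, 1)))
      stop("labels must be in {0, 1} when map01 = TRUE; offending row ",
           which(!y %in% c(0, 1))[1])
    y <- ifelse(y == 1, 1L, -1L)
  }
  if (!all(y %in% c(-1, 1)))
    stop("invalid label '", y[which(!y %in% c(-1, 1))[1]], "' in row ",
         which(!y %in% c(-1, 1))[1], ": labels must be -1 or +1")
  clinical_samples(as.matrix(df_attr), as.integer(y), di, scale_exp)
}

#' Encrypt a dataset for cloud storage
#'
#' Encodes every attribute at the dataset's fixed-point scale and encrypts it
#' under the hospital's public key; labels and disease indices stay in
#' plaintext (the scheme accepts this leakage by design -- the label alone
#' does not identify the patient's attribute values). The layout mirrors the
#' cloud's per-disease table: one record per sample holding the ciphertext
#' vector, the plaintext label, and the disease index.
#'
#' @param samples a [clinical_samples()] object.
#' @param pk hospital \code{paillier_pubkey}.
#' @param scale_exp override of the dataset's scale.
#' @return an object of class \code{encrypted_samples}: list with \code{cx}
#'   (list of ciphertext lists), \code{y}, \code{disease_index}, \code{d},
#'   \code{n}, \code{g}, \code{scale_exp}, \code{max_abs} (largest encoded
#'   magnitude, metadata for the range guard).
#' @export
encrypt_samples <- function(samples, pk, scale_exp = samples$scale_exp) {
  xi <- round(samples$x * 10^scale_exp)
  max_abs <- max(abs(xi), 1)
  # overflow guard: every encoded magnitude must stay below n/2
  if (log2(max_abs) + 1 >= bn_nbits(pk$n) - 1)
    stop("attribute magnitudes overflow the plaintext range; use a larger key")
  cx <- lapply(seq_len(nrow(xi)), function(i)
    lapply(seq_len(ncol(xi)), function(j)
      paillier_encrypt(pk, encode_signed_int(xi[i, j], pk$n))))
  structure(list(cx = cx, y = samples$y, disease_index = samples$disease_index,
                 d = ncol(xi), n = pk$n, g = pk$g,
                 scale_exp = as.integer(scale_exp), max_abs = max_abs),
            class = "encrypted_samples")
}

#' @export
print.encrypted_samples <- function(x, ...) {
  cat("encrypted_samples:", length(x$cx), "samples x", x$d,
      "ciphertexts under key", key_id_of(x$n), "\n")
  invisible(x)
}

#' Decrypt an encrypted dataset
#'
#' Inverse of [encrypt_samples()]; used for round-trip verification.
#'
#' @param enc an \code{encrypted_samples} object.
#' @param sk,pk the hospital key pair.
#' @return a [clinical_samples()] object (attributes at the original scale).
#' @export
decrypt_samples <- function(enc, sk, pk) {
  xs <- matrix(0, length(enc$cx), enc$d)
  for (i in seq_along(enc$cx))
    xs[i, ] <- vapply(enc$cx[[i]], function(ct)
      signed_value(paillier_decrypt(sk, pk, ct), pk$n), 0)
  clinical_samples(xs / 10^enc$scale_exp, enc$y, enc$disease_index,
                   enc$scale_exp)
}

#' Encrypted dataset files (JSON lines)
#'
#' First line is a header \code{{n, g, scale_exp, d}}; each following line is
#' one sample \code{{disease_index, label, ciphertexts: [hex, ...]}}.
#'
#' @param enc an \code{encrypted_samples} object.
#' @param path file path.
#' @export
write_encrypted_dataset <- function(enc, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(
    list(n = enc$n, g = enc$g, scale_exp = enc$scale_exp, d = enc$d,
         max_abs = enc$max_abs), auto_unbox = TRUE), con)
  for (i in seq_along(enc$cx)) {
    writeLines(jsonlite::toJSON(
      list(disease_index = enc$disease_index[i], label = enc$y[i],
           ciphertexts = vapply(enc$cx[[i]], function(ct) ct$value, "")),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_encrypted_dataset
#' @export
read_encrypted_dataset <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty encrypted dataset file")
  hdr <- jsonlite::fromJSON(lines[1])
  kid <- key_id_of(as_bn(hdr$n))
  rows <- lapply(lines[-1], jsonlite::fromJSON)
  cx <- lapply(rows, function(r)
    lapply(as.character(r$ciphertexts), new_ciphertext, key_id = kid))
  structure(list(cx = cx,
                 y = vapply(rows, function(r) as.integer(r$label), 0L),
                 disease_index = vapply(rows, function(r)
                   as.integer(r$disease_index), 0L),
                 d = as.integer(hdr$d), n = as_bn(hdr$n), g = as_bn(hdr$g),
                 scale_exp = as.integer(hdr$scale_exp),
                 max_abs = as.numeric(hdr$max_abs)),
            class = "encrypted_samples")
}
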