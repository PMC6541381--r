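# Two-party computation plumbing: parties with private seeded RNG streams,
# an in-process message channel, and transcripts that record every message
# together with per-party ciphertext-operation counters (EXP = ciphertext
# exponentiation, MUL = multiplication mod n^2, DIV = the modular inverse
# consumed by a decryption).

.mpc <- new.env(parent = emptyenv())
.mpc$transcript <- NULL
.mpc$party <- NULL

ledger_tick <- function(op, k = 1L) {
  t <- .mpc$transcript
  if (is.null(t) || is.null(.mpc$party)) return(invisible(NULL))
  cnt <- t$counters[[.mpc$party]]
  if (is.null(cnt)) cnt <- c(EXP = 0L, MUL = 0L, DIV = 0L)
  cnt[[op]] <- cnt[[op]] + k
  t$counters[[.mpc$party]] <- cnt
  invisible(NULL)
}

# run expr with `party` charged for ciphertext ops on transcript `t`,
# under the party's own RNG stream
as_party_step <- function(t, party, expr) {
  old_t <- .mpc$transcript; old_p <- .mpc$party
  .mpc$transcript <- t; .mpc$party <- party$name
  on.exit({ .mpc$transcript <- old_t; .mpc$party <- old_p }, add = TRUE)
  with_party_rng(party, expr)
}

with_party_rng <- function(party, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  if (!is.null(party$rng_state)) {
    assign(".Random.seed", party$rng_state, envir = globalenv())
  } else {
    set.seed(party$seed)
  }
  on.exit({
    party$rng_state <- get(".Random.seed", globalenv(), inherits = FALSE)
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  force(expr)
}

#' Create a protocol party
#'
#' A party is a mutable environment holding a role label (e.g. \code{"Cloud"},
#' \code{"Hospital"}, \code{"UP"}), the public keys it knows, optionally a
#' private key, and its own seeded RNG stream. Parties exchange data only
#' through transcript messages; no protocol in the package reads another
#' party's fields directly.
#'
#' @param name role label.
#' @param pub a \code{paillier_pubkey} the party operates under (may be NULL).
#' @param priv a \code{paillier_privkey} if this party holds one.
#' @param seed integer seed for the party's private randomness.
#' @return an environment of class \code{mpc_party}.
#' @export
mpc_party <- function(name, pub = NULL, priv = NULL, seed = 1L) {
  e <- new.env(parent = emptyenv())
  e$name <- name
  e$pub <- pub
  e$priv <- priv
  e$seed <- seed
  e$rng_state <- NULL
  class(e) <- "mpc_party"
  e
}

#' @export
print.mpc_party <- function(x, ...) {
  cat("mpc_party <", x$name, "> holds:",
      if (!is.null(x$pub)) "public key" else "",
      if (!is.null(x$priv)) "+ private key" else "", "\n")
  invisible(x)
}

#' Protocol transcripts
#'
#' \code{new_transcript()} creates an empty transcript; protocols append
#' messages (sender, receiver, step tag, payload of hex residues) and tick the
#' per-party EXP/MUL/DIV counters as they run. \code{transcript_rounds()}
#' counts request/response exchanges: consecutive messages in the same
#' direction form one flight, and one round is a flight plus its returning
#' flight. \code{op_counts()} returns a party's counter vector.
#'
#' @return \code{new_transcript}: an environment of class
#'   \code{mpc_transcript} with fields \code{messages} and \code{counters}.
#' @export
new_transcript <- function() {
  t <- new.env(parent = emptyenv())
  t$messages <- list()
  t$counters <- list()
  class(t) <- "mpc_transcript"
  t
}

record_message <- function(t, sender, receiver, tag, payload) {
  if (is.null(t)) return(invisible(NULL))
  t$messages[[length(t$messages) + 1L]] <-
    list(sender = sender, receiver = receiver, tag = tag, payload = payload)
  invisible(NULL)
}

#' @rdname new_transcript
#' @param t an \code{mpc_transcript}.
#' @export
transcript_rounds <- function(t) {
  if (length(t$messages) == 0L) return(0L)
  dirs <- vapply(t$messages, function(m) paste0(m$sender, ">", m$receiver), "")
  flights <- rle(dirs)$lengths
  length(flights) %/% 2L
}

#' @rdname new_transcript
#' @param party role label whose counters to return.
#' @export
op_counts <- function(t, party) {
  if (length(t$counters) == 0L && length(t$messages) == 0L &&
      !party %in% names(t$counters))
    return(c(EXP = 0L, MUL = 0L, DIV = 0L))
  if (!party %in% names(t$counters)) {
    known <- unique(unlist(lapply(t$messages, function(m) c(m$sender, m$receiver))))
    if (!party %in% known) stop("unknown party: ", party)
    return(c(EXP = 0L, MUL = 0L, DIV = 0L))
  }
  t$counters[[party]]
}

#' @export
print.mpc_transcript <- function(x, ...) {
  cat("mpc_transcript:", length(x$messages), "messages,",
      transcript_rounds(x), "rounds\n")
  for (p in names(x$counters)) {
    cnt <- x$counters[[p]]
    cat("  ", p, ": EXP=", cnt[["EXP"]], " MUL=", cnt[["MUL"]],
        " DIV=", cnt[["DIV"]], "\n", sep = "")
  }
  invisible(x)
}

#' Run a protocol and capture its transcript
#'
#' A protocol object is a list with elements \code{name} and \code{fn}; the
#' function receives the party list, a fresh transcript, and any extra
#' arguments, and returns the protocol output. Runs are deterministic under
#' fixed party seeds.
#'
#' @param protocol list(name =, fn =).
#' @param parties named list of [mpc_party()] objects as expected by the
#'   protocol function.
#' @param ... forwarded to \code{protocol$fn}.
#' @return list(result =, transcript =).
#' @export
run_protocol <- function(protocol, parties, ...) {
  stopifnot(is.list(protocol), is.function(protocol$fn))
  t <- new_transcript()
  res <- protocol$fn(parties, t, ...)
  list(result = res, transcript = t)
}

#' Export a transcript as JSON lines
#'
#' One message per line with hex-encoded payload entries, followed by a final
#' summary line holding the counters and round count.
#'
#' @param t an \code{mpc_transcript}.
#' @param path output file.
#' @export
write_transcript_jsonl <- function(t, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in t$messages) {
    payload <- lapply(m$payload, function(x) {
      if (is_ciphertext(x)) list(ciphertext = x$value) else list(residue = x)
    })
    writeLines(jsonlite::toJSON(
      list(sender = m$sender, receiver = m$receiver, tag = m$tag,
           payload = payload), auto_unbox = TRUE), con)
  }
  writeLines(jsonlite::toJSON(
    list(summary = list(rounds = transcript_rounds(t), counters = t$counters)),
    auto_unbox = TRUE), con)
  invisible(NULL)
}
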