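Package: secureSLP
Title: Privacy-Preserving Perceptron Training over Paillier Ciphertexts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-party privacy-preserving clinical risk classification with an
    additively homomorphic cryptosystem. Implements the Paillier cryptosystem
    over OpenSSL big-number arithmetic, signed fixed-point encoding of clinical
    attributes into the plaintext residue ring, secure multiplication and a
    one-round secure inner-product protocol between a cloud server holding
    ciphertexts and a hospital holding the private key, encrypted-domain
    single-layer perceptron training that exactly tracks its plaintext
    counterpart, plaintext-side disease prediction returned encrypted to the
    patient, and a synthetic clinical-dataset generator with a planted linear
    separator. Protocol runs are captured in transcripts with message, round
    and ciphertext-operation accounting.
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: OpenSSL (libcrypto) headers and library
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
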