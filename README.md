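# secureSLP

Privacy-preserving clinical risk classification for a hospital that wants to
train and use a linear disease model on patient records **without exposing
them to the cloud that stores them** — and without exposing the model to the
patients who query it.

The package is aimed at researchers in applied cryptography and clinical
machine learning who want a complete, testable reference implementation of
additively-homomorphic perceptron training: every protocol step is exact
integer arithmetic, so the encrypted computation can be checked bit-for-bit
against its plaintext counterpart rather than "approximately reproduced".

## What it implements

* **Paillier cryptosystem** over OpenSSL big-number arithmetic: keygen with
  seeded, reproducible prime generation; encryption `c = g^m · r^n mod n²`;
  the additive identities `D(E(m₁)·E(m₂)) = m₁+m₂ mod n` and
  `D(E(m)^k) = k·m mod n`.
* **Signed fixed-point encoding** of attributes and weights into `Z_n`
  (scale by `10^s`, round, store negatives as `n − |v|`), with a range guard
  against sign wraparound.
* **Secure multiplication (SM)** and a **one-round secure inner product
  (LSM)** between a cloud `C1` holding ciphertext vectors and a hospital
  `C2` holding the private key: `C1` additively blinds all `2d` coordinates
  and sends one flight; `C2` decrypts masked values only and returns a
  single `H = E(Σ(xⱼ+r_xⱼ)(wⱼ+r_wⱼ))`; `C1` cancels the masks with
  aggregated correction terms `T₁ = Π E(r_xⱼ r_wⱼ)^{n−1}`,
  `T₂ = Π E(xⱼ)^{n−r_wⱼ}`, `T₃ = Π E(wⱼ)^{n−r_xⱼ}`, so
  `R = H·T₁·T₂·T₃ = E(Σ xⱼwⱼ)` exactly.
* **Encrypted-domain perceptron training**: mistake-driven rule
  `w ← w + η·O·x` executed on ciphertexts (`Cwⱼ ← Cwⱼ · Cx_{i,j}^{η}` or
  `^{n−η}`), with the hospital contributing only sign bits of decrypted
  blinded scores. Decrypted encrypted-domain weights equal the plaintext
  perceptron's weights element-wise after every epoch.
* **Prediction**: the patient submits symptoms encrypted under the
  hospital's key; the hospital scores with its plaintext model and returns
  the class encrypted under the patient's key.
* **Synthetic clinical datasets** with a planted integer separator
  (attributes in `[1,10]`, configurable dimension, margin, label noise,
  class balance, 7:3 split), protocol **transcripts** with round and
  EXP/MUL/DIV operation accounting, JSON/JSONL/CSV readers and writers, and
  a `secureslp` command-line wrapper
  (`keygen | simulate-data | encrypt | train | predict | benchmark`).

## Worked example

```r
library(secureSLP)

keys <- paillier_keygen(bits = 256, seed = 42)   # 256-bit primes: test scale
ds   <- generate_samples(synth_spec(n_samples = 100, d = 9, seed = 7))
enc  <- encrypt_samples(ds$train, keys$pub)

cloud    <- mpc_party("Cloud",    pub = keys$pub, seed = 1)
hospital <- mpc_party("Hospital", pub = keys$pub, priv = keys$priv, seed = 2)

fit  <- train_encrypted(cloud, hospital, enc,
                        train_config(eta = 1, iteration_max = 100, seed = 7))
w_ed <- decrypt_model(fit$model, keys$priv, keys$pub)
ref  <- train_plain(ds$train, train_config(eta = 1, iteration_max = 100, seed = 7),
                    init_w = fit$init_w)

# the patient queries the trained model
up  <- paillier_keygen(bits = 256, seed = 99)
res <- predict_disease(hospital,
                       list(w = w_ed, disease_index = 1L, scale_exp = 0L),
                       encrypt_symptoms(ds$test$x[1, ], keys$pub), up$pub)
decode_prediction(res, up$priv, up$pub)
```

This prints (abridged):

```
epochs: 3  converged: TRUE  updates: 21
decrypted cloud-trained weights:  12 28 19 -31 -5 5 20 -18 -18
plaintext perceptron weights:     12 28 19 -31 -5 5 20 -18 -18
identical: TRUE
prediction_result: disease 1 -> positive (+1) (result ciphertext under patient key b98d5882cb721533)
patient decodes: 1   true label: 1
held-out accuracy: 100 %
```

The weights the cloud computed *without ever seeing a plaintext attribute*
are identical to the classical perceptron's — that exact agreement, not
merely similar accuracy, is the package's central invariant. The held-out
accuracy is 100% here because the synthetic data are separable by
construction; see the vignette for what that does and does not demonstrate.

The same pipeline from a shell:

```sh
secureslp keygen --bits 256 --seed 42
secureslp simulate-data --n 100 --d 9 --seed 7
secureslp encrypt --in train.csv --enc-out enc.jsonl
secureslp train --in enc.jsonl --seed 7 --model model.json
secureslp predict --in test.csv --model model.json
```

## Further reading

The methods vignette (`vignettes/secure-perceptron.Rmd`) documents the
model and its assumptions, the encoding and protocol algebra, the range
guard, the synthetic-data design (including why the planted margin defaults
to 8), and the scheme's accepted leakages and limitations.
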