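---
title: "Privacy-preserving perceptron training over Paillier ciphertexts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving perceptron training over Paillier ciphertexts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secureSLP)
```

## The problem

A hospital wants a linear classifier for disease risk trained on patient
records it does not want to expose, using storage and compute rented from a
cloud provider it does not fully trust. secureSLP implements a two-party
scheme in which

* **diagnosed patients** encrypt their attribute vectors under the hospital's
  public key and upload them, with plaintext class labels, to the **cloud**;
* the **cloud** trains a single-layer perceptron while seeing only
  ciphertexts of attributes and weights;
* the **hospital**, which holds the private key, participates in training
  only through a narrow interface: it decrypts *blinded* intermediate values
  and returns single sign bits;
* an **undiagnosed patient** later submits encrypted symptoms and receives a
  diagnosis that only they can decrypt.

The cloud never learns an attribute or weight value; the hospital never sees
an unmasked training record; the patient learns nothing but their own result.
All parties are assumed honest-but-curious (they follow the protocol).

## The cryptosystem

The arithmetic substrate is the Paillier cryptosystem: plaintexts live in
$\mathbb{Z}_n$ for an RSA-type modulus $n = pq$, ciphertexts in
$\mathbb{Z}^*_{n^2}$, and encryption is

$$c = g^m \cdot r^n \bmod n^2,$$

with a fresh uniform blinding $r$ coprime to $n$ drawn per encryption.
(Descriptions of this scheme occasionally misprint the blinding factor as
$r^m$; only $r^n$ is consistent with the decryption equation
$m = L(c^\lambda \bmod n^2)\,\mu \bmod n$ and with the homomorphic
identities, so that is what the package implements.) The two identities that
everything else is built on are exact:

$$D(E(m_1)\cdot E(m_2) \bmod n^2) = m_1 + m_2 \bmod n, \qquad
  D(E(m)^k \bmod n^2) = k\,m \bmod n.$$

Exponentiation by $n - k$ therefore realizes subtraction of $k \cdot m$,
which is how every "remove this masked term" step below works.

Implementation notes:

* Big-integer arithmetic is delegated to OpenSSL's BIGNUM library
  (`libcrypto`), wrapped through Rcpp; values cross the R boundary as hex
  strings. Primality testing uses the library's Miller-Rabin with trial
  division (64 witness rounds, beyond the 40 we require).
* Every random draw — prime candidates, encryption blindings, protocol
  masks, weight initializations — comes from R's own RNG, so any run is
  reproducible from seeds. Key generation with `seed` set is deterministic.
* The generator defaults to $g = n + 1$, which is always valid and makes
  $g^m = 1 + mn \bmod n^2$ a single multiplication; a uniformly random valid
  generator is available (`g = "random"`) for fidelity to the textbook
  description.
* Keys with 256-bit primes (512-bit $n$) are used throughout the tests: fast
  enough for thousands of operations per second, large enough that every
  quantity the pipeline computes stays far from the $n/2$ sign boundary.
  They are *not* a production security level; use $\ge$ 1024-bit primes for
  real deployments.

## Signed fixed-point encoding

Paillier encrypts nonnegative residues only. Clinical attributes and learned
weights are signed and possibly fractional, so values are scaled by
$10^s$ (default $s = 4$), rounded, and embedded symmetrically:
nonnegative $v$ as $v$, negative $v$ as $n - |v|$. Decoding treats residues
above $n/2$ as negative. Consequences:

* the encode/decode round trip is exact to within half an encoding unit
  ($5\times10^{-5}$ at the default scale);
* sums and integer multiples of encodings are exact at the integer level, so
  the perceptron — whose updates are integer multiples of integer attribute
  vectors — runs *without any* approximation once inputs are encoded;
* a product of two scale-$s$ encodings carries scale $2s$. The training
  loop only ever takes the **sign** of an inner product, which is invariant
  to the positive factor $10^{2s}$, so no rescaling protocol is needed;
* magnitudes must stay below $n/2$ or signs become ambiguous. `fp_encode`
  refuses magnitudes of $\lfloor (n-1)/2\rfloor$ or more, and training
  enforces a per-epoch *range guard*: with $d$ attributes, worst-case weight
  magnitude $\max|w_0| + (\text{updates so far})\cdot\eta\cdot\max|x|$, it
  checks $d \cdot \max|w| \cdot \max|x| < n/2$ and aborts with advice to use
  a larger key rather than risk silent wraparound. The guard uses only
  metadata (the dataset's maximum encoded magnitude), never the secret
  weights.

Integer-valued attribute sets (the 1–10 ranges typical of the clinical
benchmarks this package's generator emulates) use scale $s = 0$.

## The secure inner product

The cloud (C1) holds element-wise ciphertext vectors
$E(x_1),\dots,E(x_d)$ and $E(w_1),\dots,E(w_d)$; the hospital (C2) holds the
private key. Classical secure multiplication (`sm_product`) computes one
product per round: C1 additively blinds both factors with secret masks, C2
decrypts the masked factors, returns the encrypted masked product, and C1
strips the three cross terms homomorphically. An inner product assembled
this way costs $d$ rounds.

The one-round protocol (`lsm_inner_product`) aggregates: C1 blinds all $2d$
coordinates and sends them in one flight; C2 decrypts, computes the *single
masked scalar* $h = \sum_j (x_j + r_{x_j})(w_j + r_{w_j}) \bmod n$, and
returns one ciphertext $H = E(h)$; C1 then multiplies in three aggregated
correction terms

$$T_1 = \prod_j E(r_{x_j} r_{w_j})^{\,n-1},\quad
  T_2 = \prod_j E(x_j)^{\,n - r_{w_j}},\quad
  T_3 = \prod_j E(w_j)^{\,n - r_{x_j}},$$

so that $R = H \cdot T_1 \cdot T_2 \cdot T_3 = E(\sum_j x_j w_j)$: every
cross term cancels mod $n$, exactly. The package asserts this against the
plaintext dot product for hundreds of random signed vectors, and asserts the
structural claims directly on transcripts: one round regardless of $d$, and
per-party EXP/MUL counters affine in $d$ (the exact intercepts depend on
op-accounting conventions, so only the affine shape with positive slope is
checked).

Blinding masks are drawn fresh per invocation from $[1, n-1]$; zero is
excluded (a zero mask would hand C2 a true value). What C2 decrypts is
always (true value + mask) mod $n$ — the tests verify this equality for every
message in a transcript, and verify that runs with different mask seeds give
the key holder different views while producing identical protocol outputs.

## Training: encrypted domain $\equiv$ plain domain

The plaintext reference (`train_plain`) is the classical mistake-driven
perceptron over integers: visit samples in order; when
$\mathrm{sign}(w \cdot x_i) \ne O_i$, update $w \leftarrow w + \eta\,O_i\,x_i$;
stop at the first update-free epoch or at `iteration_max` (default 100)
epochs. `sign` maps 0 to $+1$, matching the prediction rule "score $\ge 0$
means the patient has the disease".

The encrypted run (`train_encrypted`) executes the same recursion under
encryption:

1. the hospital draws a random not-all-zero integer weight vector, encrypts
   it, and uploads $Cw$ **once**; the cloud keeps custody of $Cw$ between
   epochs (re-uploading each iteration would discard the cloud's updates);
2. per sample the cloud obtains $R = E(x_i \cdot w)$ via the one-round inner
   product, the hospital decrypts $R$ and returns only
   $S = \mathrm{sign}(\cdot)$;
3. on a mismatch the cloud updates every coordinate homomorphically:
   exponent $\eta$ when $O_i = +1$, exponent $n - \eta$ when $O_i = -1$, so
   $Cw_j \leftarrow Cw_j \cdot Cx_{i,j}^{\text{exp}}$ decrypts to
   $w_j + \eta\,O_i\,x_{i,j}$ exactly.

Because every encrypted update is an exact homomorphic image of the
plaintext update, the decrypted encrypted-domain weights equal the plaintext
weights **element-wise after every epoch**, for any seed, visit order and
$\eta$ — and hence the two final classifiers agree on every input. This is
deliberately stronger than "comparable accuracy": with deterministic
fixed-point encoding there is no approximation step left to disagree on.
The learning rate is restricted to positive integers (default 1): ciphertext
exponents must be integers, and perceptron decisions are invariant under a
joint positive rescaling of $\eta$ and $w$, so nothing is lost.

Labels are stored in plaintext at the cloud, as the scheme prescribes; this
is an accepted leakage of the original design (a label without its attribute
vector identifies no one, but it is a leakage nonetheless). During training
the hospital receives only ciphertexts; its entire view is the sequence of
blinded residues and the inner-product values it decrypts itself.

## Prediction

Prediction is plaintext-side at the hospital by design — the model is the
hospital's asset and never leaves it. The patient encrypts symptoms under
the hospital's key; the hospital decrypts, scores $s = \sum_j x_j w_j$,
classifies ($s \ge 0 \Rightarrow +1$), and returns the outcome encrypted
under the *patient's* key, encoded in the plaintext space as 1 ("suffers")
or 0 ("does not") — the signed label $-1$ would otherwise need the $n-1$
representation. Nothing derived from the symptoms persists at the hospital
after the call returns.

## The synthetic generator

Real clinical benchmarks cannot ship with the package, so the generator
(`synth_spec` / `generate_samples`) emulates their structure: $d$ uniform
integer attributes in $[1, 10]$ (configurable), two classes, 7:3 train:test
split after a seeded shuffle. Labels come from a *planted* integer separator
$w^*$ with entries in $\{\pm1,\pm2,\pm3\}$: $O = \mathrm{sign}(w^* \cdot x -
\theta)$, with draws closer than `margin` to the boundary rejected and
optional independent label flips (`label_noise`).

Design choices that were genuinely open:

* **Planted separator rather than two Gaussians**: separability becomes a
  theorem, so the perceptron convergence guarantee yields crisp pass/fail
  properties (converges; 100% training accuracy at zero noise).
* **Threshold $\theta = 0$ by default**: the training default has no bias
  feature, and a bias-free perceptron is only guaranteed to converge when
  the separator passes through the origin. Class balance is kept by drawing
  $w^*$ with near-zero entry sum (attributes are positive, so a zero-sum
  separator splits the attribute box roughly evenly); an optional `balance`
  field fills exact per-class quotas by rejection instead.
* **Default margin 8**: by the perceptron mistake bound, total updates are
  at most $(R\,\|w^*\|/\gamma)^2$ with $R \le 10\sqrt{d}$ and
  $\|w^*\| \le 3\sqrt{d}$. At the default $d = 9$ and margin $\gamma = 8$
  this is $\approx 1.1\times10^3$ updates, comfortably inside the default
  100-epoch cap; at margin 1 the bound is $\approx 7\times10^4$ and
  convergence within 100 epochs is *not* guaranteed (and empirically does
  fail for some seeds). A margin of 8 in raw score units is narrow relative
  to the score range ($|w^* \cdot x|$ reaches several hundred), so the data
  remain visually "hard".

What passing tests on this generator do **not** show: robustness to label
noise, to non-separable classes, to correlated or heavy-tailed attributes,
or to the class imbalance of real registries. The ED $\equiv$ PD equivalence
is unaffected by any of that (it is an algebraic property of the update
rule), but accuracy numbers from synthetic draws say nothing about clinical
performance.

## Numerical and protocol bookkeeping choices

* Residues strictly greater than $n/2$ decode as negative (the symmetric
  convention); the encoder only ever produces $n - |v|$ for negatives, so
  encode/decode agree for all in-range magnitudes, both parities of $n$.
* Operation counters tick one EXP per ciphertext exponentiation, one MUL per
  multiplication mod $n^2$, one DIV per decryption (the modular inverse
  folded into $\mu$). A round is a request flight plus its response flight.
* Degenerate inputs fail loudly: empty vectors, dimension mismatches, keys
  that do not match a ciphertext's key id, plaintexts or scalars out of
  $[0, n)$, masks sharing a factor with $n$, magnitudes at the sign
  boundary, and range-guard violations are all hard errors.
* Problem sizes in the test suite — 256-bit primes, 1000-element correctness
  sweeps, 500 random inner products up to $d = 32$, one full 100-sample
  $d = 9$ encrypted training run, 20 generator seeds for convergence — were
  chosen so the whole suite completes in about a minute and a half on one
  core while still exercising every claim at realistic scale.

## Limitations

* Security holds only against honest-but-curious parties; there are no
  zero-knowledge proofs, no malicious-adversary protections, and no formal
  proof artifacts in the package (transcript checks are sanity checks, not
  proofs).
* No constant-time arithmetic or side-channel hardening; key files are plain
  JSON (private files written mode 0600).
* One sample per ciphertext vector: no packing/batching, no mini-batch or
  averaged perceptron, no kernels, no multi-layer models.
* The in-process message channel simulates the network; the
  `Message`/`Transcript` contract is designed so a socket backend could drop
  in, but none is provided.
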