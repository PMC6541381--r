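// Arbitrary-precision modular arithmetic over OpenSSL BIGNUM.
// All values cross the R boundary as hex strings (lowercase, optional "-" sign);
// R supplies every random bit so results are reproducible under set.seed().

#include <Rcpp.h>
#include <openssl/bn.h>
#include <openssl/opensslv.h>
#include <string>

namespace {

struct Ctx {
  BN_CTX *ctx;
  Ctx() : ctx(BN_CTX_new()) {
    if (!ctx) Rcpp::stop("BN_CTX allocation failed");
  }
  ~Ctx() { BN_CTX_free(ctx); }
};

struct Big {
  BIGNUM *p;
  Big() : p(BN_new()) {
    if (!p) Rcpp::stop("BIGNUM allocation failed");
  }
  explicit Big(const std::string &hex) : p(nullptr) {
    if (BN_hex2bn(&p, hex.c_str()) == 0 || p == nullptr)
      Rcpp::stop("invalid hex integer: '%s'", hex);
  }
  ~Big() { BN_free(p); }
  Big(const Big &) = delete;
  Big &operator=(const Big &) = delete;
};

std::string to_hex(const BIGNUM *a) {
  char *s = BN_bn2hex(a);
  if (!s) Rcpp::stop("BN_bn2hex failed");
  std::string out(s);
  OPENSSL_free(s);
  for (auto &c : out) c = static_cast<char>(tolower(c));
  // canonical form: no leading zeros (BN_bn2hex pads to whole bytes)
  bool neg = !out.empty() && out[0] == '-';
  std::size_t start = neg ? 1 : 0;
  std::size_t first = out.find_first_not_of('0', start);
  if (first == std::string::npos) return "0";
  return (neg ? "-" : "") + out.substr(first);
}

} // namespace

// [[Rcpp::export(name = ".bn_add")]]
std::string bn_add_(std::string a, std::string b) {
  Big x(a), y(b), r;
  if (!BN_add(r.p, x.p, y.p)) Rcpp::stop("BN_add failed");
  return to_hex(r.p);
}

// [[Rcpp::export(name = ".bn_sub")]]
std::string bn_sub_(std::string a, std::string b) {
  Big x(a), y(b), r;
  if (!BN_sub(r.p, x.p, y.p)) Rcpp::stop("BN_sub failed");
  return to_hex(r.p);
}

// [[Rcpp::export(name = ".bn_mul")]]
std::string bn_mul_(std::string a, std::string b) {
  Ctx c; Big x(a), y(b), r;
  if (!BN_mul(r.p, x.p, y.p, c.ctx)) Rcpp::stop("BN_mul failed");
  return to_hex(r.p);
}

// Truncated quotient (sign follows C semantics); b must be nonzero.
// [[Rcpp::export(name = ".bn_div")]]
std::string bn_div_(std::string a, std::string b) {
  Ctx c; Big x(a), y(b), q, r;
  if (BN_is_zero(y.p)) Rcpp::stop("division by zero");
  if (!BN_div(q.p, r.p, x.p, y.p, c.ctx)) Rcpp::stop("BN_div failed");
  return to_hex(q.p);
}

// Nonnegative residue a mod m, m > 0.
// [[Rcpp::export(name = ".bn_mod")]]
std::string bn_mod_(std::string a, std::string m) {
  Ctx c; Big x(a), mm(m), r;
  if (BN_is_zero(mm.p) || BN_is_negative(mm.p)) Rcpp::stop("modulus must be positive");
  if (!BN_nnmod(r.p, x.p, mm.p, c.ctx)) Rcpp::stop("BN_nnmod failed");
  return to_hex(r.p);
}

// a^e mod m with e >= 0.
// [[Rcpp::export(name = ".bn_powm")]]
std::string bn_powm_(std::string a, std::string e, std::string m) {
  Ctx c; Big x(a), ee(e), mm(m), base, r;
  if (BN_is_negative(ee.p)) Rcpp::stop("negative exponent");
  if (BN_is_zero(mm.p) || BN_is_negative(mm.p)) Rcpp::stop("modulus must be positive");
  if (!BN_nnmod(base.p, x.p, mm.p, c.ctx)) Rcpp::stop("BN_nnmod failed");
  if (!BN_mod_exp(r.p, base.p, ee.p, mm.p, c.ctx)) Rcpp::stop("BN_mod_exp failed");
  return to_hex(r.p);
}

// Modular inverse; errors when gcd(a, m) != 1.
// [[Rcpp::export(name = ".bn_invm")]]
std::string bn_invm_(std::string a, std::string m) {
  Ctx c; Big x(a), mm(m), r;
  if (!BN_mod_inverse(r.p, x.p, mm.p, c.ctx))
    Rcpp::stop("value is not invertible modulo the given modulus");
  return to_hex(r.p);
}

// [[Rcpp::export(name = ".bn_gcd")]]
std::string bn_gcd_(std::string a, std::string b) {
  Ctx c; Big x(a), y(b), r;
  BN_set_negative(x.p, 0);
  BN_set_negative(y.p, 0);
  if (!BN_gcd(r.p, x.p, y.p, c.ctx)) Rcpp::stop("BN_gcd failed");
  return to_hex(r.p);
}

// [[Rcpp::export(name = ".bn_cmp")]]
int bn_cmp_(std::string a, std::string b) {
  Big x(a), y(b);
  return BN_cmp(x.p, y.p);
}

// [[Rcpp::export(name = ".bn_nbits")]]
int bn_nbits_(std::string a) {
  Big x(a);
  return BN_num_bits(x.p);
}

// Miller-Rabin (with trial division) as provided by libcrypto; the witness
// count requested is at least `nchecks`, OpenSSL 3 always uses 64.
// [[Rcpp::export(name = ".bn_is_prime")]]
bool bn_is_prime_(std::string a, int nchecks = 64) {
  Ctx c; Big x(a);
  if (BN_is_negative(x.p)) return false;
#if OPENSSL_VERSION_NUMBER >= 0x30000000L
  (void)nchecks;
  int r = BN_check_prime(x.p, c.ctx, nullptr);
#else
  int r = BN_is_prime_fasttest_ex(x.p, nchecks, c.ctx, 1, nullptr);
#endif
  if (r < 0) Rcpp::stop("primality test failed internally");
  return r == 1;
}

// [[Rcpp::export(name = ".bn_dec2hex")]]
std::string bn_dec2hex_(std::string dec) {
  BIGNUM *p = nullptr;
  if (BN_dec2bn(&p, dec.c_str()) == 0 || p == nullptr)
    Rcpp::stop("invalid decimal integer: '%s'", dec);
  std::string out = to_hex(p);
  BN_free(p);
  return out;
}

// [[Rcpp::export(name = ".bn_hex2dec")]]
std::string bn_hex2dec_(std::string hex) {
  Big x(hex);
  char *s = BN_bn2dec(x.p);
  if (!s) Rcpp::stop("BN_bn2dec failed");
  std::string out(s);
  OPENSSL_free(s);
  return out;
}
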