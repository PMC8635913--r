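// SHA-256 (FIPS 180-4) and HMAC-SHA256 over raw vectors.
// Self-contained so that hash chaining, committee selection and the
// simulated signature scheme have no dependency beyond Rcpp.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>

using Rcpp::RawVector;

static const uint32_t H0[8] = {
  0x6a09e667u, 0xbb67ae85u, 0x3c6ef372u, 0xa54ff53au,
  0x510e527fu, 0x9b05688cu, 0x1f83d9abu, 0x5be0cd19u
};

static const uint32_t K[64] = {
  0x428a2f98u, 0x71374491u, 0xb5c0fbcfu, 0xe9b5dba5u, 0x3956c25bu, 0x59f111f1u, 0x923f82a4u, 0xab1c5ed5u,
  0xd807aa98u, 0x12835b01u, 0x243185beu, 0x550c7dc3u, 0x72be5d74u, 0x80deb1feu, 0x9bdc06a7u, 0xc19bf174u,
  0xe49b69c1u, 0xefbe4786u, 0x0fc19dc6u, 0x240ca1ccu, 0x2de92c6fu, 0x4a7484aau, 0x5cb0a9dcu, 0x76f988dau,
  0x983e5152u, 0xa831c66du, 0xb00327c8u, 0xbf597fc7u, 0xc6e00bf3u, 0xd5a79147u, 0x06ca6351u, 0x14292967u,
  0x27b70a85u, 0x2e1b2138u, 0x4d2c6dfcu, 0x53380d13u, 0x650a7354u, 0x766a0abbu, 0x81c2c92eu, 0x92722c85u,
  0xa2bfe8a1u, 0xa81a664bu, 0xc24b8b70u, 0xc76c51a3u, 0xd192e819u, 0xd6990624u, 0xf40e3585u, 0x106aa070u,
  0x19a4c116u, 0x1e376c08u, 0x2748774cu, 0x34b0bcb5u, 0x391c0cb3u, 0x4ed8aa4au, 0x5b9cca4fu, 0x682e6ff3u,
  0x748f82eeu, 0x78a5636fu, 0x84c87814u, 0x8cc70208u, 0x90befffau, 0xa4506cebu, 0xbef9a3f7u, 0xc67178f2u
};

static inline uint32_t rotr(uint32_t x, int n) {
  return (x >> n) | (x << (32 - n));
}

static void sha256_bytes(const uint8_t* msg, size_t len, uint8_t out[32]) {
  uint32_t h[8];
  std::memcpy(h, H0, sizeof(H0));

  // padded message: msg || 0x80 || zeros || 64-bit big-endian bit length
  size_t padded = ((len + 8) / 64 + 1) * 64;
  std::vector<uint8_t> buf(padded, 0);
  if (len > 0) std::memcpy(buf.data(), msg, len);
  buf[len] = 0x80;
  uint64_t bitlen = static_cast<uint64_t>(len) * 8u;
  for (int i = 0; i < 8; ++i)
    buf[padded - 1 - i] = static_cast<uint8_t>((bitlen >> (8 * i)) & 0xffu);

  uint32_t w[64];
  for (size_t off = 0; off < padded; off += 64) {
    const uint8_t* p = buf.data() + off;
    for (int t = 0; t < 16; ++t)
      w[t] = (uint32_t(p[4 * t]) << 24) | (uint32_t(p[4 * t + 1]) << 16) |
             (uint32_t(p[4 * t + 2]) << 8) | uint32_t(p[4 * t + 3]);
    for (int t = 16; t < 64; ++t) {
      uint32_t s0 = rotr(w[t - 15], 7) ^ rotr(w[t - 15], 18) ^ (w[t - 15] >> 3);
      uint32_t s1 = rotr(w[t - 2], 17) ^ rotr(w[t - 2], 19) ^ (w[t - 2] >> 10);
      w[t] = w[t - 16] + s0 + w[t - 7] + s1;
    }
    uint32_t a = h[0], b = h[1], c = h[2], d = h[3];
    uint32_t e = h[4], f = h[5], g = h[6], hh = h[7];
    for (int t = 0; t < 64; ++t) {
      uint32_t S1 = rotr(e, 6) ^ rotr(e, 11) ^ rotr(e, 25);
      uint32_t ch = (e & f) ^ (~e & g);
      uint32_t t1 = hh + S1 + ch + K[t] + w[t];
      uint32_t S0 = rotr(a, 2) ^ rotr(a, 13) ^ rotr(a, 22);
      uint32_t maj = (a & b) ^ (a & c) ^ (b & c);
      uint32_t t2 = S0 + maj;
      hh = g; g = f; f = e; e = d + t1;
      d = c; c = b; b = a; a = t1 + t2;
    }
    h[0] += a; h[1] += b; h[2] += c; h[3] += d;
    h[4] += e; h[5] += f; h[6] += g; h[7] += hh;
  }
  for (int i = 0; i < 8; ++i) {
    out[4 * i]     = static_cast<uint8_t>((h[i] >> 24) & 0xffu);
    out[4 * i + 1] = static_cast<uint8_t>((h[i] >> 16) & 0xffu);
    out[4 * i + 2] = static_cast<uint8_t>((h[i] >> 8) & 0xffu);
    out[4 * i + 3] = static_cast<uint8_t>(h[i] & 0xffu);
  }
}

//' SHA-256 digest of a raw vector
//'
//' @param data raw vector to hash.
//' @return 32-byte raw vector.
//' @export
// [[Rcpp::export]]
RawVector sha256_raw(RawVector data) {
  uint8_t out[32];
  sha256_bytes(data.length() ? &data[0] : nullptr,
               static_cast<size_t>(data.length()), out);
  RawVector res(32);
  std::memcpy(&res[0], out, 32);
  return res;
}

//' HMAC-SHA256 of a raw message under a raw key
//'
//' @param key raw key (any length; hashed first if longer than 64 bytes).
//' @param msg raw message.
//' @return 32-byte raw vector.
//' @export
// [[Rcpp::export]]
RawVector hmac_sha256_raw(RawVector key, RawVector msg) {
  uint8_t k[64];
  std::memset(k, 0, 64);
  if (key.length() > 64) {
    uint8_t kh[32];
    sha256_bytes(&key[0], static_cast<size_t>(key.length()), kh);
    std::memcpy(k, kh, 32);
  } else if (key.length() > 0) {
    std::memcpy(k, &key[0], static_cast<size_t>(key.length()));
  }
  std::vector<uint8_t> inner(64 + static_cast<size_t>(msg.length()));
  for (int i = 0; i < 64; ++i) inner[i] = k[i] ^ 0x36u;
  if (msg.length() > 0) std::memcpy(inner.data() + 64, &msg[0],
                                    static_cast<size_t>(msg.length()));
  uint8_t ih[32];
  sha256_bytes(inner.data(), inner.size(), ih);
  std::vector<uint8_t> outer(64 + 32);
  for (int i = 0; i < 64; ++i) outer[i] = k[i] ^ 0x5cu;
  std::memcpy(outer.data() + 64, ih, 32);
  uint8_t out[32];
  sha256_bytes(outer.data(), outer.size(), out);
  RawVector res(32);
  std::memcpy(&res[0], out, 32);
  return res;
}
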