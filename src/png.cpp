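// Minimal PNG codec backed by zlib: 8-bit grayscale / RGB / RGBA,
// non-interlaced.  Reading understands all five scanline filters; writing
// emits filter 0 rows.  16-bit files are rejected with an explicit format
// error rather than silently cast.

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <cstring>
#include <vector>

using namespace Rcpp;

static const unsigned char PNG_SIG[8] = {137, 80, 78, 71, 13, 10, 26, 10};

static uint32_t be32(const unsigned char* p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) |
         ((uint32_t)p[2] << 8) | (uint32_t)p[3];
}

static void put_be32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static int paeth(int a, int b, int c) {
  const int p = a + b - c;
  const int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// [[Rcpp::export]]
List png_read_cpp(std::string path) {
  FILE* fp = std::fopen(path.c_str(), "rb");
  if (!fp) stop("cannot open '%s'", path);
  std::vector<unsigned char> buf;
  unsigned char tmp[65536];
  size_t n;
  while ((n = std::fread(tmp, 1, sizeof(tmp), fp)) > 0)
    buf.insert(buf.end(), tmp, tmp + n);
  std::fclose(fp);
  if (buf.size() < 45 || std::memcmp(buf.data(), PNG_SIG, 8) != 0)
    stop("'%s' is not a PNG file", path);

  uint32_t W = 0, H = 0;
  int bit_depth = 0, color_type = 0, interlace = 0;
  std::vector<unsigned char> idat;
  size_t pos = 8;
  while (pos + 8 <= buf.size()) {
    const uint32_t len = be32(&buf[pos]);
    const char* type = (const char*)&buf[pos + 4];
    if (pos + 12 + len > buf.size()) stop("truncated PNG '%s'", path);
    const unsigned char* data = &buf[pos + 8];
    if (std::memcmp(type, "IHDR", 4) == 0) {
      W = be32(data);
      H = be32(data + 4);
      bit_depth = data[8];
      color_type = data[9];
      interlace = data[12];
    } else if (std::memcmp(type, "IDAT", 4) == 0) {
      idat.insert(idat.end(), data, data + len);
    } else if (std::memcmp(type, "IEND", 4) == 0) {
      break;
    }
    pos += 12 + len;
  }
  if (W == 0 || H == 0) stop("PNG '%s' has no IHDR", path);
  if (bit_depth == 16)
    stop("PNG '%s' is 16-bit; only 8-bit images are supported", path);
  if (bit_depth != 8)
    stop("PNG '%s' has unsupported bit depth %d", path, bit_depth);
  if (interlace != 0) stop("interlaced PNG is not supported ('%s')", path);
  int channels;
  switch (color_type) {
    case 0: channels = 1; break;
    case 2: channels = 3; break;
    case 4: channels = 2; break;
    case 6: channels = 4; break;
    default: stop("PNG '%s' has unsupported color type %d", path, color_type);
  }

  const size_t stride = (size_t)W * channels;
  std::vector<unsigned char> raw(H * (stride + 1));
  z_stream zs;
  std::memset(&zs, 0, sizeof(zs));
  if (inflateInit(&zs) != Z_OK) stop("zlib init failed");
  zs.next_in = idat.data();
  zs.avail_in = (uInt)idat.size();
  zs.next_out = raw.data();
  zs.avail_out = (uInt)raw.size();
  const int zret = inflate(&zs, Z_FINISH);
  inflateEnd(&zs);
  if (zret != Z_STREAM_END && !(zret == Z_OK && zs.avail_out == 0))
    stop("PNG '%s': corrupt compressed image data", path);

  // undo per-row filters
  std::vector<unsigned char> img(H * stride);
  const int bpp = channels;
  for (uint32_t r = 0; r < H; ++r) {
    const unsigned char ft = raw[r * (stride + 1)];
    const unsigned char* src = &raw[r * (stride + 1) + 1];
    unsigned char* dst = &img[r * stride];
    const unsigned char* up = r > 0 ? &img[(r - 1) * stride] : NULL;
    for (size_t i = 0; i < stride; ++i) {
      const int a = i >= (size_t)bpp ? dst[i - bpp] : 0;
      const int b = up ? up[i] : 0;
      const int c = (up && i >= (size_t)bpp) ? up[i - bpp] : 0;
      int x = src[i];
      switch (ft) {
        case 0: break;
        case 1: x += a; break;
        case 2: x += b; break;
        case 3: x += (a + b) / 2; break;
        case 4: x += paeth(a, b, c); break;
        default: stop("PNG '%s': bad filter type %d", path, (int)ft);
      }
      dst[i] = (unsigned char)(x & 0xff);
    }
  }

  // to column-major H x W x channels integer array
  IntegerVector out((size_t)H * W * channels);
  for (uint32_t r = 0; r < H; ++r)
    for (uint32_t c = 0; c < W; ++c)
      for (int ch = 0; ch < channels; ++ch)
        out[(size_t)ch * H * W + (size_t)c * H + r] =
            img[r * stride + (size_t)c * channels + ch];
  return List::create(Named("height") = (int)H, Named("width") = (int)W,
                      Named("channels") = channels, Named("data") = out);
}

static void write_chunk(std::vector<unsigned char>& out, const char* type,
                        const std::vector<unsigned char>& data) {
  put_be32(out, (uint32_t)data.size());
  std::vector<unsigned char> td(type, type + 4);
  td.insert(td.end(), data.begin(), data.end());
  const uint32_t crc = crc32(0L, td.data(), (uInt)td.size());
  out.insert(out.end(), td.begin(), td.end());
  put_be32(out, crc);
}

// data: column-major H x W x channels integers in 0..255
// [[Rcpp::export]]
void png_write_cpp(std::string path, IntegerVector data, int H, int W,
                   int channels) {
  if (channels != 1 && channels != 3)
    stop("png_write supports 1 (gray) or 3 (RGB) channels");
  const size_t stride = (size_t)W * channels;
  std::vector<unsigned char> raw((size_t)H * (stride + 1));
  for (int r = 0; r < H; ++r) {
    raw[(size_t)r * (stride + 1)] = 0;  // filter type 0
    unsigned char* dst = &raw[(size_t)r * (stride + 1) + 1];
    for (int c = 0; c < W; ++c)
      for (int ch = 0; ch < channels; ++ch) {
        int v = data[(size_t)ch * H * W + (size_t)c * H + r];
        if (v < 0) v = 0;
        if (v > 255) v = 255;
        dst[(size_t)c * channels + ch] = (unsigned char)v;
      }
  }
  uLongf clen = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(clen);
  if (compress2(comp.data(), &clen, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("zlib compression failed");
  comp.resize(clen);

  std::vector<unsigned char> out(PNG_SIG, PNG_SIG + 8);
  std::vector<unsigned char> ihdr;
  put_be32(ihdr, (uint32_t)W);
  put_be32(ihdr, (uint32_t)H);
  ihdr.push_back(8);                               // bit depth
  ihdr.push_back(channels == 1 ? 0 : 2);           // color type
  ihdr.push_back(0);
  ihdr.push_back(0);
  ihdr.push_back(0);
  write_chunk(out, "IHDR", ihdr);
  write_chunk(out, "IDAT", comp);
  write_chunk(out, "IEND", std::vector<unsigned char>());

  FILE* fp = std::fopen(path.c_str(), "wb");
  if (!fp) stop("cannot write '%s'", path);
  std::fwrite(out.data(), 1, out.size(), fp);
  std::fclose(fp);
}
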