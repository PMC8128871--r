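// Scale-invariant feature transform: difference-of-Gaussians keypoint
// detection plus the 4x4x8 gradient-orientation descriptor.  Operates on a
// single scalar channel scaled to [0,1]; colour handling (per-channel
// pooling) lives on the R side.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

const double TWO_PI = 6.283185307179586476925286766559;

// separable Gaussian blur with reflected borders, in place
void gaussian_blur(std::vector<double>& img, int w, int h, double sigma) {
  if (sigma < 1e-8) return;
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s2 = 2.0 * sigma * sigma, sum = 0.0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-(double)(i * i) / s2); sum += k[i + r]; }
  for (double& v : k) v /= sum;
  std::vector<double> tmp(img.size());
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) {
        int xx = x + i;
        if (xx < 0) xx = -xx;
        if (xx >= w) xx = 2 * w - 2 - xx;
        acc += k[i + r] * img[(size_t)y * w + xx];
      }
      tmp[(size_t)y * w + x] = acc;
    }
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) {
        int yy = y + i;
        if (yy < 0) yy = -yy;
        if (yy >= h) yy = 2 * h - 2 - yy;
        acc += k[i + r] * tmp[(size_t)yy * w + x];
      }
      img[(size_t)y * w + x] = acc;
    }
}

struct Keypoint { double x, y, sigma, theta; int octave, level; };

// 36-bin orientation histogram around (x, y) on a Gaussian level; returns
// dominant orientations (>= 80% of the peak, parabolic interpolation)
std::vector<double> keypoint_orientations(const std::vector<double>& img, int w, int h,
                                          int x, int y, double sigma_rel) {
  const int NB = 36;
  double hist[NB] = {0.0};
  double sw = 1.5 * sigma_rel;
  int R = (int)std::lround(3.0 * sw);
  if (R < 1) R = 1;
  for (int dy = -R; dy <= R; ++dy)
    for (int dx = -R; dx <= R; ++dx) {
      int px = x + dx, py = y + dy;
      if (px < 1 || px >= w - 1 || py < 1 || py >= h - 1) continue;
      double gx = 0.5 * (img[(size_t)py * w + px + 1] - img[(size_t)py * w + px - 1]);
      double gy = 0.5 * (img[(size_t)(py + 1) * w + px] - img[(size_t)(py - 1) * w + px]);
      double mag = std::sqrt(gx * gx + gy * gy);
      if (mag <= 0.0) continue;
      double ang = std::atan2(gy, gx);
      if (ang < 0) ang += TWO_PI;
      double wgt = std::exp(-(double)(dx * dx + dy * dy) / (2.0 * sw * sw));
      int bin = (int)std::floor(ang / TWO_PI * NB) % NB;
      hist[bin] += wgt * mag;
    }
  // circular smoothing
  for (int pass = 0; pass < 6; ++pass) {
    double prev = hist[NB - 1], first = hist[0];
    for (int i = 0; i < NB; ++i) {
      double next = (i == NB - 1) ? first : hist[i + 1];
      double cur = hist[i];
      hist[i] = (prev + cur + next) / 3.0;
      prev = cur;
    }
  }
  double hmax = *std::max_element(hist, hist + NB);
  std::vector<double> out;
  if (hmax <= 0.0) return out;
  for (int i = 0; i < NB; ++i) {
    double l = hist[(i + NB - 1) % NB], c = hist[i], r = hist[(i + 1) % NB];
    if (c >= 0.8 * hmax && c > l && c > r) {
      double off = 0.5 * (l - r) / (l - 2.0 * c + r);
      double th = (i + 0.5 + off) / NB * TWO_PI;
      if (th < 0) th += TWO_PI;
      if (th >= TWO_PI) th -= TWO_PI;
      out.push_back(th);
    }
  }
  return out;
}

// standard 4x4 spatial x 8 orientation descriptor; returns false when the
// support region has no gradient energy
bool compute_descriptor(const std::vector<double>& img, int w, int h,
                        double x, double y, double sigma_rel, double theta,
                        double* desc) {
  const int NBP = 4, NBO = 8;
  const double SBP = 3.0 * sigma_rel;
  double ct = std::cos(theta), st = std::sin(theta);
  int R = (int)std::ceil(SBP * (NBP + 1) / 2.0 * M_SQRT2);
  std::fill(desc, desc + NBP * NBP * NBO, 0.0);
  int xi = (int)std::lround(x), yi = (int)std::lround(y);
  for (int dy = -R; dy <= R; ++dy)
    for (int dx = -R; dx <= R; ++dx) {
      int px = xi + dx, py = yi + dy;
      if (px < 1 || px >= w - 1 || py < 1 || py >= h - 1) continue;
      double gx = 0.5 * (img[(size_t)py * w + px + 1] - img[(size_t)py * w + px - 1]);
      double gy = 0.5 * (img[(size_t)(py + 1) * w + px] - img[(size_t)(py - 1) * w + px]);
      double mag = std::sqrt(gx * gx + gy * gy);
      if (mag <= 0.0) continue;
      // rotate into the keypoint frame, in spatial-bin units
      double nx = (ct * dx + st * dy) / SBP;
      double ny = (-st * dx + ct * dy) / SBP;
      if (std::fabs(nx) >= (NBP + 1) / 2.0 || std::fabs(ny) >= (NBP + 1) / 2.0) continue;
      double win = std::exp(-(nx * nx + ny * ny) / (2.0 * (NBP / 2.0) * (NBP / 2.0)));
      double ang = std::atan2(gy, gx) - theta;
      while (ang < 0) ang += TWO_PI;
      while (ang >= TWO_PI) ang -= TWO_PI;
      double ob = ang / TWO_PI * NBO;
      double bx = nx + NBP / 2.0 - 0.5;
      double by = ny + NBP / 2.0 - 0.5;
      int bx0 = (int)std::floor(bx), by0 = (int)std::floor(by), ob0 = (int)std::floor(ob);
      double fx = bx - bx0, fy = by - by0, fo = ob - ob0;
      for (int ix = 0; ix <= 1; ++ix) {
        int cbx = bx0 + ix;
        if (cbx < 0 || cbx >= NBP) continue;
        double wx = ix ? fx : 1.0 - fx;
        for (int iy = 0; iy <= 1; ++iy) {
          int cby = by0 + iy;
          if (cby < 0 || cby >= NBP) continue;
          double wy = iy ? fy : 1.0 - fy;
          for (int io = 0; io <= 1; ++io) {
            int cbo = (ob0 + io) % NBO;
            double wo = io ? fo : 1.0 - fo;
            desc[(cby * NBP + cbx) * NBO + cbo] += mag * win * wx * wy * wo;
          }
        }
      }
    }
  double nrm = 0.0;
  for (int i = 0; i < 128; ++i) nrm += desc[i] * desc[i];
  if (nrm <= 1e-24) return false;
  nrm = std::sqrt(nrm);
  for (int i = 0; i < 128; ++i) {
    desc[i] /= nrm;
    if (desc[i] > 0.2) desc[i] = 0.2;
  }
  nrm = 0.0;
  for (int i = 0; i < 128; ++i) nrm += desc[i] * desc[i];
  nrm = std::sqrt(nrm);
  for (int i = 0; i < 128; ++i) {
    desc[i] = desc[i] / nrm * 512.0;
    if (desc[i] > 255.0) desc[i] = 255.0;
  }
  return true;
}

} // namespace

// Sparse SIFT on one channel.  `img` holds values in [0,1], row-major by R
// column-major convention: img(row, col).  Returned keypoint coordinates are
// 0-based (x = column, y = row) in the input image frame.
// [[Rcpp::export]]
List sift_detect_cpp(NumericMatrix img, double peak_threshold, double edge_threshold,
                     int n_levels) {
  int h0 = img.nrow(), w0 = img.ncol();
  const int S = n_levels;               // sampled scales per octave
  const double sigma0 = 1.6, sigma_in = 0.5;
  int n_oct = std::max(1, (int)std::floor(std::log2((double)std::min(w0, h0) / 12.0)));

  std::vector<double> base((size_t)w0 * h0);
  for (int y = 0; y < h0; ++y)
    for (int x = 0; x < w0; ++x) base[(size_t)y * w0 + x] = img(y, x);
  gaussian_blur(base, w0, h0, std::sqrt(std::max(0.0, sigma0 * sigma0 - sigma_in * sigma_in)));

  std::vector<Keypoint> kps;
  std::vector<std::vector<double>> descs;
  double edge_k = (edge_threshold + 1.0) * (edge_threshold + 1.0) / edge_threshold;

  int w = w0, h = h0;
  for (int o = 0; o < n_oct; ++o) {
    // Gaussian stack: levels 0..S+2, level s at sigma0 * 2^(s/S)
    std::vector<std::vector<double>> G(S + 3);
    G[0] = base;
    for (int s = 1; s < S + 3; ++s) {
      double sa = sigma0 * std::pow(2.0, (double)(s - 1) / S);
      double sb = sigma0 * std::pow(2.0, (double)s / S);
      G[s] = G[s - 1];
      gaussian_blur(G[s], w, h, std::sqrt(sb * sb - sa * sa));
    }
    std::vector<std::vector<double>> D(S + 2);
    for (int s = 0; s < S + 2; ++s) {
      D[s].resize((size_t)w * h);
      for (size_t i = 0; i < D[s].size(); ++i) D[s][i] = G[s + 1][i] - G[s][i];
    }
    double scale_mult = std::pow(2.0, o);
    for (int s = 1; s <= S; ++s) {
      const std::vector<double>& d = D[s];
      for (int y = 1; y < h - 1; ++y)
        for (int x = 1; x < w - 1; ++x) {
          double v = d[(size_t)y * w + x];
          if (std::fabs(v) < peak_threshold) continue;
          bool ismax = v > 0, ismin = v < 0;
          for (int ds = -1; ds <= 1 && (ismax || ismin); ++ds)
            for (int dy = -1; dy <= 1 && (ismax || ismin); ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!ds && !dy && !dx) continue;
                double nv = D[s + ds][(size_t)(y + dy) * w + (x + dx)];
                if (nv >= v) ismax = false;
                if (nv <= v) ismin = false;
              }
          if (!ismax && !ismin) continue;
          // reject edge-like responses via the 2x2 Hessian ratio
          double dxx = d[(size_t)y * w + x + 1] + d[(size_t)y * w + x - 1] - 2.0 * v;
          double dyy = d[(size_t)(y + 1) * w + x] + d[(size_t)(y - 1) * w + x] - 2.0 * v;
          double dxy = 0.25 * (d[(size_t)(y + 1) * w + x + 1] - d[(size_t)(y + 1) * w + x - 1]
                               - d[(size_t)(y - 1) * w + x + 1] + d[(size_t)(y - 1) * w + x - 1]);
          double tr = dxx + dyy, det = dxx * dyy - dxy * dxy;
          if (det <= 0.0 || tr * tr / det >= edge_k) continue;
          double sigma_rel = sigma0 * std::pow(2.0, (double)s / S);
          std::vector<double> thetas = keypoint_orientations(G[s], w, h, x, y, sigma_rel);
          for (double th : thetas) {
            std::vector<double> dd(128);
            if (!compute_descriptor(G[s], w, h, x, y, sigma_rel, th, dd.data())) continue;
            Keypoint kp;
            kp.x = x * scale_mult;
            kp.y = y * scale_mult;
            kp.sigma = sigma_rel * scale_mult;
            kp.theta = th;
            kp.octave = o;
            kp.level = s;
            kps.push_back(kp);
            descs.push_back(std::move(dd));
          }
        }
    }
    // next octave: subsample level S (sigma = 2*sigma0)
    if (o + 1 < n_oct) {
      int nw = w / 2, nh = h / 2;
      if (nw < 12 || nh < 12) break;
      std::vector<double> nb((size_t)nw * nh);
      for (int y = 0; y < nh; ++y)
        for (int x = 0; x < nw; ++x) nb[(size_t)y * nw + x] = G[S][(size_t)(2 * y) * w + 2 * x];
      base = std::move(nb);
      w = nw; h = nh;
    }
  }

  int n = (int)kps.size();
  NumericMatrix dm(n, 128), km(n, 4);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 128; ++j) dm(i, j) = descs[i][j];
    km(i, 0) = kps[i].x;
    km(i, 1) = kps[i].y;
    km(i, 2) = kps[i].sigma;
    km(i, 3) = kps[i].theta;
  }
  colnames(km) = CharacterVector::create("x", "y", "scale", "orientation");
  return List::create(_["descriptors"] = dm, _["keypoints"] = km);
}

// Dense descriptors on a regular grid at a single scale, orientation 0.
// Fallback for patches where the blob detector fires nowhere.
// [[Rcpp::export]]
List sift_dense_cpp(NumericMatrix img, int step, double sigma) {
  int h = img.nrow(), w = img.ncol();
  std::vector<double> base((size_t)w * h);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) base[(size_t)y * w + x] = img(y, x);
  gaussian_blur(base, w, h, std::sqrt(std::max(0.0, sigma * sigma - 0.25)));
  int margin = (int)std::ceil(3.0 * sigma * 2.5);
  std::vector<std::vector<double>> descs;
  std::vector<std::pair<int, int>> pts;
  for (int y = margin; y < h - margin; y += step)
    for (int x = margin; x < w - margin; x += step) {
      std::vector<double> dd(128);
      if (!compute_descriptor(base, w, h, x, y, sigma, 0.0, dd.data())) continue;
      descs.push_back(std::move(dd));
      pts.push_back(std::make_pair(x, y));
    }
  int n = (int)descs.size();
  NumericMatrix dm(n, 128), km(n, 4);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 128; ++j) dm(i, j) = descs[i][j];
    km(i, 0) = pts[i].first;
    km(i, 1) = pts[i].second;
    km(i, 2) = sigma;
    km(i, 3) = 0.0;
  }
  colnames(km) = CharacterVector::create("x", "y", "scale", "orientation");
  return List::create(_["descriptors"] = dm, _["keypoints"] = km);
}
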