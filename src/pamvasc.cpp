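#include <Rcpp.h>
using namespace Rcpp;

// reflect index into [0, n): symmetric padding with edge repeat
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(const NumericMatrix& x, int k) {
  int nr = x.nrow(), nc = x.ncol(), h = k / 2, kk = k * k;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(kk);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int m = 0;
      for (int dc = -h; dc <= h; ++dc) {
        int cc = reflect_idx(c + dc, nc);
        for (int dr = -h; dr <= h; ++dr)
          buf[m++] = x(reflect_idx(r + dr, nr), cc);
      }
      std::nth_element(buf.begin(), buf.begin() + kk / 2, buf.begin() + kk);
      double med = buf[kk / 2];
      if (kk % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + kk / 2 - 1, buf.begin() + kk);
        med = 0.5 * (med + buf[kk / 2 - 1]);
      }
      out(r, c) = med;
    }
  }
  return out;
}

// Guo-Hall thinning; mask is 0/1. Returns one-pixel-wide,
// topology-preserving skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img(clone(mask));
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img(r, c);
  };
  bool changed = true;
  std::vector<std::pair<int, int>> del;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      del.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!img(r, c)) continue;
          int p2 = at(r - 1, c),     p3 = at(r - 1, c + 1);
          int p4 = at(r, c + 1),     p5 = at(r + 1, c + 1);
          int p6 = at(r + 1, c),     p7 = at(r + 1, c - 1);
          int p8 = at(r, c - 1),     p9 = at(r - 1, c - 1);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int m = iter == 0 ? ((p6 | p7 | (!p9)) & p8)
                            : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && m == 0)
            del.push_back(std::make_pair(r, c));
        }
      }
      for (size_t i = 0; i < del.size(); ++i)
        img(del[i].first, del[i].second) = 0;
      if (!del.empty()) changed = true;
    }
  }
  // post-pass: dissolve any remaining fully-set 2x2 block by deleting
  // sequentially simple pixels (crossing number 1, not an endpoint)
  bool again = true;
  while (again) {
    again = false;
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        if (!img(r, c)) continue;
        bool in22 = false;
        for (int dr = -1; dr <= 0 && !in22; ++dr)
          for (int dc = -1; dc <= 0 && !in22; ++dc)
            if (at(r + dr, c + dc) && at(r + dr + 1, c + dc) &&
                at(r + dr, c + dc + 1) && at(r + dr + 1, c + dc + 1))
              in22 = true;
        if (!in22) continue;
        int nb[8] = {at(r - 1, c), at(r - 1, c + 1), at(r, c + 1),
                     at(r + 1, c + 1), at(r + 1, c), at(r + 1, c - 1),
                     at(r, c - 1), at(r - 1, c - 1)};
        int A = 0, B = 0;
        for (int i = 0; i < 8; ++i) {
          B += nb[i];
          if (!nb[i] && nb[(i + 1) % 8]) ++A;
        }
        if (A == 1 && B >= 2) {
          img(r, c) = 0;
          again = true;
        }
      }
    }
  }
  return img;
}

// Connected-component labelling, conn = 4 or 8. Labels 1..K, 0 background.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const IntegerMatrix& mask, int conn) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = conn == 8 ? dr8 : dr4;
  const int* dc = conn == 8 ? dc8 : dc4;
  int nd = conn == 8 ? 8 : 4;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nd; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

static inline double window_vc(const std::vector<int>& fr,
                               const std::vector<int>& fc, int w) {
  // box-counting dimension on a w x w window, sizes = powers of 2 <= min(w,8)
  int nfg = (int)fr.size();
  if (nfg == 0) return 0.0;
  std::vector<int> sizes;
  for (int s = 1; s <= w && s <= 8; s *= 2) sizes.push_back(s);
  if ((int)sizes.size() < 3) return 0.0;
  int ns = (int)sizes.size();
  std::vector<double> lx(ns), ly(ns);
  std::vector<char> seen;
  for (int si = 0; si < ns; ++si) {
    int s = sizes[si], g = (w + s - 1) / s;
    seen.assign(g * g, 0);
    int cnt = 0;
    for (int i = 0; i < nfg; ++i) {
      int cell = (fr[i] / s) * g + (fc[i] / s);
      if (!seen[cell]) { seen[cell] = 1; ++cnt; }
    }
    lx[si] = std::log((double)s);
    ly[si] = std::log((double)cnt);
  }
  double mx = 0, my = 0;
  for (int i = 0; i < ns; ++i) { mx += lx[i]; my += ly[i]; }
  mx /= ns; my /= ns;
  double sxy = 0, sxx = 0;
  for (int i = 0; i < ns; ++i) {
    sxy += (lx[i] - mx) * (ly[i] - my);
    sxx += (lx[i] - mx) * (lx[i] - mx);
  }
  return -sxy / sxx;
}

// Sliding-window quantitative maps. Window of size w is centred so that for
// even w the centre pixel has (w/2 - 1) rows above and w/2 below; borders are
// reflect-padded; stride > 1 positions are filled from the nearest computed
// centre. Returns diameter (um), density, pvd, complexity maps.
// [[Rcpp::export]]
List cpp_quant_maps(const IntegerMatrix& mask, const IntegerMatrix& skel,
                    const NumericMatrix& dist, int w, int stride,
                    double pixel_size_um) {
  int nr = mask.nrow(), nc = mask.ncol();
  int lo = (w - 1) / 2, hi = w / 2;
  NumericMatrix dia(nr, nc), den(nr, nc), pvd(nr, nc), cpx(nr, nc);
  std::vector<int> fr, fc;
  fr.reserve(w * w); fc.reserve(w * w);
  std::vector<int> centers_r, centers_c;
  for (int r = 0; r < nr; r += stride) centers_r.push_back(r);
  for (int c = 0; c < nc; c += stride) centers_c.push_back(c);
  int ncr = (int)centers_r.size(), ncc = (int)centers_c.size();
  NumericMatrix gdia(ncr, ncc), gden(ncr, ncc), gpvd(ncr, ncc), gcpx(ncr, ncc);
  for (int ci = 0; ci < ncc; ++ci) {
    int c = centers_c[ci];
    for (int ri = 0; ri < ncr; ++ri) {
      int r = centers_r[ri];
      int mcnt = 0, scnt = 0;
      double dsum = 0;
      fr.clear(); fc.clear();
      for (int dc = -lo; dc <= hi; ++dc) {
        int cc = reflect_idx(c + dc, nc);
        for (int dr = -lo; dr <= hi; ++dr) {
          int rr = reflect_idx(r + dr, nr);
          if (mask(rr, cc)) ++mcnt;
          if (skel(rr, cc)) {
            ++scnt;
            dsum += 2.0 * dist(rr, cc) - 1.0;
            fr.push_back(dr + lo);
            fc.push_back(dc + lo);
          }
        }
      }
      gden(ri, ci) = (double)mcnt / (double)(w * w);
      gpvd(ri, ci) = (double)scnt / (double)(w * w);
      gdia(ri, ci) = scnt ? pixel_size_um * dsum / scnt : 0.0;
      gcpx(ri, ci) = window_vc(fr, fc, w);
    }
  }
  for (int c = 0; c < nc; ++c) {
    int ci = (c + stride / 2) / stride; if (ci >= ncc) ci = ncc - 1;
    for (int r = 0; r < nr; ++r) {
      int ri = (r + stride / 2) / stride; if (ri >= ncr) ri = ncr - 1;
      dia(r, c) = gdia(ri, ci);
      den(r, c) = gden(ri, ci);
      pvd(r, c) = gpvd(ri, ci);
      cpx(r, c) = gcpx(ri, ci);
    }
  }
  return List::create(_["diameter"] = dia, _["density"] = den,
                      _["pvd"] = pvd, _["complexity"] = cpx);
}
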