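#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Feature maps are column-major arrays of dim (D1, D2, D3, C): spatial-first,
// channels last, so the innermost spatial loop walks contiguous memory.
// Convolution weights have dim (k, k, k, C_in, C_out).

static inline int idx4(int t1, int t2, int t3, int c, int D1, int D2, int D3) {
  return t1 + D1 * (t2 + D2 * (t3 + D3 * c));
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, int D1, int D2, int D3, int C,
                             NumericVector w, int k, int O, int pad) {
  NumericVector y(D1 * D2 * D3 * O);
  const double *px = x.begin();
  const double *pw = w.begin();
  double *py = y.begin();
  for (int o = 0; o < O; ++o) {
    for (int c = 0; c < C; ++c) {
      for (int d = 0; d < k; ++d) {
        int s3 = d - pad;
        int lo3 = std::max(0, -s3), hi3 = std::min(D3, D3 - s3);
        for (int b = 0; b < k; ++b) {
          int s2 = b - pad;
          int lo2 = std::max(0, -s2), hi2 = std::min(D2, D2 - s2);
          for (int a = 0; a < k; ++a) {
            int s1 = a - pad;
            int lo1 = std::max(0, -s1), hi1 = std::min(D1, D1 - s1);
            double wv = pw[a + k * (b + k * (d + k * (c + C * o)))];
            if (wv == 0.0) continue;
            for (int t3 = lo3; t3 < hi3; ++t3) {
              for (int t2 = lo2; t2 < hi2; ++t2) {
                const double *xr =
                    px + idx4(s1, t2 + s2, t3 + s3, c, D1, D2, D3);
                double *yr = py + idx4(0, t2, t3, o, D1, D2, D3);
                for (int t1 = lo1; t1 < hi1; ++t1) yr[t1] += wv * xr[t1];
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_input(NumericVector dy, int D1, int D2, int D3,
                                   int O, NumericVector w, int k, int C,
                                   int pad) {
  NumericVector dx(D1 * D2 * D3 * C);
  const double *pdy = dy.begin();
  const double *pw = w.begin();
  double *pdx = dx.begin();
  for (int o = 0; o < O; ++o) {
    for (int c = 0; c < C; ++c) {
      for (int d = 0; d < k; ++d) {
        int s3 = d - pad;
        int lo3 = std::max(0, -s3), hi3 = std::min(D3, D3 - s3);
        for (int b = 0; b < k; ++b) {
          int s2 = b - pad;
          int lo2 = std::max(0, -s2), hi2 = std::min(D2, D2 - s2);
          for (int a = 0; a < k; ++a) {
            int s1 = a - pad;
            int lo1 = std::max(0, -s1), hi1 = std::min(D1, D1 - s1);
            double wv = pw[a + k * (b + k * (d + k * (c + C * o)))];
            if (wv == 0.0) continue;
            for (int t3 = lo3; t3 < hi3; ++t3) {
              for (int t2 = lo2; t2 < hi2; ++t2) {
                double *dxr = pdx + idx4(s1, t2 + s2, t3 + s3, c, D1, D2, D3);
                const double *dyr = pdy + idx4(0, t2, t3, o, D1, D2, D3);
                for (int t1 = lo1; t1 < hi1; ++t1) dxr[t1] += wv * dyr[t1];
              }
            }
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_weight(NumericVector x, int D1, int D2, int D3,
                                    int C, NumericVector dy, int O, int k,
                                    int pad) {
  NumericVector dw(k * k * k * C * O);
  const double *px = x.begin();
  const double *pdy = dy.begin();
  double *pdw = dw.begin();
  for (int o = 0; o < O; ++o) {
    for (int c = 0; c < C; ++c) {
      for (int d = 0; d < k; ++d) {
        int s3 = d - pad;
        int lo3 = std::max(0, -s3), hi3 = std::min(D3, D3 - s3);
        for (int b = 0; b < k; ++b) {
          int s2 = b - pad;
          int lo2 = std::max(0, -s2), hi2 = std::min(D2, D2 - s2);
          for (int a = 0; a < k; ++a) {
            int s1 = a - pad;
            int lo1 = std::max(0, -s1), hi1 = std::min(D1, D1 - s1);
            double acc = 0.0;
            for (int t3 = lo3; t3 < hi3; ++t3) {
              for (int t2 = lo2; t2 < hi2; ++t2) {
                const double *xr =
                    px + idx4(s1, t2 + s2, t3 + s3, c, D1, D2, D3);
                const double *dyr = pdy + idx4(0, t2, t3, o, D1, D2, D3);
                for (int t1 = lo1; t1 < hi1; ++t1) acc += xr[t1] * dyr[t1];
              }
            }
            pdw[a + k * (b + k * (d + k * (c + C * o)))] = acc;
          }
        }
      }
    }
  }
  return dw;
}

// 2x2x2 max pooling, stride 2. Returns pooled values and 1-based argmax
// indices into the input (for the backward scatter).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, int D1, int D2, int D3, int C) {
  int E1 = D1 / 2, E2 = D2 / 2, E3 = D3 / 2;
  NumericVector y(E1 * E2 * E3 * C);
  IntegerVector am(E1 * E2 * E3 * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int t3 = 0; t3 < E3; ++t3) {
      for (int t2 = 0; t2 < E2; ++t2) {
        for (int t1 = 0; t1 < E1; ++t1) {
          double best = R_NegInf;
          int besti = -1;
          for (int d = 0; d < 2; ++d)
            for (int b = 0; b < 2; ++b)
              for (int a = 0; a < 2; ++a) {
                int ii = idx4(2 * t1 + a, 2 * t2 + b, 2 * t3 + d, c, D1, D2, D3);
                if (px[ii] > best) { best = px[ii]; besti = ii; }
              }
          int oo = t1 + E1 * (t2 + E2 * (t3 + E3 * c));
          y[oo] = best;
          am[oo] = besti + 1;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector argmax, int n_in) {
  NumericVector dx(n_in);
  for (int i = 0; i < dy.size(); ++i) dx[argmax[i] - 1] += dy[i];
  return dx;
}

// Transposed convolution, kernel 2, stride 2 (doubles each spatial dim).
// Weights dim (2, 2, 2, C_in, C_out).
// [[Rcpp::export]]
NumericVector cpp_deconv2_fwd(NumericVector x, int D1, int D2, int D3, int C,
                              NumericVector w, int O) {
  int E1 = 2 * D1, E2 = 2 * D2, E3 = 2 * D3;
  NumericVector y(E1 * E2 * E3 * O);
  const double *px = x.begin();
  const double *pw = w.begin();
  double *py = y.begin();
  for (int o = 0; o < O; ++o) {
    for (int c = 0; c < C; ++c) {
      for (int d = 0; d < 2; ++d)
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            double wv = pw[a + 2 * (b + 2 * (d + 2 * (c + C * o)))];
            for (int t3 = 0; t3 < D3; ++t3)
              for (int t2 = 0; t2 < D2; ++t2) {
                const double *xr = px + idx4(0, t2, t3, c, D1, D2, D3);
                double *yr =
                    py + idx4(a, 2 * t2 + b, 2 * t3 + d, o, E1, E2, E3);
                for (int t1 = 0; t1 < D1; ++t1) yr[2 * t1] += wv * xr[t1];
              }
          }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_deconv2_bwd(NumericVector x, int D1, int D2, int D3, int C,
                     NumericVector w, int O, NumericVector dy) {
  int E1 = 2 * D1, E2 = 2 * D2, E3 = 2 * D3;
  NumericVector dx(D1 * D2 * D3 * C);
  NumericVector dw(8 * C * O);
  const double *px = x.begin();
  const double *pw = w.begin();
  const double *pdy = dy.begin();
  double *pdx = dx.begin();
  double *pdw = dw.begin();
  for (int o = 0; o < O; ++o) {
    for (int c = 0; c < C; ++c) {
      for (int d = 0; d < 2; ++d)
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            int wi = a + 2 * (b + 2 * (d + 2 * (c + C * o)));
            double wv = pw[wi];
            double acc = 0.0;
            for (int t3 = 0; t3 < D3; ++t3)
              for (int t2 = 0; t2 < D2; ++t2) {
                const double *xr = px + idx4(0, t2, t3, c, D1, D2, D3);
                double *dxr = pdx + idx4(0, t2, t3, c, D1, D2, D3);
                const double *dyr =
                    pdy + idx4(a, 2 * t2 + b, 2 * t3 + d, o, E1, E2, E3);
                for (int t1 = 0; t1 < D1; ++t1) {
                  acc += xr[t1] * dyr[2 * t1];
                  dxr[t1] += wv * dyr[2 * t1];
                }
              }
            pdw[wi] = acc;
          }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Trilinear resampling of a single-channel 3D grid. The output voxel t maps
// to continuous input coordinate scale*t + off per axis (0-based voxel
// centers); out-of-range samples clamp to the edge.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector x, int D1, int D2, int D3,
                            int E1, int E2, int E3,
                            NumericVector scale, NumericVector off) {
  NumericVector y(E1 * E2 * E3);
  const double *px = x.begin();
  double *py = y.begin();
  for (int t3 = 0; t3 < E3; ++t3) {
    double u3 = scale[2] * t3 + off[2];
    u3 = std::min(std::max(u3, 0.0), (double)(D3 - 1));
    int f3 = (int)std::floor(u3); int c3 = std::min(f3 + 1, D3 - 1);
    double w3 = u3 - f3;
    for (int t2 = 0; t2 < E2; ++t2) {
      double u2 = scale[1] * t2 + off[1];
      u2 = std::min(std::max(u2, 0.0), (double)(D2 - 1));
      int f2 = (int)std::floor(u2); int c2 = std::min(f2 + 1, D2 - 1);
      double w2 = u2 - f2;
      for (int t1 = 0; t1 < E1; ++t1) {
        double u1 = scale[0] * t1 + off[0];
        u1 = std::min(std::max(u1, 0.0), (double)(D1 - 1));
        int f1 = (int)std::floor(u1); int c1 = std::min(f1 + 1, D1 - 1);
        double w1 = u1 - f1;
        double v000 = px[f1 + D1 * (f2 + D2 * f3)];
        double v100 = px[c1 + D1 * (f2 + D2 * f3)];
        double v010 = px[f1 + D1 * (c2 + D2 * f3)];
        double v110 = px[c1 + D1 * (c2 + D2 * f3)];
        double v001 = px[f1 + D1 * (f2 + D2 * c3)];
        double v101 = px[c1 + D1 * (f2 + D2 * c3)];
        double v011 = px[f1 + D1 * (c2 + D2 * c3)];
        double v111 = px[c1 + D1 * (c2 + D2 * c3)];
        double v00 = v000 * (1 - w1) + v100 * w1;
        double v10 = v010 * (1 - w1) + v110 * w1;
        double v01 = v001 * (1 - w1) + v101 * w1;
        double v11 = v011 * (1 - w1) + v111 * w1;
        double v0 = v00 * (1 - w2) + v10 * w2;
        double v1 = v01 * (1 - w2) + v11 * w2;
        py[t1 + E1 * (t2 + E2 * t3)] = v0 * (1 - w3) + v1 * w3;
      }
    }
  }
  return y;
}

// Binary dilation of a 3D mask by an explicit offset list (n x 3, 0-based
// voxel offsets along dims 1..3). Out-of-bounds neighbours are ignored.
// [[Rcpp::export]]
IntegerVector cpp_dilate(IntegerVector m, int D1, int D2, int D3,
                         IntegerMatrix offs) {
  IntegerVector out(m.size());
  int n = offs.nrow();
  for (int t3 = 0; t3 < D3; ++t3)
    for (int t2 = 0; t2 < D2; ++t2)
      for (int t1 = 0; t1 < D1; ++t1) {
        int ii = t1 + D1 * (t2 + D2 * t3);
        if (!m[ii]) continue;
        for (int q = 0; q < n; ++q) {
          int u1 = t1 + offs(q, 0), u2 = t2 + offs(q, 1), u3 = t3 + offs(q, 2);
          if (u1 < 0 || u1 >= D1 || u2 < 0 || u2 >= D2 || u3 < 0 || u3 >= D3)
            continue;
          out[u1 + D1 * (u2 + D2 * u3)] = 1;
        }
      }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_erode(IntegerVector m, int D1, int D2, int D3,
                        IntegerMatrix offs) {
  IntegerVector out(m.size());
  int n = offs.nrow();
  for (int t3 = 0; t3 < D3; ++t3)
    for (int t2 = 0; t2 < D2; ++t2)
      for (int t1 = 0; t1 < D1; ++t1) {
        int ii = t1 + D1 * (t2 + D2 * t3);
        int keep = 1;
        for (int q = 0; q < n && keep; ++q) {
          int u1 = t1 + offs(q, 0), u2 = t2 + offs(q, 1), u3 = t3 + offs(q, 2);
          if (u1 < 0 || u1 >= D1 || u2 < 0 || u2 >= D2 || u3 < 0 || u3 >= D3) {
            keep = 0;  // treat outside as background
          } else if (!m[u1 + D1 * (u2 + D2 * u3)]) {
            keep = 0;
          }
        }
        out[ii] = keep;
      }
  return out;
}

// 6-connected component labelling of a binary 3D mask. Labels start at 1.
// [[Rcpp::export]]
IntegerVector cpp_label6(IntegerVector m, int D1, int D2, int D3) {
  IntegerVector lab(m.size());
  std::vector<int> stack;
  int next = 0;
  const int d1[6] = {1, -1, 0, 0, 0, 0};
  const int d2[6] = {0, 0, 1, -1, 0, 0};
  const int d3[6] = {0, 0, 0, 0, 1, -1};
  for (int start = 0; start < m.size(); ++start) {
    if (!m[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      int t1 = v % D1, rest = v / D1;
      int t2 = rest % D2, t3 = rest / D2;
      for (int q = 0; q < 6; ++q) {
        int u1 = t1 + d1[q], u2 = t2 + d2[q], u3 = t3 + d3[q];
        if (u1 < 0 || u1 >= D1 || u2 < 0 || u2 >= D2 || u3 < 0 || u3 >= D3)
          continue;
        int uu = u1 + D1 * (u2 + D2 * u3);
        if (m[uu] && !lab[uu]) {
          lab[uu] = next;
          stack.push_back(uu);
        }
      }
    }
  }
  return lab;
}
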