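// 3D connected-component labelling and threshold-free cluster enhancement.
// Hot path of the permutation engine: one TFCE evaluation per permutation.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// neighbour offsets for 6/18/26-connectivity in (dx,dy,dz)
void neighbour_offsets(int conn, std::vector<int> &dx, std::vector<int> &dy,
                       std::vector<int> &dz) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nz = std::abs(a) + std::abs(b) + std::abs(c);
        if (nz == 0) continue;
        if (conn == 6 && nz > 1) continue;
        if (conn == 18 && nz > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// flood-fill labelling of `in` (true = foreground); labels start at 1,
// 0 = background.  Returns number of components; sizes[l-1] = voxels in l.
int label_components(const std::vector<char> &in, int nx, int ny, int nz,
                     const std::vector<int> &dx, const std::vector<int> &dy,
                     const std::vector<int> &dz,
                     std::vector<int> &labels, std::vector<int> &sizes,
                     std::vector<int> &stack) {
  const int n = nx * ny * nz;
  std::fill(labels.begin(), labels.end(), 0);
  sizes.clear();
  int ncomp = 0;
  const int nd = (int)dx.size();
  for (int i = 0; i < n; ++i) {
    if (!in[i] || labels[i]) continue;
    ++ncomp;
    int sz = 0;
    stack.clear();
    stack.push_back(i);
    labels[i] = ncomp;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      ++sz;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int k = 0; k < nd; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (in[w] && !labels[w]) { labels[w] = ncomp; stack.push_back(w); }
      }
    }
    sizes.push_back(sz);
  }
  return ncomp;
}

} // namespace

// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int conn) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<int> dx, dy, dz;
  neighbour_offsets(conn, dx, dy, dz);
  std::vector<char> in(n);
  for (int i = 0; i < n; ++i) in[i] = (mask[i] == TRUE);
  std::vector<int> labels(n), sizes, stack;
  label_components(in, nx, ny, nz, dx, dy, dz, labels, sizes, stack);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = labels[i];
  out.attr("dim") = dims;
  return out;
}

// TFCE of the positive part of a 3D statistic map: for each voxel,
// sum over h = dh, 2dh, ... <= stat[v] of e(h)^E * h^H * dh, where e(h) is
// the size of the suprathreshold (stat >= h) component containing v.
// The suprathreshold set shrinks as h rises, so only the surviving voxel
// list is scanned per step; foreground membership and labels use per-step
// stamps so nothing is reset between steps.
// [[Rcpp::export(name = ".cpp_tfce")]]
NumericVector cpp_tfce(NumericVector stat, IntegerVector dims,
                       double E, double H, double dh, int conn) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  if (stat.size() != n) stop("stat length does not match dims");
  if (dh <= 0) stop("dh must be positive");
  NumericVector out(n);
  double hmax = 0;
  for (int i = 0; i < n; ++i)
    if (stat[i] > hmax) hmax = stat[i];
  if (hmax <= 0) { out.attr("dim") = dims; return out; }
  std::vector<int> dx, dy, dz;
  neighbour_offsets(conn, dx, dy, dz);
  const int nd = (int)dx.size();
  std::vector<int> fg;                      // surviving voxel list
  for (int i = 0; i < n; ++i)
    if (stat[i] >= dh) fg.push_back(i);
  std::vector<int> instep(n, -1);           // stamp: in foreground at step s
  std::vector<int> labstep(n, -1), labels(n);
  std::vector<int> stack, sizes;
  std::vector<double> powsize;
  int nsteps = (int)std::floor(hmax / dh + 1e-12);
  for (int s = 1; s <= nsteps; ++s) {
    double h = s * dh;
    // shrink the survivor list in place and stamp membership
    size_t keep = 0;
    for (size_t q = 0; q < fg.size(); ++q)
      if (stat[fg[q]] >= h) { fg[keep++] = fg[q]; instep[fg[q]] = s; }
    fg.resize(keep);
    // label components among survivors
    int ncomp = 0;
    sizes.clear();
    for (size_t q = 0; q < keep; ++q) {
      int seed = fg[q];
      if (labstep[seed] == s) continue;
      ++ncomp;
      int sz = 0;
      stack.clear();
      stack.push_back(seed);
      labstep[seed] = s; labels[seed] = ncomp;
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        ++sz;
        int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
        for (int k = 0; k < nd; ++k) {
          int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int w = xx + nx * (yy + ny * zz);
          if (instep[w] == s && labstep[w] != s) {
            labstep[w] = s; labels[w] = ncomp;
            stack.push_back(w);
          }
        }
      }
      sizes.push_back(sz);
    }
    double hH = std::pow(h, H) * dh;
    powsize.resize(ncomp);
    for (int c = 0; c < ncomp; ++c)
      powsize[c] = std::pow((double)sizes[c], E) * hH;
    for (size_t q = 0; q < keep; ++q)
      out[fg[q]] += powsize[labels[fg[q]] - 1];
  }
  out.attr("dim") = dims;
  return out;
}
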