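#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// neighbour offsets for 6/18/26 connectivity on a 3D lattice
static std::vector<std::array<int,3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int,3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

static void label_bfs(const std::vector<char>& pass, int nx, int ny, int nz,
                      const std::vector<std::array<int,3>>& off,
                      std::vector<int>& labels, std::vector<int>& sizes) {
  const int V = nx * ny * nz;
  labels.assign(V, 0);
  sizes.clear();
  std::vector<int> queue;
  int next = 0;
  for (int v = 0; v < V; ++v) {
    if (!pass[v] || labels[v]) continue;
    ++next;
    int count = 0;
    queue.clear();
    queue.push_back(v);
    labels[v] = next;
    while (!queue.empty()) {
      int cur = queue.back(); queue.pop_back();
      ++count;
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
      for (const auto& d : off) {
        int x = cx + d[0], y = cy + d[1], z = cz + d[2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        int w = x + nx * (y + ny * z);
        if (pass[w] && !labels[w]) { labels[w] = next; queue.push_back(w); }
      }
    }
    sizes.push_back(count);
  }
}

// [[Rcpp::export(name = ".label_components_cpp")]]
List label_components_cpp(LogicalVector pass, IntegerVector dims,
                          int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((int)pass.size() != nx * ny * nz) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<char> p(pass.size());
  for (int i = 0; i < pass.size(); ++i) p[i] = pass[i] == TRUE;
  auto off = neighbour_offsets(connectivity);
  std::vector<int> labels, sizes;
  label_bfs(p, nx, ny, nz, off, labels, sizes);
  return List::create(_["labels"] = IntegerVector(labels.begin(), labels.end()),
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}

// Freedman-Lane permutation null of the maximum conjunction-cluster size.
//
// Yt: V x N matrix of Fisher-Z maps (rows = in-mask voxels, in the order
//   given by mask_idx); X: N x P full design; age_col: 0-based column of
//   the regressor under test. For each permutation row (0-based subject
//   indices) the reduced-model residuals are permuted, the full model is
//   refit, the one-sided age t-map is thresholded at t_crit in direction
//   age_dir, intersected with the fixed observed main-effect pass set,
//   and the largest connected cluster size is recorded.
// [[Rcpp::export(name = ".fl_max_cluster_cpp")]]
IntegerVector fl_max_cluster_cpp(const arma::mat& Yt, const arma::mat& X,
                                 int age_col, const arma::imat& perms,
                                 LogicalVector main_pass, IntegerVector mask_idx,
                                 IntegerVector dims, double t_crit,
                                 int age_dir, int connectivity,
                                 double t_cap) {
  const int V = Yt.n_rows, N = Yt.n_cols, P = X.n_cols;
  const int n_perm = perms.n_rows;
  if ((int)perms.n_cols != N) stop("permutation matrix has wrong width");
  if (mask_idx.size() != V) stop("mask_idx length must equal nrow(Yt)");
  const int df = N - P;
  if (df <= 0) stop("no residual degrees of freedom");

  arma::mat XtXinv = arma::inv_sympd(X.t() * X);
  double c_aa = XtXinv(age_col, age_col);

  // reduced model (drop age column)
  arma::uvec keep(P - 1);
  for (int j = 0, k = 0; j < P; ++j) if (j != age_col) keep(k++) = j;
  arma::mat Xr = X.cols(keep);
  arma::mat Br = arma::solve(Xr.t() * Xr, Xr.t() * Yt.t()); // (P-1) x V
  arma::mat Ft = (Xr * Br).t();          // fitted reduced, V x N
  arma::mat Rt = Yt - Ft;                // reduced residuals, V x N

  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto off = neighbour_offsets(connectivity);
  std::vector<char> pass((size_t)nx * ny * nz);
  std::vector<int> labels, sizes;

  IntegerVector out(n_perm);
  arma::mat Yp(V, N), XtY(V, P), B(V, P);
  arma::vec rss(V), ysq(V);
  for (int pi = 0; pi < n_perm; ++pi) {
    for (int i = 0; i < N; ++i)
      Yp.col(i) = Ft.col(i) + Rt.col(perms(pi, i));
    XtY = Yp * X;                        // V x P
    B = XtY * XtXinv;                    // V x P coefficient estimates
    rss = arma::sum(Yp % Yp, 1) - arma::sum(XtY % B, 1);
    std::fill(pass.begin(), pass.end(), 0);
    bool any = false;
    for (int v = 0; v < V; ++v) {
      if (main_pass[v] != TRUE) continue;
      double s2 = rss(v) / df;
      double b = B(v, age_col);
      double t;
      if (s2 <= 0) t = (b == 0.0) ? 0.0 : (b > 0 ? t_cap : -t_cap);
      else t = b / std::sqrt(s2 * c_aa);
      if (age_dir * t > t_crit) { pass[mask_idx[v] - 1] = 1; any = true; }
    }
    int mx = 0;
    if (any) {
      label_bfs(pass, nx, ny, nz, off, labels, sizes);
      for (int s : sizes) if (s > mx) mx = s;
    }
    out[pi] = mx;
  }
  return out;
}

// separable Gaussian smoothing of a time-major series: data is T x V with
// voxels in column-major (x fastest) order; one 1D reflect-padded
// convolution per axis, applied volume by volume.
// [[Rcpp::export(name = ".gauss_smooth_cpp")]]
arma::mat gauss_smooth_cpp(const arma::mat& data, IntegerVector dims,
                           NumericVector sigma) {
  const int T = data.n_rows;
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  if ((int)data.n_cols != V) stop("data columns do not match dims");

  // per-axis normalized kernels
  std::array<std::vector<double>,3> ker;
  std::array<int,3> rad;
  for (int a = 0; a < 3; ++a) {
    double s = sigma[a];
    int r = (s > 0) ? std::max(1, (int)std::ceil(4.0 * s)) : 0;
    rad[a] = r;
    std::vector<double> w(2 * r + 1, 1.0);
    if (r > 0) {
      double tot = 0;
      for (int d = -r; d <= r; ++d) {
        w[d + r] = std::exp(-0.5 * d * d / (s * s));
        tot += w[d + r];
      }
      for (auto& x : w) x /= tot;
    }
    ker[a] = w;
  }
  auto reflect = [](int j, int n) {
    while (j < 0 || j >= n) { if (j < 0) j = -1 - j; if (j >= n) j = 2 * n - 1 - j; }
    return j;
  };
  // per-axis table of reflected source offsets: tap d at position i reads
  // from offset idx[a][i * (2r+1) + d]
  std::array<std::vector<int>,3> tap;
  const int sizes[3] = {nx, ny, nz};
  const int strides[3] = {1, nx, nx * ny};
  for (int a = 0; a < 3; ++a) {
    const int n = sizes[a], r = rad[a], w = 2 * r + 1;
    tap[a].resize((size_t)n * w);
    for (int i = 0; i < n; ++i)
      for (int d = -r; d <= r; ++d)
        tap[a][(size_t)i * w + d + r] = reflect(i + d, n) * strides[a];
  }

  arma::mat out = data.t();              // V x T, volumes contiguous
  std::vector<double> buf(V);
  for (int t = 0; t < T; ++t) {
    double* vol = out.colptr(t);
    for (int a = 0; a < 3; ++a) {
      if (rad[a] == 0) continue;
      const int n = sizes[a], st = strides[a];
      const double* w = ker[a].data();
      const int nw = 2 * rad[a] + 1;
      const int* tp = tap[a].data();
      for (int hi = 0; hi < V / (n * st); ++hi)
        for (int lo = 0; lo < st; ++lo) {
          double* line = vol + hi * n * st + lo;
          for (int i = 0; i < n; ++i) {
            double acc = 0;
            const int* ti = tp + (size_t)i * nw;
            for (int d = 0; d < nw; ++d) acc += w[d] * line[ti[d]];
            buf[i] = acc;
          }
          for (int i = 0; i < n; ++i) line[i * st] = buf[i];
        }
    }
  }
  return out.t();
}
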