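#include "moco_utils.h"

using namespace Rcpp;

// [[Rcpp::export(name = ".warp_frame_cpp")]]
NumericMatrix warp_frame_cpp(NumericMatrix frame, NumericMatrix u, NumericMatrix v,
                             bool bilinear) {
    Img im = from_rmat(frame), uu = from_rmat(u), vv = from_rmat(v);
    Img out(im.h, im.w);
    for (int y = 0; y < im.h; ++y)
        for (int x = 0; x < im.w; ++x) {
            double sx = x + uu.at(y, x), sy = y + vv.at(y, x);
            out.at(y, x) = bilinear ? sample_bilinear(im, sx, sy) : sample_nearest(im, sx, sy);
        }
    return to_rmat(out);
}

// Box-mean smoothing of a H x W x T array with replicate padding, applied
// separably along x, y and t.  Diameters kx, ky, kt are odd.
// [[Rcpp::export(name = ".smooth_box3d_cpp")]]
NumericVector smooth_box3d_cpp(NumericVector arr, int kx, int ky, int kt) {
    IntegerVector dim = arr.attr("dim");
    int H = dim[0], W = dim[1], T = dim.size() > 2 ? dim[2] : 1;
    std::vector<double> a(arr.begin(), arr.end()), b(a.size());
    int rx = (kx - 1) / 2, ry = (ky - 1) / 2, rt = (kt - 1) / 2;
    size_t HW = (size_t)H * W;
    // along y (rows)
    for (int t = 0; t < T; ++t)
        for (int x = 0; x < W; ++x)
            for (int y = 0; y < H; ++y) {
                double s = 0.0;
                for (int i = -ry; i <= ry; ++i)
                    s += a[(size_t)t * HW + (size_t)x * H + clampi(y + i, 0, H - 1)];
                b[(size_t)t * HW + (size_t)x * H + y] = s / ky;
            }
    std::swap(a, b);
    // along x (columns)
    for (int t = 0; t < T; ++t)
        for (int y = 0; y < H; ++y)
            for (int x = 0; x < W; ++x) {
                double s = 0.0;
                for (int i = -rx; i <= rx; ++i)
                    s += a[(size_t)t * HW + (size_t)clampi(x + i, 0, W - 1) * H + y];
                b[(size_t)t * HW + (size_t)x * H + y] = s / kx;
            }
    std::swap(a, b);
    // along t
    for (int x = 0; x < W; ++x)
        for (int y = 0; y < H; ++y)
            for (int t = 0; t < T; ++t) {
                double s = 0.0;
                for (int i = -rt; i <= rt; ++i)
                    s += a[(size_t)clampi(t + i, 0, T - 1) * HW + (size_t)x * H + y];
                b[(size_t)t * HW + (size_t)x * H + y] = s / kt;
            }
    NumericVector out(b.begin(), b.end());
    out.attr("dim") = dim;
    return out;
}

// Local contrast enhancement of one frame: per pixel, min/max over the
// disc of pixels within Euclidean distance (k-1)/2 (disc clipped at the
// image borders); flat guard -> 0.
// [[Rcpp::export(name = ".contrast_enhance_frame_cpp")]]
NumericMatrix contrast_enhance_frame_cpp(NumericMatrix frame, int k, double eps) {
    Img im = from_rmat(frame);
    int r = (k - 1) / 2;
    std::vector<std::pair<int, int> > offs;
    for (int dy = -r; dy <= r; ++dy)
        for (int dx = -r; dx <= r; ++dx)
            if (dx * dx + dy * dy <= r * r) offs.push_back(std::make_pair(dy, dx));
    Img out(im.h, im.w);
    for (int y = 0; y < im.h; ++y)
        for (int x = 0; x < im.w; ++x) {
            double mn = R_PosInf, mx = R_NegInf;
            for (size_t i = 0; i < offs.size(); ++i) {
                int yy = y + offs[i].first, xx = x + offs[i].second;
                if (yy < 0 || yy >= im.h || xx < 0 || xx >= im.w) continue;
                double val = im.at(yy, xx);
                if (val < mn) mn = val;
                if (val > mx) mx = val;
            }
            out.at(y, x) = (mx - mn < eps) ? 0.0 : (im.at(y, x) - mn) / (mx - mn);
        }
    return to_rmat(out);
}

// Pixel-wise sliding-window min/max normalization along t.  Window of L
// frames centered on t (indices t - floor((L-1)/2) .. t + floor(L/2)),
// truncated at the video ends; flat guard -> 0.
// [[Rcpp::export(name = ".pixelwise_normalize_cpp")]]
NumericVector pixelwise_normalize_cpp(NumericVector arr, int L, double eps) {
    IntegerVector dim = arr.attr("dim");
    int H = dim[0], W = dim[1], T = dim.size() > 2 ? dim[2] : 1;
    size_t HW = (size_t)H * W;
    NumericVector out(arr.size());
    int lo_off = (L - 1) / 2, hi_off = L / 2;
    for (int x = 0; x < W; ++x)
        for (int y = 0; y < H; ++y) {
            size_t base = (size_t)x * H + y;
            for (int t = 0; t < T; ++t) {
                int t0 = std::max(t - lo_off, 0), t1 = std::min(t + hi_off, T - 1);
                double mn = R_PosInf, mx = R_NegInf;
                for (int s = t0; s <= t1; ++s) {
                    double val = arr[(size_t)s * HW + base];
                    if (val < mn) mn = val;
                    if (val > mx) mx = val;
                }
                double val = arr[(size_t)t * HW + base];
                out[(size_t)t * HW + base] = (mx - mn < eps) ? 0.0 : (val - mn) / (mx - mn);
            }
        }
    out.attr("dim") = dim;
    return out;
}

// Fixed-point inversion of a displacement field: returns w with
// w(z) = -u(z + w(z)), so that sampling at z + w(z) realizes the forward
// push of the field u.
// [[Rcpp::export(name = ".invert_flow_cpp")]]
List invert_flow_cpp(NumericMatrix u, NumericMatrix v, int max_iter, double tol) {
    Img uu = from_rmat(u), vv = from_rmat(v);
    // warm start at -u: exact for locally constant fields
    Img wx(uu.h, uu.w), wy(uu.h, uu.w);
    for (size_t i = 0; i < wx.d.size(); ++i) {
        wx.d[i] = -uu.d[i];
        wy.d[i] = -vv.d[i];
    }
    double max_change = R_PosInf;
    for (int it = 0; it < max_iter && max_change > tol; ++it) {
        max_change = 0.0;
        for (int y = 0; y < uu.h; ++y)
            for (int x = 0; x < uu.w; ++x) {
                double nx = -sample_bilinear(uu, x + wx.at(y, x), y + wy.at(y, x));
                double ny = -sample_bilinear(vv, x + wx.at(y, x), y + wy.at(y, x));
                double ch = std::max(std::fabs(nx - wx.at(y, x)), std::fabs(ny - wy.at(y, x)));
                if (ch > max_change) max_change = ch;
                wx.at(y, x) = nx;
                wy.at(y, x) = ny;
            }
    }
    return List::create(_["u"] = to_rmat(wx), _["v"] = to_rmat(wy),
                        _["converged"] = (max_change <= tol));
}

// [[Rcpp::export(name = ".gaussian_blur_cpp")]]
NumericMatrix gaussian_blur_cpp(NumericMatrix m, double sigma) {
    return to_rmat(gaussian_blur(from_rmat(m), sigma));
}

// [[Rcpp::export(name = ".resize_bilinear_cpp")]]
NumericMatrix resize_bilinear_cpp(NumericMatrix m, int nh, int nw) {
    return to_rmat(resize_bilinear(from_rmat(m), nh, nw));
}
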