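#include "moco_utils.h"

using namespace Rcpp;

// Farneback two-frame motion estimation.
//
// Each image is locally approximated by a quadratic polynomial
// f(dx,dy) ~ r1 + r2 dx + r3 dy + r4 dx^2 + r5 dy^2 + r6 dx dy fitted by
// Gaussian-weighted least squares over a (2n+1)^2 neighborhood (computed
// with separable correlations).  Displacements follow from the polynomial
// coefficients of the two images, accumulated over an averaging window
// and refined iteratively over a coarse-to-fine pyramid.

namespace {

struct PolyExp {
    // coefficient images: b1 (x), b2 (y), a11 (x^2), a22 (y^2), a12 (xy/2)
    Img bx, by, axx, ayy, axy;
};

// Invert a 6x6 SPD-ish matrix by Gauss-Jordan.
static void invert6(double G[6][6], double Gi[6][6]) {
    double a[6][12];
    for (int i = 0; i < 6; ++i)
        for (int j = 0; j < 6; ++j) {
            a[i][j] = G[i][j];
            a[i][j + 6] = (i == j) ? 1.0 : 0.0;
        }
    for (int col = 0; col < 6; ++col) {
        int piv = col;
        for (int i = col + 1; i < 6; ++i)
            if (std::fabs(a[i][col]) > std::fabs(a[piv][col])) piv = i;
        for (int j = 0; j < 12; ++j) std::swap(a[col][j], a[piv][j]);
        double d = a[col][col];
        for (int j = 0; j < 12; ++j) a[col][j] /= d;
        for (int i = 0; i < 6; ++i) {
            if (i == col) continue;
            double f = a[i][col];
            for (int j = 0; j < 12; ++j) a[i][j] -= f * a[col][j];
        }
    }
    for (int i = 0; i < 6; ++i)
        for (int j = 0; j < 6; ++j) Gi[i][j] = a[i][j + 6];
}

// Correlate with sep. kernels kx (horizontal) and ky (vertical), replicate borders.
static Img sep_corr(const Img &im, const std::vector<double> &kxv,
                    const std::vector<double> &kyv) {
    int rx = ((int)kxv.size() - 1) / 2, ry = ((int)kyv.size() - 1) / 2;
    Img tmp(im.h, im.w), out(im.h, im.w);
    for (int y = 0; y < im.h; ++y)
        for (int x = 0; x < im.w; ++x) {
            double s = 0.0;
            for (int i = -rx; i <= rx; ++i)
                s += kxv[i + rx] * im.at(y, clampi(x + i, 0, im.w - 1));
            tmp.at(y, x) = s;
        }
    for (int y = 0; y < im.h; ++y)
        for (int x = 0; x < im.w; ++x) {
            double s = 0.0;
            for (int i = -ry; i <= ry; ++i)
                s += kyv[i + ry] * tmp.at(clampi(y + i, 0, im.h - 1), x);
            out.at(y, x) = s;
        }
    return out;
}

static PolyExp poly_expansion(const Img &im, int n, double sigma) {
    std::vector<double> g(2 * n + 1), xg(2 * n + 1), xxg(2 * n + 1);
    double s = 0.0;
    for (int i = -n; i <= n; ++i) s += std::exp(-0.5 * i * i / (sigma * sigma));
    for (int i = -n; i <= n; ++i) {
        double gi = std::exp(-0.5 * i * i / (sigma * sigma)) / s;
        g[i + n] = gi;
        xg[i + n] = i * gi;
        xxg[i + n] = i * i * gi;
    }
    // G(k,l) = sum w(dx,dy) basis_k basis_l with basis = {1, x, y, x^2, y^2, xy}
    double G[6][6] = {{0}}, Gi[6][6];
    for (int dy = -n; dy <= n; ++dy)
        for (int dx = -n; dx <= n; ++dx) {
            double w = g[dy + n] * g[dx + n];
            double b[6] = {1.0, (double)dx, (double)dy, (double)dx * dx,
                           (double)dy * dy, (double)dx * dy};
            for (int k = 0; k < 6; ++k)
                for (int l = 0; l < 6; ++l) G[k][l] += w * b[k] * b[l];
        }
    invert6(G, Gi);
    // projections p_k = sum w basis_k I
    Img p[6];
    p[0] = sep_corr(im, g, g);
    p[1] = sep_corr(im, xg, g);
    p[2] = sep_corr(im, g, xg);
    p[3] = sep_corr(im, xxg, g);
    p[4] = sep_corr(im, g, xxg);
    p[5] = sep_corr(im, xg, xg);
    PolyExp pe;
    pe.bx = Img(im.h, im.w);
    pe.by = Img(im.h, im.w);
    pe.axx = Img(im.h, im.w);
    pe.ayy = Img(im.h, im.w);
    pe.axy = Img(im.h, im.w);
    for (size_t i = 0; i < im.d.size(); ++i) {
        double r[6] = {0, 0, 0, 0, 0, 0};
        for (int k = 1; k < 6; ++k) {
            double acc = 0.0;
            for (int l = 0; l < 6; ++l) acc += Gi[k][l] * p[l].d[i];
            r[k] = acc;
        }
        pe.bx.d[i] = r[1];
        pe.by.d[i] = r[2];
        pe.axx.d[i] = r[3];
        pe.ayy.d[i] = r[4];
        pe.axy.d[i] = r[5] * 0.5;  // A = [[r4, r6/2], [r6/2, r5]]
    }
    return pe;
}

// One round of displacement estimation given expansions of both images and
// the current flow; returns the updated flow.
static void update_flow(const PolyExp &p0, const PolyExp &p1, Img &u, Img &v,
                        int win, int iters) {
    int h = p0.bx.h, w = p0.bx.w;
    int r = (win - 1) / 2;
    for (int it = 0; it < iters; ++it) {
        Img g11(h, w), g12(h, w), g22(h, w), h1(h, w), h2(h, w);
        for (int y = 0; y < h; ++y)
            for (int x = 0; x < w; ++x) {
                double dx0 = u.at(y, x), dy0 = v.at(y, x);
                // interpolate the second image's expansion coefficients at
                // the exact displaced position so the A*d0 correction is
                // consistent with the sampling point
                double sx = clampd(x + dx0, 0.0, (double)(w - 1));
                double sy = clampd(y + dy0, 0.0, (double)(h - 1));
                dx0 = sx - x;
                dy0 = sy - y;
                double a11 = 0.5 * (p0.axx.at(y, x) + sample_bilinear(p1.axx, sx, sy));
                double a22 = 0.5 * (p0.ayy.at(y, x) + sample_bilinear(p1.ayy, sx, sy));
                double a12 = 0.5 * (p0.axy.at(y, x) + sample_bilinear(p1.axy, sx, sy));
                double dbx = -0.5 * (sample_bilinear(p1.bx, sx, sy) - p0.bx.at(y, x)) +
                             a11 * dx0 + a12 * dy0;
                double dby = -0.5 * (sample_bilinear(p1.by, sx, sy) - p0.by.at(y, x)) +
                             a12 * dx0 + a22 * dy0;
                g11.at(y, x) = a11 * a11 + a12 * a12;
                g12.at(y, x) = a12 * (a11 + a22);
                g22.at(y, x) = a22 * a22 + a12 * a12;
                h1.at(y, x) = a11 * dbx + a12 * dby;
                h2.at(y, x) = a12 * dbx + a22 * dby;
            }
        Img G11 = box_mean(g11, r), G12 = box_mean(g12, r), G22 = box_mean(g22, r);
        Img H1 = box_mean(h1, r), H2 = box_mean(h2, r);
        for (int y = 0; y < h; ++y)
            for (int x = 0; x < w; ++x) {
                double det = G11.at(y, x) * G22.at(y, x) - G12.at(y, x) * G12.at(y, x);
                if (det < 1e-12) continue;  // flat: keep prior flow
                u.at(y, x) = (G22.at(y, x) * H1.at(y, x) - G12.at(y, x) * H2.at(y, x)) / det;
                v.at(y, x) = (G11.at(y, x) * H2.at(y, x) - G12.at(y, x) * H1.at(y, x)) / det;
            }
    }
}

}  // namespace

// [[Rcpp::export(name = ".flow_farneback_cpp")]]
List flow_farneback_cpp(NumericMatrix reference, NumericMatrix frame,
                        double pyr_scale, int levels, int winsize, int iterations,
                        int poly_n, double poly_sigma) {
    Img im0 = from_rmat(reference), im1 = from_rmat(frame);
    int H = im0.h, W = im0.w;
    // pyramid sizes: level l has dimensions scaled by pyr_scale^l
    std::vector<std::pair<int, int> > sizes;
    int min_dim = 4 * poly_n;
    for (int l = 0; l < levels; ++l) {
        double f = std::pow(pyr_scale, l);
        int h = (int)std::lround(H * f), w = (int)std::lround(W * f);
        if (std::min(h, w) < min_dim && l > 0) break;
        sizes.push_back(std::make_pair(h, w));
    }
    int nlev = (int)sizes.size();
    Img u, v;
    for (int l = nlev - 1; l >= 0; --l) {
        int h = sizes[l].first, w = sizes[l].second;
        double f = std::pow(pyr_scale, l);
        double sigma_pre = (f < 1.0) ? 0.5 * std::sqrt(1.0 / (f * f) - 1.0) : 0.0;
        Img r0 = resize_bilinear(gaussian_blur(im0, sigma_pre), h, w);
        Img r1 = resize_bilinear(gaussian_blur(im1, sigma_pre), h, w);
        if (l == nlev - 1) {
            u = Img(h, w);
            v = Img(h, w);
        } else {
            double fx = (double)w / u.w, fy = (double)h / u.h;
            Img u2 = resize_bilinear(u, h, w), v2 = resize_bilinear(v, h, w);
            for (size_t i = 0; i < u2.d.size(); ++i) {
                u2.d[i] *= fx;
                v2.d[i] *= fy;
            }
            u = u2;
            v = v2;
        }
        PolyExp p0 = poly_expansion(r0, poly_n, poly_sigma);
        PolyExp p1 = poly_expansion(r1, poly_n, poly_sigma);
        update_flow(p0, p1, u, v, winsize, iterations);
    }
    return List::create(_["u"] = to_rmat(u), _["v"] = to_rmat(v));
}
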