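#include "moco_utils.h"

using namespace Rcpp;

// Duality-based TV-L1 optical flow (Zach-type primal-dual scheme with
// warping, coarse-to-fine).  The data term is the linearized brightness
// residual; the flow is regularized by total variation with an L1 data
// penalty, solved by alternating a pointwise thresholding step with a
// projected dual ascent on the TV term.

namespace {

static void forward_grad(const Img &f, Img &fx, Img &fy) {
    fx = Img(f.h, f.w);
    fy = Img(f.h, f.w);
    for (int y = 0; y < f.h; ++y)
        for (int x = 0; x < f.w; ++x) {
            fx.at(y, x) = (x < f.w - 1) ? f.at(y, x + 1) - f.at(y, x) : 0.0;
            fy.at(y, x) = (y < f.h - 1) ? f.at(y + 1, x) - f.at(y, x) : 0.0;
        }
}

static void divergence(const Img &px, const Img &py, Img &div) {
    div = Img(px.h, px.w);
    for (int y = 0; y < px.h; ++y)
        for (int x = 0; x < px.w; ++x) {
            double dx = (x == 0) ? px.at(y, 0)
                        : (x == px.w - 1) ? -px.at(y, x - 1)
                                          : px.at(y, x) - px.at(y, x - 1);
            double dy = (y == 0) ? py.at(0, x)
                        : (y == px.h - 1) ? -py.at(y - 1, x)
                                          : py.at(y, x) - py.at(y - 1, x);
            div.at(y, x) = dx + dy;
        }
}

static void tvl1_level(const Img &I0, const Img &I1, Img &u1, Img &u2,
                       double tau, double lambda, double theta, int warps,
                       double epsilon, int max_iter, bool use_median) {
    int h = I0.h, w = I0.w;
    double l_t = lambda * theta;
    Img I1x, I1y;
    gradients(I1, I1x, I1y);
    Img p11(h, w), p12(h, w), p21(h, w), p22(h, w);
    for (int wi = 0; wi < warps; ++wi) {
        Img I1w = warp_image(I1, u1, u2);
        Img I1wx = warp_image(I1x, u1, u2);
        Img I1wy = warp_image(I1y, u1, u2);
        Img grad(h, w), rho_c(h, w);
        for (size_t i = 0; i < grad.d.size(); ++i) {
            grad.d[i] = I1wx.d[i] * I1wx.d[i] + I1wy.d[i] * I1wy.d[i];
            rho_c.d[i] = I1w.d[i] - I1wx.d[i] * u1.d[i] - I1wy.d[i] * u2.d[i] - I0.d[i];
        }
        double err = R_PosInf;
        for (int it = 0; it < max_iter && err > epsilon * epsilon; ++it) {
            // thresholding step (pointwise minimization of the data term)
            Img v1(h, w), v2(h, w);
            for (size_t i = 0; i < v1.d.size(); ++i) {
                double rho = rho_c.d[i] + I1wx.d[i] * u1.d[i] + I1wy.d[i] * u2.d[i];
                double d1, d2;
                if (rho < -l_t * grad.d[i]) {
                    d1 = l_t * I1wx.d[i];
                    d2 = l_t * I1wy.d[i];
                } else if (rho > l_t * grad.d[i]) {
                    d1 = -l_t * I1wx.d[i];
                    d2 = -l_t * I1wy.d[i];
                } else if (grad.d[i] > 1e-10) {
                    d1 = -rho / grad.d[i] * I1wx.d[i];
                    d2 = -rho / grad.d[i] * I1wy.d[i];
                } else {
                    d1 = d2 = 0.0;
                }
                v1.d[i] = u1.d[i] + d1;
                v2.d[i] = u2.d[i] + d2;
            }
            // TV proximal step via the dual variables
            Img div1, div2;
            divergence(p11, p12, div1);
            divergence(p21, p22, div2);
            err = 0.0;
            for (size_t i = 0; i < v1.d.size(); ++i) {
                double n1 = v1.d[i] + theta * div1.d[i];
                double n2 = v2.d[i] + theta * div2.d[i];
                err += (n1 - u1.d[i]) * (n1 - u1.d[i]) + (n2 - u2.d[i]) * (n2 - u2.d[i]);
                u1.d[i] = n1;
                u2.d[i] = n2;
            }
            err /= (double)h * w;
            Img u1x, u1y, u2x, u2y;
            forward_grad(u1, u1x, u1y);
            forward_grad(u2, u2x, u2y);
            double tt = tau / theta;
            for (size_t i = 0; i < u1x.d.size(); ++i) {
                double ng1 = 1.0 + tt * std::sqrt(u1x.d[i] * u1x.d[i] + u1y.d[i] * u1y.d[i]);
                double ng2 = 1.0 + tt * std::sqrt(u2x.d[i] * u2x.d[i] + u2y.d[i] * u2y.d[i]);
                p11.d[i] = (p11.d[i] + tt * u1x.d[i]) / ng1;
                p12.d[i] = (p12.d[i] + tt * u1y.d[i]) / ng1;
                p21.d[i] = (p21.d[i] + tt * u2x.d[i]) / ng2;
                p22.d[i] = (p22.d[i] + tt * u2y.d[i]) / ng2;
            }
        }
        if (use_median) {
            u1 = median5(u1);
            u2 = median5(u2);
        }
    }
}

}  // namespace

// [[Rcpp::export(name = ".flow_tvl1_cpp")]]
List flow_tvl1_cpp(NumericMatrix reference, NumericMatrix frame, double tau,
                   double lambda, double theta, int nscales, int warps,
                   double epsilon, int max_iter, bool use_median) {
    Img im0 = from_rmat(reference), im1 = from_rmat(frame);
    // the data-vs-smoothness balance (lambda) is calibrated for a 0..255
    // intensity scale; unit-range inputs are rescaled internally
    for (size_t i = 0; i < im0.d.size(); ++i) {
        im0.d[i] *= 255.0;
        im1.d[i] *= 255.0;
    }
    std::vector<Img> p0(1, im0), p1(1, im1);
    for (int l = 1; l < nscales; ++l) {
        if (std::min(p0.back().h, p0.back().w) < 32) break;
        p0.push_back(pyr_down(p0.back()));
        p1.push_back(pyr_down(p1.back()));
    }
    int nlev = (int)p0.size();
    Img u1(p0[nlev - 1].h, p0[nlev - 1].w), u2(p0[nlev - 1].h, p0[nlev - 1].w);
    for (int l = nlev - 1; l >= 0; --l) {
        if (l < nlev - 1) {
            double fx = (double)p0[l].w / u1.w, fy = (double)p0[l].h / u1.h;
            Img a = resize_bilinear(u1, p0[l].h, p0[l].w);
            Img b = resize_bilinear(u2, p0[l].h, p0[l].w);
            for (size_t i = 0; i < a.d.size(); ++i) {
                a.d[i] *= fx;
                b.d[i] *= fy;
            }
            u1 = a;
            u2 = b;
        }
        tvl1_level(p0[l], p1[l], u1, u2, tau, lambda, theta, warps, epsilon,
                   max_iter, use_median);
    }
    return List::create(_["u"] = to_rmat(u1), _["v"] = to_rmat(u2));
}
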