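#include "moco_utils.h"

using namespace Rcpp;

// Brox-style variational optical flow: brightness + gradient constancy
// data terms with a robust penalty Psi(s^2) = sqrt(s^2 + eps^2), TV-like
// robust smoothness, solved coarse-to-fine with warping.  At each level,
// an outer fixed-point loop linearizes the data terms and updates the
// robustness weights; the resulting linear system is relaxed with SOR.

namespace {

const double PSI_EPS2 = 1e-6;  // eps = 1e-3 on unit intensities

inline double psi_deriv(double s2) { return 0.5 / std::sqrt(s2 + PSI_EPS2); }

static void brox_level(const Img &I0, const Img &I1, Img &u, Img &v, double alpha,
                       double gamma, int outer, int inner, int solver) {
    int h = I0.h, w = I0.w;
    Img I1x, I1y;
    gradients(I1, I1x, I1y);
    Img I0x, I0y;
    gradients(I0, I0x, I0y);
    for (int wi = 0; wi < outer; ++wi) {
        Img I1w = warp_image(I1, u, v);
        Img Ix = warp_image(I1x, u, v);
        Img Iy = warp_image(I1y, u, v);
        Img Ixx, Ixy, Iyy, tmp;
        gradients(Ix, Ixx, Ixy);
        gradients(Iy, tmp, Iyy);
        Img It(h, w), Ixt(h, w), Iyt(h, w);
        for (size_t i = 0; i < It.d.size(); ++i) {
            It.d[i] = I1w.d[i] - I0.d[i];
            Ixt.d[i] = Ix.d[i] - I0x.d[i];
            Iyt.d[i] = Iy.d[i] - I0y.d[i];
        }
        Img du(h, w), dv(h, w);
        for (int in = 0; in < inner; ++in) {
            // data-term robustness weights at current (du, dv)
            Img wd(h, w), wg(h, w);
            for (int y = 0; y < h; ++y)
                for (int x = 0; x < w; ++x) {
                    double iz = It.at(y, x) + Ix.at(y, x) * du.at(y, x) +
                                Iy.at(y, x) * dv.at(y, x);
                    double ixz = Ixt.at(y, x) + Ixx.at(y, x) * du.at(y, x) +
                                 Ixy.at(y, x) * dv.at(y, x);
                    double iyz = Iyt.at(y, x) + Ixy.at(y, x) * du.at(y, x) +
                                 Iyy.at(y, x) * dv.at(y, x);
                    wd.at(y, x) = psi_deriv(iz * iz);
                    wg.at(y, x) = psi_deriv(ixz * ixz + iyz * iyz);
                }
            // smoothness weights at u+du (per pixel, central differences)
            Img uc(h, w), vc(h, w);
            for (size_t i = 0; i < uc.d.size(); ++i) {
                uc.d[i] = u.d[i] + du.d[i];
                vc.d[i] = v.d[i] + dv.d[i];
            }
            Img ux, uy, vx, vy;
            gradients(uc, ux, uy);
            gradients(vc, vx, vy);
            Img ws(h, w);
            for (size_t i = 0; i < ws.d.size(); ++i)
                ws.d[i] = psi_deriv(ux.d[i] * ux.d[i] + uy.d[i] * uy.d[i] +
                                    vx.d[i] * vx.d[i] + vy.d[i] * vy.d[i]);
            const double omega = 1.9;
            for (int so = 0; so < solver; ++so) {
                for (int y = 0; y < h; ++y)
                    for (int x = 0; x < w; ++x) {
                        double a11 = wd.at(y, x) * Ix.at(y, x) * Ix.at(y, x) +
                                     gamma * wg.at(y, x) *
                                         (Ixx.at(y, x) * Ixx.at(y, x) +
                                          Ixy.at(y, x) * Ixy.at(y, x));
                        double a22 = wd.at(y, x) * Iy.at(y, x) * Iy.at(y, x) +
                                     gamma * wg.at(y, x) *
                                         (Iyy.at(y, x) * Iyy.at(y, x) +
                                          Ixy.at(y, x) * Ixy.at(y, x));
                        double a12 = wd.at(y, x) * Ix.at(y, x) * Iy.at(y, x) +
                                     gamma * wg.at(y, x) * Ixy.at(y, x) *
                                         (Ixx.at(y, x) + Iyy.at(y, x));
                        double b1 = -(wd.at(y, x) * Ix.at(y, x) * It.at(y, x) +
                                      gamma * wg.at(y, x) *
                                          (Ixx.at(y, x) * Ixt.at(y, x) +
                                           Ixy.at(y, x) * Iyt.at(y, x)));
                        double b2 = -(wd.at(y, x) * Iy.at(y, x) * It.at(y, x) +
                                      gamma * wg.at(y, x) *
                                          (Ixy.at(y, x) * Ixt.at(y, x) +
                                           Iyy.at(y, x) * Iyt.at(y, x)));
                        double sw = 0.0, su = 0.0, sv = 0.0;
                        int nb[4][2] = {{y - 1, x}, {y + 1, x}, {y, x - 1}, {y, x + 1}};
                        for (int k = 0; k < 4; ++k) {
                            int yy = nb[k][0], xx = nb[k][1];
                            if (yy < 0 || yy >= h || xx < 0 || xx >= w) continue;
                            double we = 0.5 * (ws.at(y, x) + ws.at(yy, xx));
                            sw += we;
                            su += we * (u.at(yy, xx) + du.at(yy, xx) - u.at(y, x));
                            sv += we * (v.at(yy, xx) + dv.at(yy, xx) - v.at(y, x));
                        }
                        double A11 = a11 + alpha * sw, A22 = a22 + alpha * sw;
                        double A12 = a12;
                        double r1 = b1 + alpha * su;
                        double r2 = b2 + alpha * sv;
                        double det = A11 * A22 - A12 * A12;
                        if (det < 1e-12) continue;
                        double ndu = (A22 * r1 - A12 * r2) / det;
                        double ndv = (A11 * r2 - A12 * r1) / det;
                        du.at(y, x) += omega * (ndu - du.at(y, x));
                        dv.at(y, x) += omega * (ndv - dv.at(y, x));
                    }
            }
        }
        // the linearized data terms are only valid for sub-pixel increments;
        // clamp each warp's update so the fixed-point iteration stays in range
        for (size_t i = 0; i < u.d.size(); ++i) {
            u.d[i] += clampd(du.d[i], -1.0, 1.0);
            v.d[i] += clampd(dv.d[i], -1.0, 1.0);
        }
    }
}

}  // namespace

// [[Rcpp::export(name = ".flow_brox_cpp")]]
List flow_brox_cpp(NumericMatrix reference, NumericMatrix frame, double alpha,
                   double gamma, double scale_factor, int inner_iterations,
                   int outer_iterations, int solver_iterations) {
    Img im0 = from_rmat(reference), im1 = from_rmat(frame);
    int H = im0.h, W = im0.w;
    std::vector<std::pair<int, int> > sizes;
    double f = 1.0;
    while (true) {
        int h = (int)std::lround(H * f), w = (int)std::lround(W * f);
        if (std::min(h, w) < 16 && !sizes.empty()) break;
        sizes.push_back(std::make_pair(h, w));
        if (std::min(h, w) <= 16) break;
        f *= scale_factor;
    }
    int nlev = (int)sizes.size();
    Img u, v;
    for (int l = nlev - 1; l >= 0; --l) {
        int h = sizes[l].first, w = sizes[l].second;
        double fl = (double)w / W;
        double sigma_pre = (fl < 1.0) ? 0.5 * std::sqrt(1.0 / (fl * fl) - 1.0) : 0.0;
        Img r0 = resize_bilinear(gaussian_blur(im0, sigma_pre), h, w);
        Img r1 = resize_bilinear(gaussian_blur(im1, sigma_pre), h, w);
        if (l == nlev - 1) {
            u = Img(h, w);
            v = Img(h, w);
        } else {
            double fx = (double)w / u.w, fy = (double)h / u.h;
            Img a = resize_bilinear(u, h, w), b = resize_bilinear(v, h, w);
            for (size_t i = 0; i < a.d.size(); ++i) {
                a.d[i] *= fx;
                b.d[i] *= fy;
            }
            u = a;
            v = b;
        }
        brox_level(r0, r1, u, v, alpha, gamma, outer_iterations, inner_iterations,
                   solver_iterations);
    }
    return List::create(_["u"] = to_rmat(u), _["v"] = to_rmat(v));
}
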