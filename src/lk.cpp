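#include "moco_utils.h"

using namespace Rcpp;

// Dense pyramidal Lucas-Kanade.
//
// Coarse-to-fine scheme on factor-2 Gaussian pyramids.  At each level the
// moving frame is warped by the current flow and the per-pixel 2x2 normal
// equations are accumulated over an unweighted square window, using the
// average of the reference and warped-frame gradients (a symmetric
// linearization, second-order accurate in the displacement).  Where the
// smaller eigenvalue of the window-averaged structure tensor falls below
// `eig_thresh` the incoming (upsampled) flow is kept.  Per-pass updates
// are clamped to one pixel -- the validity range of the linearization --
// and the pass loop stops once the update is negligible.
// [[Rcpp::export(name = ".flow_lk_cpp")]]
List flow_lk_cpp(NumericMatrix reference, NumericMatrix frame, int levels,
                 int window, int iterations, double eig_thresh) {
    Img ref0 = from_rmat(reference), frm0 = from_rmat(frame);
    int H = ref0.h, W = ref0.w;
    int max_levels = (int)std::floor(std::log2((double)std::min(H, W) / 32.0)) + 1;
    if (max_levels < 1) max_levels = 1;
    int nlev = std::min(levels, max_levels);

    std::vector<Img> pyr_ref(nlev), pyr_frm(nlev);
    pyr_ref[0] = ref0;
    pyr_frm[0] = frm0;
    for (int l = 1; l < nlev; ++l) {
        pyr_ref[l] = pyr_down(pyr_ref[l - 1]);
        pyr_frm[l] = pyr_down(pyr_frm[l - 1]);
    }

    int r = (window - 1) / 2;
    Img u, v;
    for (int l = nlev - 1; l >= 0; --l) {
        // light per-level smoothing: wavelengths near the pixel pitch are
        // invisible to central-difference gradients and destabilize the
        // fixed-point updates
        Img ref = gaussian_blur(pyr_ref[l], 1.0);
        Img frm = gaussian_blur(pyr_frm[l], 1.0);
        if (l == nlev - 1) {
            u = Img(ref.h, ref.w);
            v = Img(ref.h, ref.w);
        } else {
            double fx = (double)ref.w / u.w, fy = (double)ref.h / u.h;
            Img u2 = resize_bilinear(u, ref.h, ref.w), v2 = resize_bilinear(v, ref.h, ref.w);
            for (size_t i = 0; i < u2.d.size(); ++i) {
                u2.d[i] *= fx;
                v2.d[i] *= fy;
            }
            u = u2;
            v = v2;
        }
        Img rx, ry;
        gradients(ref, rx, ry);
        for (int it = 0; it < iterations; ++it) {
            Img warped = warp_image(frm, u, v);
            Img wx, wy;
            gradients(warped, wx, wy);
            Img gxx(ref.h, ref.w), gxy(ref.h, ref.w), gyy(ref.h, ref.w);
            Img gxt(ref.h, ref.w), gyt(ref.h, ref.w);
            for (size_t i = 0; i < warped.d.size(); ++i) {
                double gx = 0.5 * (rx.d[i] + wx.d[i]);
                double gy = 0.5 * (ry.d[i] + wy.d[i]);
                double dt = warped.d[i] - ref.d[i];
                gxx.d[i] = gx * gx;
                gxy.d[i] = gx * gy;
                gyy.d[i] = gy * gy;
                gxt.d[i] = gx * dt;
                gyt.d[i] = gy * dt;
            }
            Img Sxx = box_mean(gxx, r), Sxy = box_mean(gxy, r), Syy = box_mean(gyy, r);
            Img Sxt = box_mean(gxt, r), Syt = box_mean(gyt, r);
            Img du(ref.h, ref.w), dv(ref.h, ref.w);
            for (int y = 0; y < ref.h; ++y)
                for (int x = 0; x < ref.w; ++x) {
                    double a = Sxx.at(y, x), b = Sxy.at(y, x), c = Syy.at(y, x);
                    double tr = a + c, det = a * c - b * b;
                    double disc = tr * tr / 4.0 - det;
                    double lam_min = tr / 2.0 - std::sqrt(std::max(disc, 0.0));
                    if (lam_min < eig_thresh) continue;  // keep incoming flow
                    double b1 = -Sxt.at(y, x), b2 = -Syt.at(y, x);
                    du.at(y, x) = clampd((c * b1 - b * b2) / det, -1.0, 1.0);
                    dv.at(y, x) = clampd((a * b2 - b * b1) / det, -1.0, 1.0);
                }
            // a 3x3 average of the update suppresses the grid-frequency
            // modes the symmetric gradient cannot observe
            du = box_mean(du, 1);
            dv = box_mean(dv, 1);
            double max_step = 0.0;
            for (size_t i = 0; i < du.d.size(); ++i) {
                u.d[i] += du.d[i];
                v.d[i] += dv.d[i];
                double st = std::max(std::fabs(du.d[i]), std::fabs(dv.d[i]));
                if (st > max_step) max_step = st;
            }
            if (max_step < 1e-3) break;
        }
    }
    return List::create(_["u"] = to_rmat(u), _["v"] = to_rmat(v));
}
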