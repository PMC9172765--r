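#ifndef MOCO_UTILS_H
#define MOCO_UTILS_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

// Row-major single-channel float image used by the flow backends.
struct Img {
    int h, w;
    std::vector<double> d;
    Img() : h(0), w(0) {}
    Img(int h_, int w_, double v = 0.0) : h(h_), w(w_), d((size_t)h_ * w_, v) {}
    inline double &at(int y, int x) { return d[(size_t)y * w + x]; }
    inline double at(int y, int x) const { return d[(size_t)y * w + x]; }
};

inline int clampi(int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); }
inline double clampd(double v, double lo, double hi) { return v < lo ? lo : (v > hi ? hi : v); }

// Bilinear sample with clamp-to-edge (replicate) boundary handling.
inline double sample_bilinear(const Img &im, double x, double y) {
    x = clampd(x, 0.0, (double)(im.w - 1));
    y = clampd(y, 0.0, (double)(im.h - 1));
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    int x1 = std::min(x0 + 1, im.w - 1), y1 = std::min(y0 + 1, im.h - 1);
    double fx = x - x0, fy = y - y0;
    return (1 - fy) * ((1 - fx) * im.at(y0, x0) + fx * im.at(y0, x1)) +
           fy * ((1 - fx) * im.at(y1, x0) + fx * im.at(y1, x1));
}

inline double sample_nearest(const Img &im, double x, double y) {
    int xi = clampi((int)std::lround(x), 0, im.w - 1);
    int yi = clampi((int)std::lround(y), 0, im.h - 1);
    return im.at(yi, xi);
}

Img from_rmat(const Rcpp::NumericMatrix &m);
Rcpp::NumericMatrix to_rmat(const Img &im);

// out(y, x) = im(y + v(y,x), x + u(y,x)), bilinear, clamped.
Img warp_image(const Img &im, const Img &u, const Img &v);
// Central-difference gradients with replicate borders.
void gradients(const Img &im, Img &gx, Img &gy);
// Separable Gaussian blur, replicate borders; radius = ceil(3 sigma).
Img gaussian_blur(const Img &im, double sigma);
// Box mean over a (2r+1)^2 window clipped at the image borders (true mean
// of the in-image pixels), via integral images.
Img box_mean(const Img &im, int r);
// Bilinear resize to (nh, nw) treating pixel centres on a uniform grid.
Img resize_bilinear(const Img &im, int nh, int nw);
// Gaussian 5-tap pyramid downsampling to ceil(h/2) x ceil(w/2).
Img pyr_down(const Img &im);
// 5x5 median filter (replicate borders).
Img median5(const Img &im);

#endif
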