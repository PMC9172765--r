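#include "moco_utils.h"

using namespace Rcpp;

Img from_rmat(const NumericMatrix &m) {
    Img im(m.nrow(), m.ncol());
    for (int x = 0; x < im.w; ++x)
        for (int y = 0; y < im.h; ++y) im.at(y, x) = m(y, x);
    return im;
}

NumericMatrix to_rmat(const Img &im) {
    NumericMatrix m(im.h, im.w);
    for (int x = 0; x < im.w; ++x)
        for (int y = 0; y < im.h; ++y) m(y, x) = im.at(y, x);
    return m;
}

Img warp_image(const Img &im, const Img &u, const Img &v) {
    Img out(im.h, im.w);
    for (int y = 0; y < im.h; ++y)
        for (int x = 0; x < im.w; ++x)
            out.at(y, x) = sample_bilinear(im, x + u.at(y, x), y + v.at(y, x));
    return out;
}

void gradients(const Img &im, Img &gx, Img &gy) {
    gx = Img(im.h, im.w);
    gy = Img(im.h, im.w);
    for (int y = 0; y < im.h; ++y)
        for (int x = 0; x < im.w; ++x) {
            int xm = std::max(x - 1, 0), xp = std::min(x + 1, im.w - 1);
            int ym = std::max(y - 1, 0), yp = std::min(y + 1, im.h - 1);
            gx.at(y, x) = 0.5 * (im.at(y, xp) - im.at(y, xm));
            gy.at(y, x) = 0.5 * (im.at(yp, x) - im.at(ym, x));
        }
}

static std::vector<double> gauss_kernel(double sigma, int r) {
    std::vector<double> k(2 * r + 1);
    double s = 0.0;
    for (int i = -r; i <= r; ++i) {
        k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
        s += k[i + r];
    }
    for (double &v : k) v /= s;
    return k;
}

Img gaussian_blur(const Img &im, double sigma) {
    if (sigma <= 0) return im;
    int r = (int)std::ceil(3.0 * sigma);
    std::vector<double> k = gauss_kernel(sigma, r);
    Img tmp(im.h, im.w), out(im.h, im.w);
    for (int y = 0; y < im.h; ++y)
        for (int x = 0; x < im.w; ++x) {
            double s = 0.0;
            for (int i = -r; i <= r; ++i) s += k[i + r] * im.at(y, clampi(x + i, 0, im.w - 1));
            tmp.at(y, x) = s;
        }
    for (int y = 0; y < im.h; ++y)
        for (int x = 0; x < im.w; ++x) {
            double s = 0.0;
            for (int i = -r; i <= r; ++i) s += k[i + r] * tmp.at(clampi(y + i, 0, im.h - 1), x);
            out.at(y, x) = s;
        }
    return out;
}

Img box_mean(const Img &im, int r) {
    // integral image with one row/col of zero padding
    int h = im.h, w = im.w;
    std::vector<double> ii((size_t)(h + 1) * (w + 1), 0.0);
    for (int y = 0; y < h; ++y) {
        double rowsum = 0.0;
        for (int x = 0; x < w; ++x) {
            rowsum += im.at(y, x);
            ii[(size_t)(y + 1) * (w + 1) + (x + 1)] = ii[(size_t)y * (w + 1) + (x + 1)] + rowsum;
        }
    }
    Img out(h, w);
    for (int y = 0; y < h; ++y)
        for (int x = 0; x < w; ++x) {
            int y0 = std::max(y - r, 0), y1 = std::min(y + r, h - 1);
            int x0 = std::max(x - r, 0), x1 = std::min(x + r, w - 1);
            double s = ii[(size_t)(y1 + 1) * (w + 1) + (x1 + 1)] -
                       ii[(size_t)y0 * (w + 1) + (x1 + 1)] -
                       ii[(size_t)(y1 + 1) * (w + 1) + x0] + ii[(size_t)y0 * (w + 1) + x0];
            out.at(y, x) = s / ((y1 - y0 + 1) * (x1 - x0 + 1));
        }
    return out;
}

Img resize_bilinear(const Img &im, int nh, int nw) {
    Img out(nh, nw);
    double sy = (nh > 1) ? (double)(im.h - 1) / (nh - 1) : 0.0;
    double sx = (nw > 1) ? (double)(im.w - 1) / (nw - 1) : 0.0;
    for (int y = 0; y < nh; ++y)
        for (int x = 0; x < nw; ++x)
            out.at(y, x) = sample_bilinear(im, x * sx, y * sy);
    return out;
}

Img pyr_down(const Img &im) {
    static const double k[5] = {1.0 / 16, 4.0 / 16, 6.0 / 16, 4.0 / 16, 1.0 / 16};
    Img tmp(im.h, im.w), blur(im.h, im.w);
    for (int y = 0; y < im.h; ++y)
        for (int x = 0; x < im.w; ++x) {
            double s = 0.0;
            for (int i = -2; i <= 2; ++i) s += k[i + 2] * im.at(y, clampi(x + i, 0, im.w - 1));
            tmp.at(y, x) = s;
        }
    for (int y = 0; y < im.h; ++y)
        for (int x = 0; x < im.w; ++x) {
            double s = 0.0;
            for (int i = -2; i <= 2; ++i) s += k[i + 2] * tmp.at(clampi(y + i, 0, im.h - 1), x);
            blur.at(y, x) = s;
        }
    int nh = (im.h + 1) / 2, nw = (im.w + 1) / 2;
    Img out(nh, nw);
    for (int y = 0; y < nh; ++y)
        for (int x = 0; x < nw; ++x)
            out.at(y, x) = blur.at(std::min(2 * y, im.h - 1), std::min(2 * x, im.w - 1));
    return out;
}

Img median5(const Img &im) {
    Img out(im.h, im.w);
    double buf[25];
    for (int y = 0; y < im.h; ++y)
        for (int x = 0; x < im.w; ++x) {
            int n = 0;
            for (int dy = -2; dy <= 2; ++dy)
                for (int dx = -2; dx <= 2; ++dx)
                    buf[n++] = im.at(clampi(y + dy, 0, im.h - 1), clampi(x + dx, 0, im.w - 1));
            std::nth_element(buf, buf + 12, buf + 25);
            out.at(y, x) = buf[12];
        }
    return out;
}
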