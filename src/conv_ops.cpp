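// Convolution and pooling primitives for the 2D CNN. Valid padding,
// stride 1, column-major layouts matching R arrays: inputs (H, W, C, B),
// kernels (k, k, C, F). GEMM goes through R's BLAS.
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

static NumericVector makeArr4(int a, int b, int c, int d) {
    NumericVector v((R_xlen_t)a * b * c * d);
    v.attr("dim") = IntegerVector::create(a, b, c, d);
    return v;
}

static void im2col(const double* x, int H, int W, int C, int k,
                   double* col /* (Ho*Wo) x (k*k*C) */) {
    const int Ho = H - k + 1, Wo = W - k + 1, P = Ho * Wo;
    for (int c = 0; c < C; ++c)
        for (int kw = 0; kw < k; ++kw)
            for (int kh = 0; kh < k; ++kh) {
                double* dst = col + (std::size_t)P * (kh + k * kw + k * k * c);
                const double* src = x + (std::size_t)H * W * c;
                for (int wo = 0; wo < Wo; ++wo) {
                    const double* s = src + (std::size_t)H * (wo + kw) + kh;
                    std::copy(s, s + Ho, dst + (std::size_t)Ho * wo);
                }
            }
}

static void col2im(const double* col, int H, int W, int C, int k,
                   double* x /* accumulated */) {
    const int Ho = H - k + 1, Wo = W - k + 1, P = Ho * Wo;
    for (int c = 0; c < C; ++c)
        for (int kw = 0; kw < k; ++kw)
            for (int kh = 0; kh < k; ++kh) {
                const double* src =
                    col + (std::size_t)P * (kh + k * kw + k * k * c);
                double* dst = x + (std::size_t)H * W * c;
                for (int wo = 0; wo < Wo; ++wo) {
                    double* d = dst + (std::size_t)H * (wo + kw) + kh;
                    const double* s = src + (std::size_t)Ho * wo;
                    for (int ho = 0; ho < Ho; ++ho) d[ho] += s[ho];
                }
            }
}

// [[Rcpp::export(name = ".convForward")]]
NumericVector convForward(NumericVector x, NumericVector w,
                          NumericVector bias) {
    IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
    const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
    const int k = wd[0], F = wd[3];
    if (wd[1] != k || wd[2] != C) stop("kernel dims mismatch");
    const int Ho = H - k + 1, Wo = W - k + 1, P = Ho * Wo, K = k * k * C;
    if (Ho < 1 || Wo < 1) stop("kernel larger than input");
    NumericVector y = makeArr4(Ho, Wo, F, B);
    std::vector<double> col((std::size_t)P * K);
    const double one = 1.0, zero = 0.0;
    for (int b = 0; b < B; ++b) {
        im2col(&x[0] + (std::size_t)H * W * C * b, H, W, C, k, col.data());
        // y_b (P x F) = col (P x K) %*% w (K x F)
        F77_CALL(dgemm)("N", "N", &P, &F, &K, &one, col.data(), &P,
                        &w[0], &K, &zero,
                        &y[0] + (std::size_t)P * F * b, &P FCONE FCONE);
        double* yb = &y[0] + (std::size_t)P * F * b;
        for (int f = 0; f < F; ++f) {
            double* yf = yb + (std::size_t)P * f;
            for (int p = 0; p < P; ++p) yf[p] += bias[f];
        }
    }
    return y;
}

// [[Rcpp::export(name = ".convBackward")]]
List convBackward(NumericVector x, NumericVector w, NumericVector dy) {
    IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
    const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
    const int k = wd[0], F = wd[3];
    const int Ho = H - k + 1, Wo = W - k + 1, P = Ho * Wo, K = k * k * C;
    NumericVector dx = makeArr4(H, W, C, B);
    NumericVector dw = makeArr4(k, k, C, F);
    NumericVector db(F);
    std::vector<double> col((std::size_t)P * K), dcol((std::size_t)P * K);
    const double one = 1.0, zero = 0.0;
    for (int b = 0; b < B; ++b) {
        const double* xb = &x[0] + (std::size_t)H * W * C * b;
        const double* dyb = &dy[0] + (std::size_t)P * F * b;
        im2col(xb, H, W, C, k, col.data());
        // dw += col^T (K x P) %*% dy_b (P x F)
        F77_CALL(dgemm)("T", "N", &K, &F, &P, &one, col.data(), &P,
                        dyb, &P, &one, &dw[0], &K FCONE FCONE);
        // dcol (P x K) = dy_b (P x F) %*% w^T (F x K)
        F77_CALL(dgemm)("N", "T", &P, &K, &F, &one, dyb, &P,
                        &w[0], &K, &zero, dcol.data(), &P FCONE FCONE);
        col2im(dcol.data(), H, W, C, k,
               &dx[0] + (std::size_t)H * W * C * b);
        for (int f = 0; f < F; ++f) {
            const double* d = dyb + (std::size_t)P * f;
            double s = 0.0;
            for (int p = 0; p < P; ++p) s += d[p];
            db[f] += s;
        }
    }
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".poolForward")]]
List poolForward(NumericVector x, int p, bool maxPool) {
    IntegerVector xd = x.attr("dim");
    const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
    const int Ho = H / p, Wo = W / p;
    NumericVector y = makeArr4(Ho, Wo, C, B);
    IntegerVector idx;
    if (maxPool) {
        idx = IntegerVector((R_xlen_t)Ho * Wo * C * B);
        idx.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
    }
    for (int b = 0; b < B; ++b)
        for (int c = 0; c < C; ++c) {
            const double* plane = &x[0] + (std::size_t)H * W * (c + (std::size_t)C * b);
            for (int wo = 0; wo < Wo; ++wo)
                for (int ho = 0; ho < Ho; ++ho) {
                    std::size_t t = (std::size_t)ho + (std::size_t)Ho * wo +
                        (std::size_t)Ho * Wo * (c + (std::size_t)C * b);
                    if (maxPool) {
                        double best = R_NegInf;
                        int bestIdx = 0;
                        for (int dw = 0; dw < p; ++dw)
                            for (int dh = 0; dh < p; ++dh) {
                                int hi = ho * p + dh, wi = wo * p + dw;
                                double v = plane[hi + (std::size_t)H * wi];
                                if (v > best) {
                                    best = v;
                                    bestIdx = hi + H * wi;
                                }
                            }
                        y[t] = best;
                        idx[t] = bestIdx;
                    } else {
                        double s = 0.0;
                        for (int dw = 0; dw < p; ++dw)
                            for (int dh = 0; dh < p; ++dh)
                                s += plane[ho * p + dh +
                                           (std::size_t)H * (wo * p + dw)];
                        y[t] = s / (p * p);
                    }
                }
        }
    if (maxPool) return List::create(_["y"] = y, _["idx"] = idx);
    return List::create(_["y"] = y);
}

// [[Rcpp::export(name = ".poolBackward")]]
NumericVector poolBackward(NumericVector dy, Nullable<IntegerVector> idxN,
                           IntegerVector inDim, int p, bool maxPool) {
    IntegerVector yd = dy.attr("dim");
    const int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
    const int H = inDim[0], W = inDim[1];
    NumericVector dx((R_xlen_t)H * W * C * B);
    dx.attr("dim") = inDim;
    if (maxPool) {
        IntegerVector idx(idxN);
        for (R_xlen_t t = 0; t < dy.size(); ++t) {
            R_xlen_t plane = t / ((R_xlen_t)Ho * Wo);
            dx[(R_xlen_t)H * W * plane + idx[t]] += dy[t];
        }
    } else {
        const double inv = 1.0 / (p * p);
        for (int b = 0; b < B; ++b)
            for (int c = 0; c < C; ++c) {
                double* plane =
                    &dx[0] + (std::size_t)H * W * (c + (std::size_t)C * b);
                for (int wo = 0; wo < Wo; ++wo)
                    for (int ho = 0; ho < Ho; ++ho) {
                        std::size_t s = (std::size_t)ho +
                            (std::size_t)Ho * wo +
                            (std::size_t)Ho * Wo * (c + (std::size_t)C * b);
                        double g = dy[s] * inv;
                        for (int dw = 0; dw < p; ++dw)
                            for (int dh = 0; dh < p; ++dh)
                                plane[ho * p + dh +
                                      (std::size_t)H * (wo * p + dw)] += g;
                    }
            }
    }
    return dx;
}
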