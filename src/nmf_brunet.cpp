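#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multiplicative-update NMF minimizing generalized KL divergence
// (the "brunet" algorithm). The divergence
//   D(V||WH) = sum_{v>0} v log(v/wh) - v + wh  +  sum_{v=0} wh
// is recorded once per update sweep; WH is floored at 1e-12 inside logs.
// Stops when the relative divergence change over a `window`-iteration lag
// drops below `tol`, or at `max_iter`.
// [[Rcpp::export(name = ".nmf_brunet_cpp")]]
Rcpp::List nmf_brunet_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                          int max_iter, double tol, int window) {
    const double eps = 1e-12;
    const uword nel = V.n_elem;

    // constant part of the divergence: sum over v>0 of (v log v - v)
    double const_term = 0.0;
    for (uword i = 0; i < nel; ++i) {
        const double v = V(i);
        if (v > 0.0) const_term += v * std::log(v) - v;
    }

    // D given the current WH: const + sum(wh) - sum_{v>0} v log(wh)
    mat WH(V.n_rows, V.n_cols);
    mat Q(V.n_rows, V.n_cols);
    auto divergence = [&]() -> double {
        double s = 0.0, xlog = 0.0;
        for (uword i = 0; i < nel; ++i) {
            double wh = WH(i);
            if (wh < eps) wh = eps;
            s += wh;
            const double v = V(i);
            if (v > 0.0) xlog += v * std::log(wh);
        }
        return const_term + s - xlog;
    };
    auto fill_quotient = [&]() {
        for (uword i = 0; i < nel; ++i) {
            double wh = WH(i);
            if (wh < eps) wh = eps;
            Q(i) = V(i) / wh;
        }
    };

    std::vector<double> trace;
    trace.reserve(static_cast<size_t>(max_iter) + 1);
    WH = W * H;
    trace.push_back(divergence());

    int it = 0;
    rowvec wsum;
    colvec hsum;
    for (it = 1; it <= max_iter; ++it) {
        // H <- H .* (W' (V ./ WH)) ./ (W' 1)
        fill_quotient();
        wsum = sum(W, 0);
        wsum.transform([&](double x) { return x < eps ? eps : x; });
        H %= (W.t() * Q);
        H.each_col() /= wsum.t();

        // W <- W .* ((V ./ WH) H') ./ (1 H'), with refreshed quotient
        WH = W * H;
        fill_quotient();
        hsum = sum(H, 1);
        hsum.transform([&](double x) { return x < eps ? eps : x; });
        W %= (Q * H.t());
        W.each_row() /= hsum.t();

        WH = W * H;
        trace.push_back(divergence());

        if (it >= window) {
            const double prev = trace[trace.size() - 1 - window];
            const double cur = trace.back();
            const double denom = std::max(std::abs(prev), eps);
            if (std::abs(prev - cur) / denom < tol) break;
        }
    }
    if (it > max_iter) it = max_iter;

    return Rcpp::List::create(
        Rcpp::Named("W") = W,
        Rcpp::Named("H") = H,
        Rcpp::Named("trace") = trace,
        Rcpp::Named("iterations") = it);
}
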