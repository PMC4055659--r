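// Small dense matrix exponential (scaling-and-squaring Pade, via Armadillo).
// Matrix::expm's S4 dispatch overhead dominates the linear-ODE scans; the
// systems here are tiny (typically 4 x 4).

#include <RcppArmadillo.h>

// [[Rcpp::export(name = ".expm_cpp")]]
arma::mat expm_cpp(const arma::mat& m) { return arma::expmat(m); }
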