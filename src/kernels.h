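#ifndef PROMASWIM_KERNELS_H
#define PROMASWIM_KERNELS_H
#include <RcppArmadillo.h>
void stokeslet_G(const double* x, const double* y, arma::mat& G);
void blake_image(const double* x, const double* y, arma::mat& W);
#endif
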