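# shared fixtures built in code

# noise-free titration from any model object on a saturating grid
exact_titration <- function(p, conc = exp(seq(log(5), log(2000),
                                              length.out = 50))) {
  data.frame(conc_uM = conc, rate = unwindr:::model_rate(conc, p))
}

# two-sided Kolmogorov distance between samples and a reference CDF
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  F <- cdf(x)
  max(abs(seq_len(n) / n - F), abs((seq_len(n) - 1) / n - F))
}

# random mechanistic parameter draw (log-uniform equilibria)
random_capture <- function(variant) {
  capture_params(K1 = exp(stats::runif(1, log(0.01), log(100))),
                 K2 = exp(stats::runif(1, log(0.01), log(100))),
                 Kd_t = stats::runif(1, 20, 300),
                 kcat = stats::runif(1, 50, 300),
                 variant = variant)
}

random_ordered <- function() {
  ordered_params(K1 = exp(stats::runif(1, log(0.01), log(100))),
                 Kd_nt = stats::runif(1, 2, 50),
                 kcat = stats::runif(1, 50, 300))
}
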