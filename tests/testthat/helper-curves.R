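# Published replicate-mean parameter values used as generating truths
# throughout the suite (cooked white / brown / germinated brown rice).
table1 <- list(
  powerlaw = list(
    white = c(eps0 = 0.6, k1 = 41.88, k2 = 6.24, n = 0.59),
    brown = c(eps0 = 0.6, k1 = 35.00, k2 = 7.07, n = 0.60),
    germinated = c(eps0 = 0.6, k1 = 41.60, k2 = 6.76, n = 0.65)
  ),
  peleg = list(white = c(k1 = 0.010, k2 = 1.43)),
  purkayastha = list(white = c(k0 = 0.65, k1 = 0.0001, k2 = 137.8,
                               k3 = 17.21))
)

noiseless_curve <- function(model_id, params, t = 0:120) {
  creep_curve(t, creep_strain(creep_model(model_id), params, t))
}

rel_err <- function(est, truth) max(abs(est - truth) / abs(truth))
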