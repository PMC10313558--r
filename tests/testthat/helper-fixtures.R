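# Shared fixtures: the two published worked cases used as generating truth,
# random in-model parameter generators, and brute-force oracles.

fig1_biexp <- function() biexp_params(0.673e-3, 67.5e-3, 0.266)
fig2_biexp <- function() biexp_params(1.01e-3, 29.6e-3, 0.483)
fig1_stretched <- function() stretched_params(0.513e-3, 0.729)
fig2_stretched <- function() stretched_params(0.619e-3, 0.751)
fig2_adc <- 0.936e-3
adc_cutoff <- 1.15e-3

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# Random valid parameter sets, drawn inside the fit bounds (and, for the
# segmented bi-exponential, inside its validity domain D* >> D).
random_mono <- function() monoexp_params(runif(1, 0.3e-3, 2.5e-3))
random_biexp <- function() {
  d <- runif(1, 0.4e-3, 2e-3)
  biexp_params(d, runif(1, max(20e-3, 10 * d), 300e-3), runif(1, 0.05, 0.6))
}
random_stretched <- function()
  stretched_params(runif(1, 0.2e-3, 2e-3), runif(1, 0.4, 1))

# Exhaustive pairwise AUC: concordant pairs + half ties, oriented >= 0.5.
auc_pair_oracle <- function(values, labels, positive = "failure") {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  a <- tot / (length(pos) * length(neg))
  max(a, 1 - a)
}

# A small uniform parameter-map object without running fit_volume.
fake_maps <- function(maps3d, model = "mono") {
  structure(list(maps = maps3d, model = model, protocol = default_protocol(),
                 report = list(n_voxels = length(maps3d[[1]]),
                               n_masked = length(maps3d[[1]]),
                               n_fitted = length(maps3d[[1]]), n_failed = 0L)),
            class = "param_maps")
}
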