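# Small fixture builders shared across test files.

with_seed_rnorm <- function(n, seed) {
  set.seed(seed)
  rnorm(n)
}

# White-noise ROI: n_vox independent voxels x n_vol volumes.
null_roi <- function(n_vox, n_vol, seed) {
  set.seed(seed)
  matrix(rnorm(n_vox * n_vol), n_vox)
}
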