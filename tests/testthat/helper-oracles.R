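# Independent oracles and small fixture builders shared across tests.

# exhaustive O(N^2 * T) degree oracle: plain double loop over voxel pairs
# using stats::cor, independent of the blockwise implementation
brute_degree <- function(x, hemi, threshold = 0.6) {
  N <- ncol(x)
  g <- integer(N); cc <- integer(N)
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      if (stats::cor(x[, i], x[, j]) > threshold) {
        g[i] <- g[i] + 1L; g[j] <- g[j] + 1L
        if (hemi[i] * hemi[j] == -1L) {
          cc[i] <- cc[i] + 1L; cc[j] <- cc[j] + 1L
        }
      }
    }
  }
  list(g_raw = g, c_raw = cc)
}

# normal-equations OLS residual oracle
ols_resid_oracle <- function(y, X) {
  as.numeric(y - X %*% solve(crossprod(X), crossprod(X, y)))
}

# homotopic phantom: a block of `m` voxels in the left hemisphere plus its
# mirror image, sharing one latent signal
homotopic_spec <- function(grid_shape = c(12, 10, 10), m = 15, w = 0.8,
                           n_timepoints = 200, group_effect = 1, ...) {
  vox <- as.matrix(expand.grid(x = 2:4, y = 2:6, z = 2:4))[seq_len(m), ]
  net <- network_spec(vox, coupling = w, laterality = "homotopic",
                      group_effect = group_effect)
  spec <- phantom_spec(grid_shape, networks = list(net),
                       n_timepoints = n_timepoints, ...)
  grid <- make_phantom_grid(spec)
  lin <- fcdmap:::.vox_linear(vox, grid$dim)
  mir <- fcdmap:::.vox_linear(fcdmap:::.mirror_vox(vox, grid$dim), grid$dim)
  list(spec = spec, grid = grid, members = c(lin, mir), left = lin,
       right = mir)
}

unilateral_spec <- function(grid_shape = c(12, 10, 10), m = 30, w = 0.8,
                            n_timepoints = 200, ...) {
  vox <- as.matrix(expand.grid(x = 2:4, y = 2:6, z = 2:3))[seq_len(m), ]
  net <- network_spec(vox, coupling = w, laterality = "unilateral-left")
  spec <- phantom_spec(grid_shape, networks = list(net),
                       n_timepoints = n_timepoints, ...)
  grid <- make_phantom_grid(spec)
  list(spec = spec, grid = grid,
       members = fcdmap:::.vox_linear(vox, grid$dim))
}
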