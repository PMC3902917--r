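# Shared fixtures and independent oracles.

# O(n^2) brute-force MSD oracle: average squared displacement over all
# ordered pairs at each lag, written without any vectorised shortcuts so it
# stays independent of compute_msd().
msd_brute_force <- function(x, y, dt, axis, kmax) {
  n <- length(x)
  out <- numeric(kmax)
  for (k in seq_len(kmax)) {
    acc <- 0
    cnt <- 0
    for (i in seq_len(n - k)) {
      dxx <- x[i + k] - x[i]
      dyy <- y[i + k] - y[i]
      acc <- acc + switch(axis, long = dxx^2, short = dyy^2,
                          `2d` = dxx^2 + dyy^2)
      cnt <- cnt + 1
    }
    out[k] <- acc / cnt
  }
  out
}

# Noise-free MSD curve from the closed-form confined-diffusion model.
exact_msd_curve <- function(L, D, lags, offset = 0, axis = "long") {
  structure(
    data.frame(lag_s = lags,
               msd_um2 = (L^2 / 6) * (1 - exp(-12 * D * lags / L^2)) + offset,
               n_pairs = rev(seq_along(lags))),
    class = c("msd_curve", "data.frame"), axis = axis)
}

# Mean fitted confinement length over an ensemble of synthetic tracks.
fit_ensemble_L <- function(n_tracks, L_true, D, dt, n_steps, seed0,
                           cell_dim = 3) {
  fits <- lapply(seq_len(n_tracks), function(i) {
    tr <- gen_confined_trajectory(D = D, box_long = L_true, box_short = 0.4,
                                  dt = dt, n_steps = n_steps, seed = seed0 + i)
    fit_confinement(compute_msd(tr, axis = "long"), cell_dim = cell_dim)
  })
  keep <- vapply(fits, function(f) f$plateau_reached, TRUE)
  list(L = vapply(fits[keep], function(f) f$L, 0),
       D = vapply(fits[keep], function(f) f$D, 0),
       n_kept = sum(keep), n_total = n_tracks)
}
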