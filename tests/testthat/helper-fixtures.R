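# Shared fixtures, built in code at test time.

# desk-scale cohort configuration for fast tests
tiny_config <- function(seed = 11, ...) {
  defaults <- list(seed = seed, n_patients = 3,
                   timepoints = c("baseline", "fx11"),
                   grid_dim = 24, n_frames = 60,
                   baseline_profile = modifyList(
                     default_baseline_profile(),
                     list(gtv_mr_patients = c(3.0, 6.4, 2.0))),
                   pet_sigma = 0, dwi_sigma = 0, dce_sigma = 0)
  do.call(cohort_config, modifyList(defaults, list(...)))
}

# the acquisition time grid: 150 frames at 2.5 s
study_times <- function(n_frames = 150, dt = 2.5) (seq_len(n_frames) - 1) * dt

study_aif <- function(times = study_times()) {
  generate_aif(times, bolus_time = times[11])
}

# a uniform sphere in a zero or warm background
sphere_volume <- function(radius_mm, dim = 32, spacing = 1, value = 10,
                          bg = 0) {
  ctr <- (dim + 1) / 2 * spacing
  g <- (seq_len(dim) - 0.5) * spacing
  d2 <- outer(outer((g - ctr)^2, (g - ctr)^2, "+"), (g - ctr)^2, "+")
  vals <- array(bg, dim = c(dim, dim, dim))
  vals[d2 <= radius_mm^2] <- value
  list(vol = image_volume(vals, rep(spacing, 3), "PET", "SUV"),
       mask = d2 <= radius_mm^2)
}

# independent brute-force signed-rank oracle: enumerate all 2^n assignments
signed_rank_bruteforce_p <- function(changes) {
  changes <- changes[changes != 0]
  n <- length(changes)
  r <- rank(abs(changes))
  w_obs <- sum(r[changes > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  lo <- mean(w_all <= w_obs)
  hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}
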