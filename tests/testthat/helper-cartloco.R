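# Shared fixtures: small, fast model configurations.  Mouse-scale grids
# (dr = 0.005 cm) keep unit tests cheap; human-scale 2-cm baselines are
# grown once per session and memoized by the package cache.

fast_tumor <- function() tumor_params(a = 0.25, D_T = 1e-4, u_star = 2.39e6)

mouse_state <- function(radius = 0.15) {
  grow_to_size(fast_tumor(), radius, dr = 0.005)
}

weak_cart <- function() {
  cart_params(D_C = 0.01, d = 0, s = 1, l = 1, j = 0, k = 1, m = 0.1, q = 0)
}

# fabricate a cart_trajectory with prescribed scalar series, for testing
# the classification logic in isolation from the solver
fake_traj <- function(t, r_detect, detectable = NULL, tumor = NULL,
                      stop_reason = "horizon", m = 0.35) {
  n <- length(t)
  if (is.null(detectable)) detectable <- 1e8 * 4 * pi / 3 * r_detect^3
  if (is.null(tumor)) tumor <- detectable
  series <- data.frame(t = t, tumor = tumor, effector = rep(0, n),
                       exhausted = rep(0, n), r_detect = r_detect,
                       detectable = detectable, clamped = 0)
  structure(list(series = series, state = NULL, snapshots = NULL,
                 stop_reason = stop_reason, margin_hit = FALSE,
                 clamped_mass = 0, dt = NA,
                 cp = list(m = m)),
            class = "cart_trajectory")
}
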