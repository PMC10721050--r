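# Shared fixtures and independent oracles for the test suite.

# default pulsatile stenosed-tube field (the study configuration)
study_field <- function(recirc = FALSE) {
  flow_field(stenosed_tube(), coronary_waveform(),
             recirculation = if (recirc) recirculation() else NULL)
}

# steady variant: constant unit flow factor
steady_field <- function(occlusion = 0.5, flow_amplitude = 2) {
  flow_field(stenosed_tube(occlusion = occlusion),
             coronary_waveform(amplitudes = c(0, 0), baseline = 1),
             flow_amplitude = flow_amplitude)
}

# Independent Gaussian-process regression oracle with constant mean:
# closed-form generalized-least-squares formulas via an explicit kernel
# inverse. Deliberately a different algebraic route from the package's
# Lagrange-multiplier kriging system.
gp_regress_oracle <- function(train, query, sill, range, nugget = 0) {
  Pt <- as.matrix(train[, c("X", "Y", "t_c")])
  D <- as.matrix(stats::dist(Pt))
  K <- sill * exp(-D / range) + nugget * diag(nrow(Pt))
  Ki <- solve(K)
  beta <- sum(Ki %*% train$v_n) / sum(Ki)
  Pq <- as.matrix(query[, c("X", "Y", "t_c")])
  Dq <- sqrt(outer(rowSums(Pq^2), rowSums(Pt^2), "+") - 2 * Pq %*% t(Pt))
  kq <- sill * exp(-Dq / range)
  as.numeric(beta + kq %*% (Ki %*% (train$v_n - beta)))
}

# high-accuracy trajectory oracle: integrate dx/dt = v(x, t) with an
# adaptive solver at tight tolerance (positions mm, velocities m/s)
ode_trajectory_oracle <- function(field, x0, t_end) {
  f <- function(t, y, p) {
    v <- eval_velocity(field, matrix(y, ncol = 3), t)
    list(1000 * as.numeric(v))
  }
  deSolve::lsoda(x0, c(0, t_end), f, NULL, rtol = 1e-12, atol = 1e-12)[2, 2:4]
}

# build a minimal pept_tracks object by hand (for crossing-extraction tests)
fake_tracks <- function(t, x, y, z, dt) {
  n <- ncol(z)
  structure(list(t = t, x = x, y = y, z = z,
                 vx = matrix(0, nrow(z), n), vy = matrix(0, nrow(z), n),
                 vz = matrix(1, nrow(z), n),
                 seeds = data.frame(id = seq_len(n), batch = 0,
                                    release_t = 0, x = x[1, ], y = y[1, ],
                                    z = z[1, ]),
                 dt_pt = dt),
            class = "pept_tracks")
}
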