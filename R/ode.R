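# Adaptive Dormand-Prince 5(4) integrator. The reactor ODE system is small
# (a handful of concentrations plus cumulative process integrals) and
# non-stiff at default kinetics (all rates saturate), so an explicit
# embedded pair with step control is the right tool.

.DP_A <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
.DP_C <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
.DP_B5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
.DP_B4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)

# Integrate dy/dt = f(t, y) from times[1] to times[length(times)], returning
# the solution at every requested time (rows). FSAL is not exploited; the
# system is cheap. Errors out if the controller stalls.
ode_dopri <- function(f, y0, times, rtol = 1e-8, atol = 1e-10,
                      h_init = NULL, h_max = Inf, max_steps = 1e6) {
  ny <- length(y0)
  out <- matrix(NA_real_, nrow = length(times), ncol = ny,
                dimnames = list(NULL, names(y0)))
  out[1, ] <- y0
  y <- y0
  t <- times[1]
  h <- if (is.null(h_init)) min(diff(range(times)) / 100, h_max) else h_init
  nstep <- 0L
  for (i in seq_along(times)[-1]) {
    t_end <- times[i]
    while (t < t_end) {
      h <- min(h, t_end - t, h_max)
      k <- matrix(0, nrow = 7, ncol = ny)
      k[1, ] <- f(t, y)
      for (s in 2:6) {
        ys <- y + h * drop(.DP_A[[s - 1]] %*% k[seq_len(s - 1), , drop = FALSE])
        k[s, ] <- f(t + .DP_C[s] * h, ys)
      }
      y5 <- y + h * drop(.DP_B5[1:6] %*% k[1:6, , drop = FALSE])
      k[7, ] <- f(t + h, y5)
      y4 <- y + h * drop(.DP_B4 %*% k)
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (!is.finite(err))
        stop("ODE integration failed: non-finite error estimate at t = ",
             signif(t, 6), call. = FALSE)
      if (err <= 1) {
        t <- t + h
        y <- y5
      }
      h <- h * min(5, max(0.2, 0.9 * (if (err > 0) err^(-0.2) else 5)))
      nstep <- nstep + 1L
      if (nstep > max_steps)
        stop("ODE integration failed: step limit exceeded at t = ",
             signif(t, 6), call. = FALSE)
    }
    out[i, ] <- y
  }
  out
}
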