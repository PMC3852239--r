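## Implicit ODE integration for stiff metabolic systems.
##
## No stiff integrator is available in this R stack, so the package uses an
## adaptive backward-Euler scheme with analytic-Jacobian Newton inner solves
## and step-doubling error control.  First order is sufficient here: the
## integrator is used to relax models towards steady states (where accuracy is
## governed by the attractor, not the local truncation error) and for
## qualitative perturbation time courses.  Backward Euler preserves linear
## conservation relations (moiety totals) exactly up to the Newton tolerance.

ode_integrate <- function(f, jac, y0, t_end, n_out = 101L,
                          rtol = 1e-6, atol = 1e-10, hmin = 1e-12,
                          max_steps = 200000L) {
  n <- length(y0)
  times <- seq(0, t_end, length.out = n_out)
  Y <- matrix(NA_real_, n_out, n, dimnames = list(NULL, names(y0)))
  Y[1, ] <- y0
  y <- y0
  h <- t_end / 1000
  steps <- 0L

  be_step <- function(y, h) {
    ## solve z = y + h f(z) by Newton
    z <- y + h * f(y)
    for (k in 1:25) {
      Fz <- z - y - h * f(z)
      if (max(abs(Fz)) < 1e-13 * max(1, max(abs(z)))) break
      J <- diag(1, n) - h * jac(z)
      dz <- tryCatch(solve(J, Fz), error = function(e) NULL)
      if (is.null(dz)) return(NULL)
      z <- z - dz
      if (max(abs(dz)) < 1e-13 * max(1, max(abs(z)))) break
    }
    if (any(!is.finite(z))) return(NULL)
    z
  }

  for (i in 2:n_out) {
    t <- times[i - 1L]; tgt <- times[i]
    while (t < tgt - 1e-14 * t_end) {
      h <- min(h, tgt - t)
      err <- 1
      repeat {
        steps <- steps + 1L
        if (steps > max_steps)
          stop("numerical error: ODE step limit reached at t = ", format(t))
        y1 <- be_step(y, h)
        yh <- be_step(y, h / 2)
        y2 <- if (is.null(yh)) NULL else be_step(yh, h / 2)
        if (is.null(y1) || is.null(y2) || any(y2 < -atol)) {
          h <- h / 4
          if (h < hmin) {
            if (!is.null(y2)) { y2 <- pmax(y2, 0); break }
            stop("numerical error: ODE integration failed at t = ", format(t),
                 " (last good state returned in condition)", call. = FALSE)
          }
          next
        }
        err <- max(abs(y2 - y1) / (atol + rtol * pmax(abs(y), abs(y2))))
        if (err <= 1 || h <= hmin) break
        h <- max(h / 2, hmin)
      }
      y <- pmax(y2, 0)
      t <- t + h
      h <- h * min(4, max(1, 0.8 * err^-0.5))
    }
    Y[i, ] <- y
  }
  list(times = times, y = Y, steps = steps)
}
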