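## Generic adaptive Dormand-Prince 5(4) integrator with an R callback.
## Used for user-defined and demonstration models; the built-in cascade
## family has a dedicated compiled integrator.  Tolerances default tight
## because marginal-likelihood values are exponentially sensitive to
## trajectory error.

#' Integrate an ODE with an adaptive Runge-Kutta scheme
#'
#' Dormand-Prince 5(4) with PI-free step control, returning the state at
#' the requested output times.  `breaks` lists time points where the
#' right-hand side is discontinuous (e.g. stimulus switch-on/off); steps
#' never straddle them.
#'
#' @param rhs Function `(t, y) -> dy/dt`.
#' @param y0 Initial state at `t_start`.
#' @param times Nondecreasing output times (`>= t_start`).
#' @param t_start Initial time (default 0).
#' @param rtol,atol Relative and absolute local error tolerances.
#' @param breaks Optional discontinuity times.
#' @return `length(times) x length(y0)` matrix of states.
#' @export
ode_rk45 <- function(rhs, y0, times, t_start = 0, rtol = 1e-8, atol = 1e-10,
                     breaks = numeric()) {
  a <- list(c(1/5),
            c(3/40, 9/40),
            c(44/45, -56/15, 32/9),
            c(19372/6561, -25360/2187, 64448/6561, -212/729),
            c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
            c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84))
  cs <- c(1/5, 3/10, 4/5, 8/9, 1, 1)
  bb <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
  ee <- c(71/57600, 0, -71/16695, 71/1920, -17253/339200, 22/525, -1/40)
  n <- length(y0)
  span <- function(y, t0, t1) {
    if (t1 <= t0) return(y)
    t <- t0
    h <- (t1 - t0) / 10
    k1 <- rhs(t, y)
    repeat {
      if (t >= t1 - 1e-14 * max(1, abs(t1))) break
      if (t + h > t1) h <- t1 - t
      ks <- matrix(0, 7, n)
      ks[1, ] <- k1
      for (s in 1:6) {
        yt <- y + h * as.numeric(crossprod(ks[1:s, , drop = FALSE], a[[s]]))
        ks[s + 1, ] <- rhs(t + cs[s] * h, yt)
      }
      ynew <- y + h * as.numeric(crossprod(ks[1:6, , drop = FALSE], a[[6]]))
      ks[7, ] <- rhs(t + h, ynew)
      yerr <- h * as.numeric(crossprod(ks, ee))
      sc <- atol + rtol * pmax(abs(y), abs(ynew))
      errnorm <- sqrt(mean((yerr / sc)^2))
      if (!is.finite(errnorm)) stop("ode_rk45: non-finite state at t=", t)
      if (errnorm <= 1) {
        t <- t + h
        y <- ynew
        k1 <- ks[7, ]
      }
      h <- h * min(5, max(0.2, 0.9 * max(errnorm, 1e-10)^(-0.2)))
      if (h < 1e-12 * max(1, abs(t))) stop("ode_rk45: step underflow at t=", t)
    }
    y
  }
  out <- matrix(0, length(times), n)
  y <- y0
  t <- t_start
  for (j in seq_along(times)) {
    tj <- times[j]
    if (tj < t - 1e-12) stop("ode_rk45: times must be nondecreasing")
    cuts <- sort(breaks[breaks > t + 1e-12 & breaks < tj - 1e-12])
    for (tc in c(cuts, tj)) {
      y <- span(y, t, tc)
      t <- tc
    }
    out[j, ] <- y
  }
  out
}
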