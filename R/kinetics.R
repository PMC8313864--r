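#' Kinetic rate parameters of the three-compartment optogenetic model
#'
#' Bundles the six first-order rate constants of the
#' mitochondria/cytoplasm/nucleus shuttling model: nuclear import (`k_imp`,
#' cytoplasm to nucleus) and export (`k_exp`, nucleus to cytoplasm), and the
#' mitochondrial binding (`k_on`) and unbinding (`k_off`) rate constants in
#' the dark (`_unlit`) and illuminated (`_lit`) states. All rates are in
#' s^-1 and must be non-negative.
#'
#' @param k_imp,k_exp Nuclear import and export rate constants (s^-1).
#' @param k_on_unlit,k_off_unlit Dark-state mitochondrial binding/unbinding
#'   rate constants (s^-1).
#' @param k_on_lit,k_off_lit Lit-state mitochondrial binding/unbinding rate
#'   constants (s^-1).
#' @return An object of class `rate_params`.
#' @examples
#' rate_params(
#'   k_imp = 0.002, k_exp = 0.002,
#'   k_on_unlit = 0.027, k_off_unlit = 0.019,
#'   k_on_lit = 0.03, k_off_lit = 0.2
#' )
#' @export
rate_params <- function(k_imp, k_exp, k_on_unlit, k_off_unlit,
                        k_on_lit = k_on_unlit, k_off_lit = k_off_unlit) {
  r <- list(
    k_imp = k_imp, k_exp = k_exp,
    k_on_unlit = k_on_unlit, k_off_unlit = k_off_unlit,
    k_on_lit = k_on_lit, k_off_lit = k_off_lit
  )
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      abort(paste0("rate `", nm, "` must be a single number"))
    }
    if (v < 0) abort(paste0("rate `", nm, "` must be non-negative"))
  }
  structure(r, class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params> (s^-1)\n")
  cat(sprintf(
    "  k_imp = %g, k_exp = %g\n  dark:  k_on = %g, k_off = %g\n  lit:   k_on = %g, k_off = %g\n",
    x$k_imp, x$k_exp, x$k_on_unlit, x$k_off_unlit, x$k_on_lit, x$k_off_lit
  ))
  invisible(x)
}

# Generator matrix of the linear system d(M,C,N)/dt = A %*% (M,C,N) for a
# given light state. Columns sum to zero: mass is conserved exactly.
opto_rate_matrix <- function(rates, lit) {
  k_on <- if (lit) rates$k_on_lit else rates$k_on_unlit
  k_off <- if (lit) rates$k_off_lit else rates$k_off_unlit
  matrix(c(
    -k_off, k_on, 0,
    k_off, -(k_on + rates$k_imp), rates$k_exp,
    0, rates$k_imp, -rates$k_exp
  ), nrow = 3, byrow = TRUE)
}

#' Right-hand side of the three-compartment shuttling ODE
#'
#' The model tracks the proportions of protein bound to mitochondria (M),
#' free in the cytoplasm (C) and in the nucleus (N):
#' \deqn{dM/dt = k_{on} C - k_{off} M}
#' \deqn{dC/dt = k_{off} M - k_{on} C + k_{exp} N - k_{imp} C}
#' \deqn{dN/dt = k_{imp} C - k_{exp} N}
#' with `k_on`/`k_off` taking their lit or unlit values according to the
#' light state. The derivatives sum to zero: total signal is conserved.
#'
#' @param state Numeric vector or list with components `M`, `C`, `N`
#'   (non-negative, finite).
#' @param rates A [rate_params()] object.
#' @param lit Logical: is the activation light on?
#' @return Named numeric vector `c(M =, C =, N =)` of time derivatives
#'   (s^-1).
#' @export
ode_rhs <- function(state, rates, lit) {
  if (!inherits(rates, "rate_params")) rates <- do.call(rate_params, as.list(rates))
  x <- c(state$M %||% state[["M"]], state$C %||% state[["C"]], state$N %||% state[["N"]])
  if (length(x) != 3L || anyNA(x) || any(!is.finite(x))) {
    abort("state must have finite components M, C, N")
  }
  if (any(x < 0)) abort("state proportions must be non-negative")
  d <- as.vector(opto_rate_matrix(rates, lit) %*% x)
  setNames(d, c("M", "C", "N"))
}

#' Dark steady state of the shuttling model
#'
#' In the dark the system settles to the fixed point with
#' `M0 = (k_on_unlit / k_off_unlit) C0`, `N0 = (k_imp / k_exp) C0` and
#' `M0 + C0 + N0 = total`.
#'
#' @param rates A [rate_params()] object with `k_off_unlit > 0` and
#'   `k_exp > 0`.
#' @param total Total signal to distribute (default 1, proportions).
#' @return Named numeric vector `c(M =, C =, N =)`.
#' @export
steady_state <- function(rates, total = 1) {
  if (!inherits(rates, "rate_params")) rates <- do.call(rate_params, as.list(rates))
  if (rates$k_off_unlit <= 0) abort("steady state requires k_off_unlit > 0")
  if (rates$k_exp <= 0) abort("steady state requires k_exp > 0")
  rm_ <- rates$k_on_unlit / rates$k_off_unlit
  rn <- rates$k_imp / rates$k_exp
  C <- total / (1 + rm_ + rn)
  setNames(c(rm_ * C, C, rn * C), c("M", "C", "N"))
}

# Propagate x0 under constant generator A for time increments dts
# (vector of times, relative to the block start). Exact solution via
# eigendecomposition; the M-C-N chain is tridiagonal so eigenvalues are real.
# Falls back to scaling-and-squaring if the eigenbasis is ill-conditioned.
propagate_linear <- function(A, x0, dts) {
  eg <- eigen(A)
  V <- eg$vectors
  ok <- is.numeric(V) && rcond(V) > 1e-10
  if (ok) {
    a <- solve(V, x0)
    out <- vapply(dts, function(dt) {
      Re(V %*% (exp(eg$values * dt) * a))
    }, numeric(3))
  } else {
    out <- vapply(dts, function(dt) {
      as.vector(Matrix::expm(A * dt) %*% x0)
    }, numeric(3))
  }
  # out: 3 x length(dts)
  out
}

#' Simulate a compartment trace under a light schedule
#'
#' Integrates the three-compartment model over a schedule of lit/unlit
#' frames. Within each constant-illumination block the system is linear and
#' time-invariant, so the exact solution (matrix exponential via
#' eigendecomposition of the 3x3 rate matrix) is propagated from switch to
#' switch; no discretisation error is incurred and mass is conserved to
#' machine precision.
#'
#' @param rates A [rate_params()] object.
#' @param schedule A [light_schedule()].
#' @param init Either the string `"steady"` (dark steady state) or a numeric
#'   vector/list with components M, C, N.
#' @param noise `NULL` for a noiseless trace, or a list
#'   `list(prop =, floor =)` giving additive Gaussian observation noise with
#'   per-point standard deviation `prop * value + floor` (default
#'   `noise_spec()`: 1% of total plus a small floor).
#' @param seed Optional integer seed controlling the observation noise.
#' @return A `compartment_trace`: tibble with columns `time_s`, `lit`, `M`,
#'   `C`, `N` and attribute `normalized = TRUE` (values are proportions of
#'   total).
#' @examples
#' r <- rate_params(0.002, 0.002, 0.027, 0.019, 0.03, 0.2)
#' tr <- simulate_trace(r, default_protocols("opto-standard"))
#' head(tr)
#' @export
simulate_trace <- function(rates, schedule, init = "steady", noise = NULL,
                           seed = NULL) {
  if (!inherits(rates, "rate_params")) rates <- do.call(rate_params, as.list(rates))
  if (nrow(schedule) < 1L) abort("schedule must be non-empty")
  if (identical(init, "steady")) {
    x0 <- steady_state(rates)
  } else {
    x0 <- c(init$M %||% init[["M"]], init$C %||% init[["C"]], init$N %||% init[["N"]])
    if (length(x0) != 3L || anyNA(x0)) abort("init must have components M, C, N")
  }
  blocks <- schedule_blocks(schedule)
  times <- schedule$time_s
  out <- matrix(NA_real_, nrow = 3, ncol = length(times))
  x <- x0
  t_block <- times[1]
  for (i in seq_len(nrow(blocks))) {
    idx <- seq(blocks$start[i], blocks$end[i])
    A <- opto_rate_matrix(rates, blocks$lit[i])
    out[, idx] <- propagate_linear(A, x, times[idx] - t_block)
    # state at the start of the next block = end of this block propagated to
    # the next block's first frame time under THIS block's rates
    if (i < nrow(blocks)) {
      t_next <- times[blocks$start[i + 1]]
      x <- as.vector(propagate_linear(A, x, t_next - t_block))
      t_block <- t_next
    }
  }
  M <- out[1, ]; C <- out[2, ]; N <- out[3, ]
  if (!is.null(noise)) {
    if (isTRUE(noise)) noise <- noise_spec()
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    add_noise <- function(v) v + rnorm(length(v), sd = noise$prop * abs(v) + noise$floor)
    M <- add_noise(M); C <- add_noise(C); N <- add_noise(N)
  }
  new_compartment_trace(
    tibble(time_s = times, lit = schedule$lit, M = M, C = C, N = N),
    normalized = TRUE
  )
}

#' Observation-noise specification
#'
#' Additive Gaussian observation noise with standard deviation
#' `prop * signal + floor`, emulating Poisson-Gaussian detection noise on
#' normalised traces. The default is 1% of the (unit) total signal.
#'
#' @param prop Proportional component (fraction of signal).
#' @param floor Additive floor (same units as the trace).
#' @return A list usable as the `noise` argument of [simulate_trace()].
#' @export
noise_spec <- function(prop = 0.01, floor = 0.001) {
  list(prop = prop, floor = floor)
}

new_compartment_trace <- function(df, normalized = FALSE) {
  stopifnot(all(c("time_s", "lit", "M", "C", "N") %in% names(df)))
  attr(df, "normalized") <- normalized
  class(df) <- unique(c("compartment_trace", class(df)))
  df
}

#' Is a trace normalised to proportions of total?
#' @param trace A `compartment_trace`.
#' @return Logical flag.
#' @export
is_normalized <- function(trace) isTRUE(attr(trace, "normalized"))

# deSolve-based reference integrator; used in tests as an independent route
# to the piecewise matrix-exponential propagator.
simulate_trace_desolve <- function(rates, schedule, init = "steady",
                                   rtol = 1e-10, atol = 1e-12) {
  if (!inherits(rates, "rate_params")) rates <- do.call(rate_params, as.list(rates))
  x0 <- if (identical(init, "steady")) steady_state(rates) else unlist(init)[c("M", "C", "N")]
  blocks <- schedule_blocks(schedule)
  times <- schedule$time_s
  res <- matrix(NA_real_, nrow = length(times), ncol = 3)
  x <- unname(x0)
  for (i in seq_len(nrow(blocks))) {
    idx <- seq(blocks$start[i], blocks$end[i])
    t_end <- if (i < nrow(blocks)) times[blocks$start[i + 1]] else times[blocks$end[i]]
    tt <- unique(c(times[blocks$start[i]], times[idx], t_end))
    A <- opto_rate_matrix(rates, blocks$lit[i])
    sol <- deSolve::lsoda(
      y = x, times = tt,
      func = function(t, y, p) list(as.vector(A %*% y)),
      rtol = rtol, atol = atol
    )
    res[idx, ] <- sol[match(times[idx], sol[, 1]), 2:4]
    x <- as.vector(sol[nrow(sol), 2:4])
  }
  new_compartment_trace(
    tibble(time_s = times, lit = schedule$lit,
           M = res[, 1], C = res[, 2], N = res[, 3]),
    normalized = TRUE
  )
}
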