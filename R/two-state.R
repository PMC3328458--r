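# Two-state (BI/BII-like) torsion time-series generator: a hidden
# two-state Markov chain with von Mises angular emissions.

#' Specification of a two-state torsion process
#'
#' Validates and bundles the parameters of the synthetic BI/BII-like
#' process: a two-state Markov chain in discrete time (one step per
#' trajectory frame) with circular (von Mises) emissions around each
#' state's mean angle.  The stationary fraction of state 1 is
#' `(1 - p_stay_2) / ((1 - p_stay_1) + (1 - p_stay_2))` and the mean
#' dwell time in state k is `dt / (1 - p_stay_k)` ps.
#'
#' @param p_stay_1,p_stay_2 per-step self-transition probabilities,
#'   strictly inside (0, 1).
#' @param mean_1,mean_2 emission means in degrees (an epsilon-zeta-like
#'   coordinate; defaults -70 and +70, the BI and BII wells).
#' @param kappa_1,kappa_2 von Mises concentrations (> 0).
#' @param dt frame spacing in ps.
#' @param n_steps number of frames to simulate.
#' @param seed integer seed.
#' @return a validated list of class `two_state_spec` with an added
#'   `stationary_1` element.
#' @export
two_state_spec <- function(p_stay_1 = 0.99, p_stay_2 = 0.99,
                           mean_1 = -70, mean_2 = 70,
                           kappa_1 = 20, kappa_2 = 20,
                           dt = 2, n_steps = 1e4, seed = 1L) {
  if (!(p_stay_1 > 0 && p_stay_1 < 1 && p_stay_2 > 0 && p_stay_2 < 1))
    stop("self-transition probabilities must lie strictly in (0, 1)")
  if (kappa_1 <= 0 || kappa_2 <= 0)
    stop("kappa must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  q1 <- 1 - p_stay_1; q2 <- 1 - p_stay_2
  structure(list(p_stay_1 = p_stay_1, p_stay_2 = p_stay_2,
                 mean_1 = mean_1, mean_2 = mean_2,
                 kappa_1 = kappa_1, kappa_2 = kappa_2,
                 dt = dt, n_steps = n_steps, seed = as.integer(seed),
                 stationary_1 = q2 / (q1 + q2)),
            class = "two_state_spec")
}

#' Self-transition probability giving a target mean dwell time
#'
#' Inverse of the geometric dwell mean `dt / (1 - p_stay)`.
#'
#' @param mean_dwell_ps target mean dwell time in ps.
#' @param dt frame spacing in ps.
#' @return the self-transition probability `1 - dt / mean_dwell_ps`.
#' @export
p_stay_for_dwell <- function(mean_dwell_ps, dt = 2) {
  if (mean_dwell_ps <= dt) stop("mean dwell must exceed dt")
  1 - dt / mean_dwell_ps
}

# von Mises sampler (Best & Fisher 1979 wrapped-Cauchy rejection).
# mu in degrees, returns degrees in [-180, 180).
rvonmises <- function(n, mu, kappa) {
  if (kappa <= 0) stop("kappa must be > 0")
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(16L, ceiling((n - got) * 1.4))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    take <- min(sum(ok), n - got)
    out[got + seq_len(take)] <- th[seq_len(take)]
    got <- got + take
  }
  wrap_angle(out * 180 / pi + mu)
}

#' Simulate a two-state torsion time series
#'
#' Draws a hidden-state path from the two-state Markov chain (initial
#' state from the stationary distribution) by sampling alternating
#' geometric dwell lengths, then emits one angle per frame from the
#' current state's von Mises distribution.  The ground-truth state path
#' is returned alongside the observable series so that classifier- and
#' dwell-recovery can be checked against it.
#'
#' @param spec a `two_state_spec`.
#' @return a data frame of class `two_state_sim` with columns `time_ps`,
#'   `angle_deg` (degrees in `[-180, 180)`) and `true_state` (1 or 2);
#'   the spec is attached as attribute `"spec"`.
#' @examples
#' sim <- simulate_two_state(two_state_spec(n_steps = 1000, seed = 7))
#' mean(sim$true_state == 1)
#' @export
simulate_two_state <- function(spec) {
  stopifnot(inherits(spec, "two_state_spec"))
  set.seed(spec$seed)
  n <- spec$n_steps
  q <- c(1 - spec$p_stay_1, 1 - spec$p_stay_2)
  s0 <- 1L + (stats::runif(1) > spec$stationary_1)
  state <- integer(0)
  cur <- s0
  while (length(state) < n) {
    k <- max(8L, ceiling((n - length(state)) * q[cur] * 1.5))
    pat <- rep(c(cur, 3L - cur), length.out = k)
    dw <- stats::rgeom(k, q[pat]) + 1L   # alternating geometric dwells
    state <- c(state, rep(pat, dw))
    cur <- 3L - pat[k]
  }
  state <- state[seq_len(n)]
  angle <- numeric(n)
  i1 <- state == 1L
  if (any(i1)) angle[i1] <- rvonmises(sum(i1), spec$mean_1, spec$kappa_1)
  if (any(!i1)) angle[!i1] <- rvonmises(sum(!i1), spec$mean_2, spec$kappa_2)
  out <- data.frame(time_ps = (seq_len(n) - 1L) * spec$dt,
                    angle_deg = angle, true_state = state)
  attr(out, "spec") <- spec
  class(out) <- c("two_state_sim", "data.frame")
  out
}
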