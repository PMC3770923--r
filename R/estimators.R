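## Free-energy estimators: thermodynamic integration with endpoint
## extrapolation, Jarzynski direct exponential averaging, the second-order
## cumulant expansion, PMF reconstruction from steered-work profiles, and a
## 1-D overdamped steered toy simulator.
##
## Units: the TI path works in kcal/mol (alchemical convention); the
## work/PMF path works in kJ/mol (steered-simulation convention). Each
## container carries an explicit unit tag so the two are never mixed.

#' Thermodynamic context
#'
#' @param temperature Kelvin.
#' @return A `thermo_context` with `temperature`, `beta_kj` (mol/kJ),
#'   `beta_kcal` (mol/kcal), and the constants used.
#' @export
thermo_context <- function(temperature = 300) {
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(temperature = temperature,
                 beta_kj = 1 / (.KB_KJ * temperature),
                 beta_kcal = 1 / (.R_KCAL * temperature),
                 kb_kj = .KB_KJ, r_kcal = .R_KCAL),
            class = "thermo_context")
}

#' Construct a lambda series for thermodynamic integration
#'
#' @param lambda strictly increasing grid in (0, 1).
#' @param dudl mean dU/d-lambda at each grid point, kcal/mol.
#' @param se optional per-point standard errors.
#' @return A `lambda_series` data frame.
#' @export
lambda_series <- function(lambda, dudl, se = NULL) {
  if (length(lambda) != length(dudl)) stop("lambda and dudl lengths differ")
  if (any(lambda <= 0) || any(lambda >= 1)) stop("lambda must lie in (0, 1)")
  if (any(diff(lambda) <= 0)) stop("lambda must be strictly increasing")
  out <- data.frame(lambda = lambda, dudl = dudl,
                    se = if (is.null(se)) NA_real_ else se)
  class(out) <- c("lambda_series", class(out))
  out
}

## The 11-point lambda grid used for the alchemical peptide mutation.
.PAPER11 <- c(0.02, seq(0.1, 0.9, 0.1), 0.98)

## integral over [0, x1] of the line through (x1,y1),(x2,y2), as weights on
## (y1, y2); analogous helpers return endpoint-segment weights per scheme.
.ti_tail <- function(lam, y, scheme, upper = FALSE) {
  ## work in the coordinate t = lambda (lower end) or t = 1 - lambda (upper)
  t <- if (upper) rev(1 - lam) else lam
  yy <- if (upper) rev(y) else y
  n <- length(t)
  if (scheme == "linear") {
    ## line through the 2 nearest points, integrated over [0, t1]
    t1 <- t[1]; t2 <- t[2]
    s <- (yy[2] - yy[1]) / (t2 - t1)
    y0 <- yy[1] - s * t1
    val <- (y0 + yy[1]) / 2 * t1
    cover <- t1
  } else if (scheme == "quadratic") {
    ## parabola through the 3 nearest points, integrated over [0, t1]
    A <- cbind(1, t[1:3], t[1:3]^2)
    cf <- solve(A, yy[1:3])
    t1 <- t[1]
    val <- cf[1] * t1 + cf[2] * t1^2 / 2 + cf[3] * t1^3 / 3
    cover <- t1
  } else { # pow34
    ## local singular model a + c t^(-3/4) through the 2 nearest points,
    ## integrated over [0, t2] (it interpolates both, so it also replaces
    ## the first trapezoid interval, where a plain trapezoid is badly wrong
    ## for integrands diverging as t^(-3/4))
    b1 <- t[1]^(-3 / 4); b2 <- t[2]^(-3 / 4)
    cc <- (yy[1] - yy[2]) / (b1 - b2)
    aa <- yy[1] - cc * b1
    t2 <- t[2]
    val <- aa * t2 + 4 * cc * t2^(1 / 4)
    cover <- t2
  }
  list(value = val, cover = cover)
}

.ti_one <- function(lam, y, scheme) {
  lo <- .ti_tail(lam, y, scheme, upper = FALSE)
  hi <- .ti_tail(lam, y, scheme, upper = TRUE)
  lo_edge <- lo$cover                 # integrated up to this lambda
  hi_edge <- 1 - hi$cover
  keep <- which(lam >= lo_edge - 1e-12 & lam <= hi_edge + 1e-12)
  mid <- if (length(keep) >= 2)
    sum(diff(lam[keep]) * (y[keep][-length(keep)] + y[keep][-1]) / 2) else 0
  lo$value + mid + hi$value
}

#' Thermodynamic integration with endpoint extrapolation
#'
#' Trapezoidal integration of the mean Hamiltonian derivative over the
#' lambda grid, with the unsampled end segments `[0, lambda_1]` and
#' `[lambda_n, 1]` integrated under an extrapolation model fitted to the
#' nearest grid points: a line (2 points), a parabola (3 points), or the
#' singular form a + c lambda^(-3/4) (2 points; mirrored as (1-lambda) at
#' the top). The pow34 local model also covers the outermost grid interval
#' it interpolates, which is what makes it accurate for integrands
#' diverging at an endpoint. Exact for constant and linear integrands under
#' every scheme.
#'
#' @param series a [lambda_series()] (or data frame with lambda, dudl,
#'   optionally se).
#' @param endpoint_scheme `"linear"`, `"quadratic"` or `"pow34"`.
#' @return A list: `dg` (kcal/mol), `error` (propagated standard error plus
#'   half the spread across the three schemes), `scheme`, `by_scheme`.
#' @export
ti_integrate <- function(series, endpoint_scheme = c("linear", "quadratic", "pow34")) {
  endpoint_scheme <- match.arg(endpoint_scheme)
  lam <- series$lambda; y <- series$dudl
  if (length(lam) < 2) stop("need at least 2 lambda points")
  if (any(lam <= 0) || any(lam >= 1)) stop("lambda must lie in (0, 1)")
  schemes <- c("linear", "quadratic", "pow34")
  if (length(lam) < 3) schemes <- c("linear", "pow34")
  vals <- vapply(schemes, function(s) .ti_one(lam, y, s), numeric(1))
  dg <- if (endpoint_scheme %in% schemes) vals[[endpoint_scheme]] else
    .ti_one(lam, y, endpoint_scheme)
  spread <- (max(vals) - min(vals)) / 2
  se <- series$se
  prop <- if (!is.null(se) && !anyNA(se)) {
    ## trapezoid weights (tail segments approximated by their edge weights)
    w <- numeric(length(lam))
    dl <- diff(lam)
    w[-length(w)] <- w[-length(w)] + dl / 2
    w[-1] <- w[-1] + dl / 2
    w[1] <- w[1] + lam[1]
    w[length(w)] <- w[length(w)] + 1 - lam[length(lam)]
    sqrt(sum((w * se)^2))
  } else 0
  list(dg = unname(dg), error = prop + spread, scheme = endpoint_scheme,
       by_scheme = vals)
}

#' Jarzynski direct exponential average
#'
#' dG = -(1/beta) ln( mean exp(-beta W) ), evaluated with a log-sum-exp
#' contract so |beta W| up to 1e4 cannot overflow.
#'
#' @param work numeric work values at a fixed endpoint, kJ/mol.
#' @param context a [thermo_context()].
#' @return dG in kJ/mol.
#' @export
ji_direct <- function(work, context = thermo_context()) {
  if (length(work) == 0) stop("empty work sample")
  b <- context$beta_kj
  z <- -b * work
  m <- max(z)
  -(m + log(mean(exp(z - m)))) / b
}

#' Jarzynski second-order cumulant estimator
#'
#' dG = mean(W) - (beta/2) var(W), with the unbiased (n-1) sample variance.
#' Exact when the work distribution is Gaussian.
#'
#' @param work numeric work values, kJ/mol (n >= 2).
#' @param context a [thermo_context()].
#' @return dG in kJ/mol.
#' @export
ji_cumulant <- function(work, context = thermo_context()) {
  if (length(work) < 2) stop("cumulant estimator needs at least 2 work values")
  mean(work) - context$beta_kj / 2 * stats::var(work)
}

#' Work profile set
#'
#' @param xi reaction-coordinate grid (shared by all trajectories).
#' @param W matrix of accumulated work, `length(xi)` rows x one column per
#'   trajectory, kJ/mol; `W[1, ] == 0`.
#' @param units coordinate units label (default `"nm"`).
#' @return A `work_profile_set`.
#' @export
work_profile_set <- function(xi, W, units = "nm") {
  W <- as.matrix(W)
  if (nrow(W) != length(xi)) stop("W must have one row per xi point")
  if (any(abs(W[1, ]) > 1e-9)) stop("work must start at 0 (W(xi_0) = 0)")
  structure(list(xi = xi, W = W, n = ncol(W), units = units),
            class = "work_profile_set")
}

#' Potential of mean force from work profiles
#'
#' Applies a Jarzynski estimator to the per-trajectory accumulated work at
#' each point of the shared reaction-coordinate grid (stiff-spring
#' approximation: work is attributed at the guide position). G(xi_0) = 0.
#'
#' @param profiles a [work_profile_set()].
#' @param estimator `"direct"` or `"cumulant"`.
#' @param context a [thermo_context()].
#' @return A `pmf_profile` data frame with xi and G (kJ/mol).
#' @export
pmf_from_work <- function(profiles, estimator = c("direct", "cumulant"),
                          context = thermo_context()) {
  estimator <- match.arg(estimator)
  if (estimator == "cumulant" && profiles$n < 2)
    stop("cumulant estimator needs at least 2 trajectories")
  est <- if (estimator == "direct") ji_direct else ji_cumulant
  G <- apply(profiles$W, 1, est, context = context)
  G <- G - G[1]
  out <- data.frame(xi = profiles$xi, G = G)
  attr(out, "estimator") <- estimator
  class(out) <- c("pmf_profile", class(out))
  out
}

## built-in 1-D potentials: value and derivative
.toy_potential <- function(potential, params) {
  switch(potential,
    flat = list(
      U = function(x) 0 * x,
      dU = function(x) 0 * x),
    harmonic = {
      k0 <- params$k0 %||% 100; x0 <- params$x0 %||% 0
      list(U = function(x) 0.5 * k0 * (x - x0)^2,
           dU = function(x) k0 * (x - x0))
    },
    `double-well` = {
      a <- params$a %||% 10; b <- params$b %||% 0.5
      list(U = function(x) a * (x^2 - b^2)^2 / b^4,
           dU = function(x) 4 * a * x * (x^2 - b^2) / b^4)
    },
    stop("unknown potential: ", potential))
}

#' 1-D overdamped steered toy simulator
#'
#' Overdamped Langevin dynamics on U(x) plus a harmonic guide
#' 0.5 k_g (x - z(t))^2 whose center moves at constant speed v. The
#' accumulated external work is integrated as dW = -k_g (x - z) v dt, so
#' pulling against resistance yields W > 0. The work profile is recorded on
#' the guide-position grid (stiff-spring bookkeeping). Bit-reproducible for
#' a given seed.
#'
#' @param potential `"flat"`, `"harmonic"` or `"double-well"`.
#' @param params list of potential parameters (`k0`, `x0`; `a`, `b`);
#'   energies kJ/mol, coordinate nm.
#' @param k_g guide stiffness, kJ/mol/nm^2.
#' @param v pulling speed, nm per time unit.
#' @param n_traj number of trajectories.
#' @param n_steps steps per trajectory.
#' @param dt time step.
#' @param friction friction coefficient (kJ time / mol nm^2).
#' @param context a [thermo_context()].
#' @param seed integer seed.
#' @param x_start guide start position, nm.
#' @param record_every record the work every this many steps.
#' @return A [work_profile_set()] (kJ/mol, nm), with attributes `seed` and
#'   `truth` = NA (the toy's reference values are estimator-specific).
#' @export
steered_toy_simulate <- function(potential = c("flat", "harmonic", "double-well"),
                                 params = list(), k_g = 400, v = 0.5,
                                 n_traj = 150, n_steps = 1000, dt = 0.001,
                                 friction = 1, context = thermo_context(),
                                 seed = 1, x_start = 0, record_every = 50) {
  potential <- match.arg(potential)
  if (k_g <= 0 || v < 0 || dt <= 0 || n_steps < 1) stop("invalid simulation parameters")
  if (k_g * dt / friction >= 0.5)
    stop("unstable dt: k_g * dt / friction must be < 0.5")
  pot <- .toy_potential(potential, params)
  beta <- context$beta_kj
  noise_sd <- sqrt(2 * dt / (beta * friction))
  rec_steps <- seq(0, n_steps, by = record_every)
  xi <- x_start + v * rec_steps * dt
  W <- matrix(0, length(rec_steps), n_traj)
  set.seed(as.integer(seed))
  for (tr in seq_len(n_traj)) {
    ## start from the guide-constrained equilibrium at z = x_start
    x <- x_start + stats::rnorm(1, 0, sqrt(1 / (beta * k_g)))
    w <- 0; ri <- 1
    eta <- stats::rnorm(n_steps)
    for (s in seq_len(n_steps)) {
      z <- x_start + v * (s - 1) * dt
      force <- -pot$dU(x) - k_g * (x - z)
      w <- w - k_g * (x - z) * v * dt
      x <- x + force * dt / friction + noise_sd * eta[s]
      if (s %% record_every == 0) {
        ri <- ri + 1
        W[ri, tr] <- w
      }
    }
  }
  out <- work_profile_set(xi, W, units = "nm")
  attr(out, "seed") <- seed
  attr(out, "potential") <- potential
  out
}
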