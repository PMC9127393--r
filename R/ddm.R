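#' Drift-diffusion parameter set
#'
#' Parameters of a Wiener diffusion between two absorbing boundaries
#' with unit diffusion coefficient: drift rate (evidence units/s),
#' boundary separation (evidence units), non-decision time (s), and the
#' relative starting point, fixed at the midpoint (0.5) throughout this
#' package because the task carries no response bias.
#'
#' @param drift Drift rate.
#' @param boundary Boundary separation (> 0).
#' @param ndt Non-decision time in seconds (>= 0).
#' @param z Relative starting point in (0, 1); defaults to 0.5.
#' @return Object of class `ddm_params`.
#' @export
ddm_params <- function(drift, boundary, ndt, z = 0.5) {
  if (boundary <= 0) stop("ddm_params: boundary must be > 0")
  if (ndt < 0) stop("ddm_params: ndt must be >= 0")
  if (z <= 0 || z >= 1) stop("ddm_params: z must lie in (0, 1)")
  structure(list(drift = drift, boundary = boundary, ndt = ndt, z = z),
            class = "ddm_params")
}

#' First-passage-time density of the diffusion process
#'
#' Defect density of absorption at the named boundary at time `t`
#' (seconds from stimulus onset; the non-decision time shifts the
#' distribution). The two defect densities integrate to 1. Evaluated by
#' series expansion with automatic switching between the small-time and
#' large-time forms.
#'
#' @param t Time(s) in seconds.
#' @param boundary_hit `"upper"` or `"lower"` (accuracy coding: upper =
#'   correct).
#' @param params A [ddm_params()] object, or a list with vectors
#'   `drift`, `boundary`, `ndt` recycled against `t`.
#' @return Density values (0 for `t <= ndt`).
#' @export
wfpt_density <- function(t, boundary_hit = c("upper", "lower"), params) {
  boundary_hit <- match.arg(boundary_hit)
  .wfpt_pdf_cpp(as.numeric(t), boundary_hit == "upper",
                as.numeric(params$drift), as.numeric(params$boundary),
                as.numeric(params$ndt), if (is.null(params$z)) 0.5 else params$z)
}

#' Closed-form boundary hit probability
#'
#' Probability that the accumulator is absorbed at the upper boundary,
#' from the classical ruin formula for constant drift.
#'
#' @param params A [ddm_params()] object.
#' @param boundary `"upper"` or `"lower"`.
#' @return Probability in `[0, 1]`.
#' @export
ddm_choice_prob <- function(params, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  v <- params$drift
  a <- params$boundary
  w <- if (is.null(params$z)) 0.5 else params$z
  p_up <- if (abs(v) < 1e-12) w else {
    expm1(-2 * v * w * a) / expm1(-2 * v * a)
  }
  if (boundary == "upper") p_up else 1 - p_up
}

#' Simulate choices and reaction times from the diffusion process
#'
#' Euler-Maruyama paths with unit diffusion coefficient and a
#' Brownian-bridge correction for intra-step boundary crossings, which
#' removes the leading discretisation bias. RT is the absorption time
#' plus the non-decision time; the boundary hit is the choice (upper =
#' correct under accuracy coding).
#'
#' @param params A [ddm_params()], or a list of vectors `drift`,
#'   `boundary`, `ndt` (recycled) for trial-varying parameters.
#' @param n Number of trials (defaults to the parameter vector length).
#' @param dt Time step in seconds; must be much smaller than typical
#'   decision times.
#' @param seed Optional seed.
#' @return Data frame with `rt` (seconds) and `upper` (logical).
#' @export
simulate_ddm <- function(params, n = NULL, dt = 1e-3, seed = NULL) {
  v <- as.numeric(params$drift)
  a <- as.numeric(params$boundary)
  tau <- as.numeric(params$ndt)
  if (is.null(n)) n <- max(length(v), length(a), length(tau))
  if (dt <= 0) stop("simulate_ddm: dt must be > 0")
  run <- function() .ddm_sim_cpp(v, a, tau, 0.5, dt, as.integer(n))
  sim <- if (is.null(seed)) run() else .local_seed(seed, run())
  data.frame(rt = sim$rt, upper = sim$upper)
}
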