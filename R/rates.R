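# Canonical activator-inhibitor kinetics shared by the STEN and CEN:
#   dF/dt = -(a1 + a2*(R - s_in))*F + a3*F^2/(a4^2 + F^2) + a5  [+ noise]
#   dR/dt = eps*(-R + c1*F)
# The STEN has s_in = 0 and receives the stochastic drive U_N instead.

.canon <- function(p) {
  if (is(p, "STENParams"))
    list(a1 = p@a1s, a2 = p@a2s, a3 = p@a3s, a4 = p@a4s, a5 = p@a5s,
         eps = p@eps_s, c1 = p@c1s)
  else if (is(p, "CENParams"))
    list(a1 = p@a1c, a2 = p@a2c, a3 = p@a3c, a4 = p@a4c, a5 = p@a5c,
         eps = p@eps_c, c1 = p@c1c)
  else stop("'p' must be STENParams or CENParams")
}

.act_rate <- function(f, r_eff, k)
  -(k$a1 + k$a2 * r_eff) * f + k$a3 * f^2 / (k$a4^2 + f^2) + k$a5

.check_finite <- function(...) {
  vals <- list(...)
  for (v in vals) if (any(!is.finite(v)))
    stop("non-finite input to reaction kinetics", call. = FALSE)
}

#' STEN point-wise reaction rates
#'
#' Evaluates the reaction part of the STEN activator-inhibitor pair
#' (diffusion is applied by the integrator):
#' \deqn{dF_S/dt = -(a_{1s} + a_{2s} R_S) F_S +
#'       a_{3s} F_S^2/(a_{4s}^2 + F_S^2) + a_{5s} + U_N}
#' \deqn{dR_S/dt = \epsilon_s (-R_S + c_{1s} F_S)}
#'
#' @param f_s,r_s activator and inhibitor concentrations (scalars or
#'   arrays of equal shape).
#' @param u_n instantaneous noise drive added to the activator rate.
#' @param p a [STENParams-class].
#' @return list with elements `df` and `dr`.
#' @examples
#' p <- stenParams()
#' stenRates(0, 0, 0, p)   # df = a5s at the origin
#' @export
stenRates <- function(f_s, r_s, u_n = 0, p = stenParams()) {
  .check_finite(f_s, r_s, u_n)
  k <- .canon(p)
  list(df = .act_rate(f_s, r_s, k) + u_n,
       dr = k$eps * (-r_s + k$c1 * f_s))
}

#' CEN point-wise reaction rates
#'
#' Same architecture as [stenRates()] but the STEN input `s_in` offsets
#' the effective inhibition: the decay term is
#' \eqn{-(a_{1c} + a_{2c}(R_C - s_{in})) F_C}, which raises the
#' activator nullcline vertically and lowers the firing threshold.
#'
#' @param f_c,r_c activator and inhibitor concentrations.
#' @param s_in coupling drive from the STEN (see [couplingInput()]).
#' @param p a [CENParams-class].
#' @return list with elements `df` and `dr`.
#' @export
cenRates <- function(f_c, r_c, s_in = 0, p = cenParams()) {
  .check_finite(f_c, r_c, s_in)
  k <- .canon(p)
  list(df = .act_rate(f_c, r_c - s_in, k),
       dr = k$eps * (-r_c + k$c1 * f_c))
}

#' CEN-to-STEN feedback species rates
#'
#' Linear production-decay kinetics of the fast local positive loop
#' \eqn{dZ_C/dt = -p_1 Z_C + p_2 F_C} and the slow global negative loop
#' \eqn{dW_C/dt = -p_3 W_C + p_4 F_C}.
#'
#' @param z_c,w_c feedback species concentrations.
#' @param f_c CEN activator concentration driving both loops.
#' @param p a [FeedbackParams-class].
#' @return list with elements `dz` and `dw`.
#' @export
feedbackRates <- function(z_c, w_c, f_c, p = feedbackParams()) {
  .check_finite(z_c, w_c, f_c)
  list(dz = -p@p1 * z_c + p@p2 * f_c,
       dw = -p@p3 * w_c + p@p4 * f_c)
}

#' STEN-to-CEN coupling drive
#'
#' \eqn{s_{in} = s_c (R_S - R_0)}: the CEN is slaved to the STEN
#' inhibitor's excursion above its resting level.  May be negative on
#' the inhibitor's under-shoot.
#'
#' @param r_s STEN inhibitor level (scalar or array).
#' @param p a [CENParams-class] supplying the gain `s_c`.
#' @param r0 reference inhibitor level (default: the shipped `r0`).
#' @return the coupling drive, same shape as `r_s`.
#' @export
couplingInput <- function(r_s, p = cenParams(), r0 = stenParams()@r0) {
  p@s_c * (r_s - r0)
}

#' STEN noise amplitude
#'
#' Standard deviation of the zero-mean Gaussian white-noise drive:
#' \eqn{\sigma_N = u_b + Z_C - W_C}, clamped below at zero (a standard
#' deviation cannot be negative; strong global inhibition therefore
#' silences triggering entirely).
#'
#' @param z_c,w_c feedback species concentrations (scalars or arrays).
#' @param p a [STENParams-class] supplying `u_b`.
#' @return \eqn{\max(0, u_b + Z_C - W_C)}.
#' @export
noiseSigma <- function(z_c, w_c, p = stenParams()) {
  pmax(0, p@u_b + z_c - w_c)
}

#' Activator nullcline roots at fixed inhibition
#'
#' Real nonnegative roots in F of the activator reaction rate at a
#' clamped effective inhibitor level.  Multiplying the rate by
#' \eqn{a_4^2 + F^2} turns it into a cubic, whose roots are found
#' exactly; generically there are 1 (rest only) or 3
#' (\eqn{F_- < F_0 < F_+}, the bistable window) of them.
#'
#' @param r inhibitor level.
#' @param p a [STENParams-class] or [CENParams-class].
#' @param s_in coupling drive offsetting the effective inhibition
#'   (CEN only; default 0).
#' @return sorted numeric vector of roots.
#' @export
nullclineRoots <- function(r, p, s_in = 0) {
  stopifnot(is.finite(r))
  k <- .canon(p)
  r_eff <- r - s_in
  b <- k$a1 + k$a2 * r_eff
  # rate * (a4^2 + F^2) = -b F^3 + (a3 + a5) F^2 - b a4^2 F + a5 a4^2
  co <- c(k$a5 * k$a4^2, -b * k$a4^2, k$a3 + k$a5, -b)
  while (length(co) > 1L && co[length(co)] == 0) co <- co[-length(co)]
  if (length(co) <= 1L) return(numeric(0))
  z <- polyroot(co)
  re <- Re(z)[abs(Im(z)) < 1e-7 & Re(z) >= -1e-12]
  re <- sort(pmax(re, 0))
  if (length(re) > 1L) re <- re[c(TRUE, diff(re) > 1e-9)]  # tangency dedupe
  # polish by local bisection where the rate changes sign
  g <- function(f) .act_rate(f, r_eff, k)
  vapply(re, function(f0) {
    lo <- max(0, f0 - 1e-4); hi <- f0 + 1e-4
    if (sign(g(lo)) * sign(g(hi)) < 0)
      stats::uniroot(g, c(lo, hi), tol = 1e-13)$root else f0
  }, numeric(1))
}

#' Sample the activator nullcline R(F)
#'
#' Solves the activator rate for the inhibitor level at each F, giving
#' the cubic-shaped nullcline \eqn{R(F) = [a_3 F^2/(a_4^2+F^2) + a_5 -
#' a_1 F]/(a_2 F)} (plus `s_in` for the CEN).
#'
#' @param f activator values (> 0).
#' @inheritParams nullclineRoots
#' @return inhibitor levels, same length as `f`.
#' @export
activatorNullcline <- function(f, p, s_in = 0) {
  k <- .canon(p)
  (k$a3 * f^2 / (k$a4^2 + f^2) + k$a5 - k$a1 * f) / (k$a2 * f) + s_in
}

# Fold (local minimum) of the activator nullcline: c(F_min, R_min).
# The nullcline diverges at F -> 0+, dips to a local minimum, rises to a
# local maximum, then falls off; we want the first interior local
# minimum, not the large-F decline.
.cubic_minimum <- function(p, s_in = 0, f_max = 50) {
  nf <- function(f) activatorNullcline(f, p, s_in)
  fg <- exp(seq(log(1e-5), log(f_max), length.out = 6000))
  v <- nf(fg)
  d <- diff(v)
  im <- which(d[-1] > 0 & d[-length(d)] < 0) + 1L  # discrete local minima
  if (!length(im))
    stop("activator nullcline has no fold: system is not excitable",
         call. = FALSE)
  i <- im[1L]
  opt <- stats::optimize(nf, c(fg[i - 1L], fg[i + 1L]), tol = 1e-12)
  c(F = opt$minimum, R = opt$objective)
}

#' Resting equilibrium of one excitable pair
#'
#' Intersection of the activator nullcline with the inhibitor nullcline
#' `R = c1 F`, taking the lowest-F crossing (the rest state on the left
#' branch for an excitable set).
#'
#' @inheritParams nullclineRoots
#' @return named numeric `c(F, R)`.
#' @export
equilibriumState <- function(p, s_in = 0) {
  k <- .canon(p)
  g <- function(f) .act_rate(f, k$c1 * f - s_in, k)
  fg <- seq(1e-6, 20, length.out = 4000)
  s <- sign(g(fg))
  ix <- which(diff(s) != 0)
  if (!length(ix)) stop("no equilibrium found", call. = FALSE)
  f_star <- stats::uniroot(g, c(fg[ix[1L]], fg[ix[1L] + 1L]), tol = 1e-13)$root
  c(F = f_star, R = k$c1 * f_star)
}

#' Is a parameter set excitable?
#'
#' Requires a fold in the activator nullcline, a unique equilibrium on
#' the left branch (rest-state F below the fold F), and a positive
#' threshold (resting inhibition above the fold minimum).
#'
#' @inheritParams nullclineRoots
#' @return logical.
#' @export
isExcitable <- function(p, s_in = 0) {
  ok <- tryCatch({
    cm <- .cubic_minimum(p, s_in)
    eq <- equilibriumState(p, s_in)
    rts <- nullclineRoots(eq[["R"]], p, s_in)
    eq[["F"]] < cm[["F"]] && eq[["R"]] > cm[["R"]] && length(rts) == 3L
  }, error = function(e) FALSE)
  isTRUE(ok)
}
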