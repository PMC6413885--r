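#' @import methods
NULL

.nonneg <- function(x, nm) {
  if (any(!is.finite(x)) || any(x < 0))
    return(sprintf("'%s' must be finite and >= 0", nm))
  NULL
}

#' Parameters of the signal-transduction excitable network (STEN)
#'
#' Holds every rate, diffusion and noise constant of the slow
#' activator--inhibitor pair (F_S, R_S).  The activator obeys
#' dF_S/dt = -(a1s + a2s R_S) F_S + a3s F_S^2/(a4s^2 + F_S^2) + a5s + U_N
#' and the inhibitor dR_S/dt = eps_s (-R_S + c1s F_S), plus diffusion.
#'
#' @slot d_fs,d_rs diffusion coefficients (space^2/time).
#' @slot a1s basal activator decay rate.
#' @slot a2s inhibitor-dependent decay rate.
#' @slot a3s autocatalytic positive-feedback strength.
#' @slot a4s half-saturation constant of the Hill term.
#' @slot a5s basal production rate.
#' @slot eps_s inhibitor time-scale (1/time); small values mean a slow
#'   inhibitor and a long refractory tail.
#' @slot c1s slope of the (linear) inhibitor nullcline.
#' @slot u_b basal amplitude of the stochastic drive; fires the network
#'   even when the cytoskeletal layer is silenced.
#' @slot r0 reference (basal) inhibitor level used by the STEN-to-CEN
#'   coupling.
#' @export
setClass("STENParams", representation(
  d_fs = "numeric", d_rs = "numeric",
  a1s = "numeric", a2s = "numeric", a3s = "numeric", a4s = "numeric",
  a5s = "numeric", eps_s = "numeric", c1s = "numeric",
  u_b = "numeric", r0 = "numeric"))

setValidity("STENParams", function(object) {
  msgs <- c(
    .nonneg(c(object@d_fs, object@d_rs, object@a1s, object@a2s, object@a3s,
              object@a4s, object@a5s, object@eps_s, object@c1s, object@u_b,
              object@r0), "STENParams constants"),
    if (object@eps_s <= 0) "'eps_s' must be > 0",
    if (object@a4s <= 0) "'a4s' must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Parameters of the cytoskeletal excitable network (CEN)
#'
#' Same activator--inhibitor architecture as [STENParams-class] but
#' roughly eight-fold faster (larger `eps_c`) and spatially confined
#' (small diffusion).  The STEN input enters as an offset `s_in` on the
#' effective inhibition: -(a1c + a2c (R_C - s_in)) F_C.
#'
#' @slot d_fc,d_rc diffusion coefficients.
#' @slot a1c self-degradation rate of the CEN activator.
#' @slot a2c,a3c,a4c,a5c reaction constants, as in the STEN.
#' @slot eps_c inhibitor time-scale; defaults satisfy eps_c/eps_s = 8.
#' @slot c1c inhibitor-nullcline slope.
#' @slot s_c gain of the STEN-to-CEN coupling s_in = s_c (R_S - r0).
#' @slot sigma_c amplitude of CEN's own stochastic drive.
#' @export
setClass("CENParams", representation(
  d_fc = "numeric", d_rc = "numeric",
  a1c = "numeric", a2c = "numeric", a3c = "numeric", a4c = "numeric",
  a5c = "numeric", eps_c = "numeric", c1c = "numeric",
  s_c = "numeric", sigma_c = "numeric"))

setValidity("CENParams", function(object) {
  msgs <- c(
    .nonneg(c(object@d_fc, object@d_rc, object@a1c, object@a2c, object@a3c,
              object@a4c, object@a5c, object@eps_c, object@c1c, object@s_c,
              object@sigma_c), "CENParams constants"),
    if (object@eps_c <= 0) "'eps_c' must be > 0",
    if (object@a4c <= 0) "'a4c' must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Parameters of the CEN-to-STEN feedback loops
#'
#' A fast, local positive-feedback species Z_C (dZ_C/dt = -p1 Z_C + p2 F_C)
#' and a slow, global negative-feedback species W_C
#' (dW_C/dt = -p3 W_C + p4 F_C).  Both feed the STEN noise amplitude
#' sigma_N = u_b + Z_C - W_C.  `d_wc = Inf` marks W_C as spatially
#' uniform (instantaneous global mixing).
#'
#' @slot d_zc,d_wc diffusion coefficients; the default `d_wc` is `Inf`.
#' @slot p1,p2 decay and production rates of Z_C.
#' @slot p3,p4 decay and production rates of W_C; the shipped defaults
#'   give a steady-state gain ratio (p4/p3)/(p2/p1) of exactly 2.
#' @export
setClass("FeedbackParams", representation(
  d_zc = "numeric", d_wc = "numeric",
  p1 = "numeric", p2 = "numeric", p3 = "numeric", p4 = "numeric"))

setValidity("FeedbackParams", function(object) {
  v <- c(object@d_zc, object@p1, object@p2, object@p3, object@p4)
  msgs <- c(
    .nonneg(v, "FeedbackParams constants"),
    if (!(object@d_wc >= 0)) "'d_wc' must be >= 0 (Inf allowed)")
  if (length(msgs)) msgs else TRUE
})

#' Full coupled-model parameter set
#'
#' Aggregates [STENParams-class], [CENParams-class] and
#' [FeedbackParams-class].  Construct with [modelParams()] or load a
#' configuration file with [readModelConfig()].
#'
#' @slot sten a `STENParams`.
#' @slot cen a `CENParams`.
#' @slot feedback a `FeedbackParams`.
#' @export
setClass("ModelParams", representation(
  sten = "STENParams", cen = "CENParams", feedback = "FeedbackParams"))

#' Simulation grid description
#'
#' @slot shape integer vector, `n_x` or `c(n_x, n_y)`.
#' @slot spacing grid step in space units.
#' @slot boundary `"no-flux"` or `"periodic"`.
#' @export
setClass("GridSpec", representation(
  shape = "integer", spacing = "numeric", boundary = "character"))

setValidity("GridSpec", function(object) {
  msgs <- c(
    if (!length(object@shape) %in% 1:2 || any(object@shape < 1))
      "'shape' must be 1 or 2 positive integers",
    if (object@spacing <= 0) "'spacing' must be > 0",
    if (!object@boundary %in% c("no-flux", "periodic"))
      "'boundary' must be 'no-flux' or 'periodic'")
  if (length(msgs)) msgs else TRUE
})

#' State of all six dynamic fields at one time point
#'
#' @slot t simulation time.
#' @slot fields named list of arrays `F_S, R_S, F_C, R_C, Z_C, W_C`,
#'   each shaped like the grid.
#' @slot grid the [GridSpec-class] the fields live on.
#' @slot rng_state the `.Random.seed` vector captured when the state was
#'   made; advancing two states with equal `rng_state` is bit-identical.
#' @export
setClass("FieldState", representation(
  t = "numeric", fields = "list", grid = "GridSpec", rng_state = "integer"))

setValidity("FieldState", function(object) {
  need <- c("F_S", "R_S", "F_C", "R_C", "Z_C", "W_C")
  msgs <- c(
    if (!all(need %in% names(object@fields)))
      paste("fields must contain", paste(need, collapse = ", ")),
    if (!all(vapply(object@fields, function(f) all(is.finite(f)), logical(1))))
      "all fields must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Saved simulation trajectory
#'
#' @slot times save times (monotone increasing).
#' @slot frames list (one element per save time) of named lists of field
#'   arrays; which fields are saved is set by `run`'s `save_fields`.
#' @slot grid the [GridSpec-class].
#' @slot params the [ModelParams-class] the run started from.
#' @slot norm named list of fixed normalisation constants
#'   (`lo`/`hi` per readout channel) recorded for invertible scaling.
#' @slot seed integer seed of the run.
#' @export
setClass("Trajectory", representation(
  times = "numeric", frames = "list", grid = "GridSpec",
  params = "ModelParams", norm = "list", seed = "integer"))

setValidity("Trajectory", function(object) {
  if (length(object@times) && any(diff(object@times) <= 0))
    "save times must be strictly increasing" else TRUE
})

#' Phase-plane analysis report for one excitable pair
#'
#' @slot activator_nullcline two-column matrix (F, R) sampling the cubic
#'   activator nullcline.
#' @slot inhibitor_nullcline two-column matrix (F, R).
#' @slot equilibrium numeric `c(F, R)` resting state.
#' @slot cubic_minimum numeric `c(F, R)` at the local minimum (fold) of
#'   the activator nullcline.
#' @slot threshold signed threshold `r0 - R_min`; larger is harder to
#'   excite.
#' @slot net_area_curve two-column matrix (r0, A) sampling the net area
#'   under the activator rate between outer roots.
#' @slot r_stop inhibitor level at which the net area vanishes and wave
#'   propagation stops.
#' @slot window numeric `c(R_low, R_high)` bistable window.
#' @slot speed_class one of `"no-spread"`, `"excitable-waves"`,
#'   `"synchronous-oscillation"`.
#' @export
setClass("PhasePlaneReport", representation(
  activator_nullcline = "matrix", inhibitor_nullcline = "matrix",
  equilibrium = "numeric", cubic_minimum = "numeric",
  threshold = "numeric", net_area_curve = "matrix",
  r_stop = "numeric", window = "numeric", speed_class = "character"))

#' Image stack with physical metadata
#'
#' Container for simulated readouts and synthetic microscopy: a 4-D
#' pixel array indexed (y, x, frame, channel) plus pixel size and frame
#' interval.
#'
#' @slot pixels numeric 4-D array `[y, x, t, channel]`.
#' @slot pixel_size length per pixel.
#' @slot frame_interval time per frame.
#' @slot channels character labels, one per channel.
#' @export
setClass("WaveMovie", representation(
  pixels = "array", pixel_size = "numeric", frame_interval = "numeric",
  channels = "character"))

setValidity("WaveMovie", function(object) {
  msgs <- c(
    if (length(dim(object@pixels)) != 4L)
      "'pixels' must be a 4-D array [y, x, t, channel]",
    if (!is.finite(object@pixel_size) || object@pixel_size <= 0)
      "'pixel_size' must be positive",
    if (!is.finite(object@frame_interval) || object@frame_interval <= 0)
      "'frame_interval' must be positive",
    if (any(!is.finite(object@pixels))) "pixels must be finite",
    if (length(object@channels) != dim(object@pixels)[4])
      "one channel label per channel")
  if (length(msgs)) msgs else TRUE
})

#' Wave-speed quantification report
#'
#' @slot mean_speed per-frame-pair mean front displacement per unit time
#'   (length/time), over accepted boundary pixels.
#' @slot accepted_count per-frame-pair number of boundary-pixel
#'   displacements inside the low/high acceptance band.
#' @slot fraction_fastest fraction of accepted boundary pixels, over the
#'   whole video, whose displacement exceeds the video mean by at least
#'   one standard deviation.
#' @slot patch_count per-frame number of segmented wave patches.
#' @slot mean_patch_area per-frame mean patch area (length^2); `NaN`
#'   when a frame has no patches.
#' @slot video_mean_speed overall mean speed (accepted pixels pooled).
#' @export
setClass("SpeedReport", representation(
  mean_speed = "numeric", accepted_count = "numeric",
  fraction_fastest = "numeric", patch_count = "numeric",
  mean_patch_area = "numeric", video_mean_speed = "numeric"))

setValidity("SpeedReport", function(object) {
  msgs <- c(
    if (length(object@fraction_fastest) &&
        (object@fraction_fastest < 0 || object@fraction_fastest > 1))
      "'fraction_fastest' must lie in [0, 1]",
    if (any(object@mean_speed < 0, na.rm = TRUE)) "speeds must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Viscoelastic mechanical parameters of the cell boundary
#'
#' @slot k_el cortex/membrane elasticity (K).
#' @slot d_visc membrane viscosity (D).
#' @slot b_visc cytoplasm viscosity (B).
#' @slot tension_coef surface-tension stress per unit curvature.
#' @slot volume_gain stress per unit relative area error (proportional
#'   volume-conservation control).
#' @slot protrusion_gain stress per unit wave activity.
#' @export
setClass("MechParams", representation(
  k_el = "numeric", d_visc = "numeric", b_visc = "numeric",
  tension_coef = "numeric", volume_gain = "numeric",
  protrusion_gain = "numeric"))

setValidity("MechParams", function(object) {
  v <- c(object@k_el, object@d_visc, object@b_visc, object@tension_coef,
         object@volume_gain, object@protrusion_gain)
  if (any(!is.finite(v)) || any(v <= 0))
    "all mechanical constants must be finite and > 0" else TRUE
})

#' Implicit cell shape for level-set simulation
#'
#' The boundary is the zero level set of the signed distance field
#' `phi` (negative inside).  Cortex displacement `x_cor` is carried as a
#' grid field sampled near the interface.
#'
#' @slot phi numeric matrix, signed distance to the boundary.
#' @slot x_cor numeric matrix, normal cortex displacement field.
#' @slot grid the [GridSpec-class].
#' @slot reference_area enclosed area at construction time.
#' @export
setClass("CellShape", representation(
  phi = "matrix", x_cor = "matrix", grid = "GridSpec",
  reference_area = "numeric"))

setValidity("CellShape", function(object) {
  msgs <- c(
    if (!all(dim(object@phi) == dim(object@x_cor)))
      "'phi' and 'x_cor' must have equal dimensions",
    if (!any(object@phi < 0) || !any(object@phi > 0))
      "'phi' must change sign (closed boundary inside the grid)",
    if (object@reference_area <= 0) "'reference_area' must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Specification of a synthetic two-channel wave movie
#'
#' Emulates basal-surface cortical wave movies: a diffuse one-peak
#' STEN-like band and a sharp two-peak CEN-like band with trailing
#' short-lived puncta, translating at a programmed speed.
#'
#' @slot speed programmed wave speed (length/time).
#' @slot direction unit propagation vector `c(dx, dy)`.
#' @slot sten_band_width,cen_peak_width,cen_peak_separation lengths.
#' @slot cen_mid_dip_fraction intermediate intensity between the two CEN
#'   peaks, as a fraction of peak intensity, in (0, 1).
#' @slot channel_offset signed along-direction displacement of the STEN
#'   band relative to the CEN leading peak (length).
#' @slot puncta_rate trailing-puncta birth rate (events/area/time).
#' @slot puncta_lifetime_mean mean exponential punctum lifetime (time).
#' @slot noise_sd additive Gaussian noise amplitude (intensity units).
#' @slot pixel_size,frame_interval,duration acquisition metadata.
#' @slot shape integer `c(n_y, n_x)` frame shape in pixels.
#' @slot seed integer reproducibility seed.
#' @export
setClass("SyntheticWaveSpec", representation(
  speed = "numeric", direction = "numeric",
  sten_band_width = "numeric", cen_peak_width = "numeric",
  cen_peak_separation = "numeric", cen_mid_dip_fraction = "numeric",
  channel_offset = "numeric", puncta_rate = "numeric",
  puncta_lifetime_mean = "numeric", noise_sd = "numeric",
  pixel_size = "numeric", frame_interval = "numeric",
  duration = "numeric", shape = "integer", seed = "integer"))

setValidity("SyntheticWaveSpec", function(object) {
  msgs <- c(
    if (object@speed < 0) "'speed' must be >= 0",
    if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-6)
      "'direction' must be a unit vector",
    .nonneg(c(object@puncta_rate, object@noise_sd), "rates/noise"),
    if (any(c(object@sten_band_width, object@cen_peak_width,
              object@cen_peak_separation, object@puncta_lifetime_mean,
              object@pixel_size, object@frame_interval,
              object@duration) <= 0))
      "widths, lifetimes, metadata and duration must be > 0",
    if (object@cen_mid_dip_fraction <= 0 || object@cen_mid_dip_fraction >= 1)
      "'cen_mid_dip_fraction' must lie in (0, 1)")
  if (length(msgs)) msgs else TRUE
})
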