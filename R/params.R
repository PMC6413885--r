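.STEN_KEYS <- c("d_fs", "d_rs", "a1s", "a2s", "a3s", "a4s", "a5s",
                "eps_s", "c1s", "u_b", "r0")
.CEN_KEYS  <- c("d_fc", "d_rc", "a1c", "a2c", "a3c", "a4c", "a5c",
                "eps_c", "c1c", "s_c", "sigma_c")
.FB_KEYS   <- c("d_zc", "d_wc", "p1", "p2", "p3", "p4")
.ALL_KEYS  <- c(.STEN_KEYS, .CEN_KEYS, .FB_KEYS)

.default_config_env <- new.env(parent = emptyenv())

.default_config <- function() {
  if (!exists("cfg", envir = .default_config_env)) {
    path <- system.file("extdata", "default_params.cfg", package = "stencen",
                        mustWork = TRUE)
    assign("cfg", .parse_config(path), envir = .default_config_env)
  }
  get("cfg", envir = .default_config_env)
}

.parse_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  unknown <- setdiff(keys, .ALL_KEYS)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicated parameter key(s) in config")
  if (any(is.na(vals)))
    stop("non-numeric value for key(s): ", paste(keys[is.na(vals)], collapse = ", "))
  as.list(stats::setNames(vals, keys))
}

.fill_keys <- function(keys, dots, base) {
  cfg <- base[keys]
  extra <- setdiff(names(dots), keys)
  if (length(extra))
    stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Construct STEN parameters
#'
#' Starts from the shipped default configuration and overrides any named
#' constants.  See [STENParams-class] for the meaning of each symbol.
#'
#' @param ... named numeric overrides, e.g. `a3s = 5`.
#' @return a validated `STENParams` object.
#' @examples
#' stenParams()
#' stenParams(a3s = 5, eps_s = 0.03)
#' @export
stenParams <- function(...) {
  cfg <- .fill_keys(.STEN_KEYS, list(...), .default_config())
  new("STENParams", d_fs = cfg$d_fs, d_rs = cfg$d_rs, a1s = cfg$a1s,
      a2s = cfg$a2s, a3s = cfg$a3s, a4s = cfg$a4s, a5s = cfg$a5s,
      eps_s = cfg$eps_s, c1s = cfg$c1s, u_b = cfg$u_b, r0 = cfg$r0)
}

#' Construct CEN parameters
#' @param ... named numeric overrides, e.g. `a3c = 5`.
#' @return a validated `CENParams` object.
#' @export
cenParams <- function(...) {
  cfg <- .fill_keys(.CEN_KEYS, list(...), .default_config())
  new("CENParams", d_fc = cfg$d_fc, d_rc = cfg$d_rc, a1c = cfg$a1c,
      a2c = cfg$a2c, a3c = cfg$a3c, a4c = cfg$a4c, a5c = cfg$a5c,
      eps_c = cfg$eps_c, c1c = cfg$c1c, s_c = cfg$s_c,
      sigma_c = cfg$sigma_c)
}

#' Construct CEN-to-STEN feedback parameters
#' @param ... named numeric overrides, e.g. `p3 = 0.1`.
#' @return a validated `FeedbackParams` object.
#' @export
feedbackParams <- function(...) {
  cfg <- .fill_keys(.FB_KEYS, list(...), .default_config())
  new("FeedbackParams", d_zc = cfg$d_zc, d_wc = cfg$d_wc, p1 = cfg$p1,
      p2 = cfg$p2, p3 = cfg$p3, p4 = cfg$p4)
}

#' Construct the full coupled-model parameter set
#'
#' @param sten,cen,feedback component parameter objects; defaults come
#'   from the shipped configuration file.
#' @param ... named flat overrides applied on top (any key accepted by
#'   the configuration schema, e.g. `a3s = 5, sigma_c = 0`).
#' @return a `ModelParams` object.
#' @examples
#' p <- modelParams(a3s = 5)
#' modelParam(p, "sten.a3s")
#' @export
modelParams <- function(sten = stenParams(), cen = cenParams(),
                        feedback = feedbackParams(), ...) {
  p <- new("ModelParams", sten = sten, cen = cen, feedback = feedback)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("overrides must be named")
    for (k in names(dots)) modelParam(p, .flat_to_path(k)) <- dots[[k]]
  }
  p
}

.flat_to_path <- function(key) {
  if (key %in% .STEN_KEYS) return(paste0("sten.", key))
  if (key %in% .CEN_KEYS)  return(paste0("cen.", key))
  if (key %in% .FB_KEYS)   return(paste0("feedback.", key))
  stop("unknown parameter key: ", key)
}

.split_path <- function(path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) parts <- strsplit(.flat_to_path(path), ".",
                                             fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !parts[1L] %in% c("sten", "cen", "feedback"))
    stop("invalid parameter path: ", path)
  block_keys <- switch(parts[1L], sten = .STEN_KEYS, cen = .CEN_KEYS,
                       feedback = .FB_KEYS)
  if (!parts[2L] %in% block_keys)
    stop("unknown parameter '", parts[2L], "' in block '", parts[1L], "'")
  parts
}

#' Get or set one model constant by path
#'
#' Paths are `"block.symbol"` (`"sten.a3s"`) or the bare symbol
#' (`"a3s"`), which is unambiguous because symbol names are unique
#' across blocks.
#'
#' @param p a [ModelParams-class].
#' @param path parameter path.
#' @param value replacement value.
#' @return the numeric value, or the modified `ModelParams`.
#' @export
modelParam <- function(p, path) {
  parts <- .split_path(path)
  slot(slot(p, parts[1L]), parts[2L])
}

#' @rdname modelParam
#' @export
`modelParam<-` <- function(p, path, value) {
  parts <- .split_path(path)
  blk <- slot(p, parts[1L])
  slot(blk, parts[2L]) <- value
  validObject(blk)
  slot(p, parts[1L]) <- blk
  p
}

#' Read or write a flat model configuration file
#'
#' The format is plain text, one `symbol = value` pair per line,
#' `#` comments allowed; unknown keys are rejected.  Keys absent from
#' the file keep their shipped defaults.
#'
#' @param path file path.
#' @return `readModelConfig`: a [ModelParams-class];
#'   `writeModelConfig`: `path`, invisibly.
#' @export
readModelConfig <- function(path) {
  cfg <- utils::modifyList(.default_config(), .parse_config(path))
  modelParams(
    sten = do.call(stenParams, cfg[.STEN_KEYS]),
    cen = do.call(cenParams, cfg[.CEN_KEYS]),
    feedback = do.call(feedbackParams, cfg[.FB_KEYS]))
}

#' @rdname readModelConfig
#' @param p a [ModelParams-class] to serialise.
#' @export
writeModelConfig <- function(p, path) {
  stopifnot(is(p, "ModelParams"))
  fmt <- function(keys, obj)
    vapply(keys, function(k) sprintf("%s = %.17g", k, slot(obj, k)), "")
  writeLines(c("# coupled STEN-CEN model parameters",
               fmt(.STEN_KEYS, p@sten), fmt(.CEN_KEYS, p@cen),
               fmt(.FB_KEYS, p@feedback)), path)
  invisible(path)
}

#' Construct a simulation grid
#'
#' @param shape one or two positive integers (`n_x` or `c(n_x, n_y)`).
#' @param spacing grid step, space units per grid point.
#' @param boundary `"no-flux"` (default; waves stop at the cell edge) or
#'   `"periodic"`.
#' @return a `GridSpec`.
#' @examples
#' gridSpec(3000)           # fine 1D grid for wave-theory runs
#' gridSpec(c(200, 200))    # coarse 2D grid for whole-cell runs
#' @export
gridSpec <- function(shape, spacing = 1, boundary = c("no-flux", "periodic")) {
  new("GridSpec", shape = as.integer(shape), spacing = spacing,
      boundary = match.arg(boundary))
}

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams (coupled STEN-CEN excitable model)\n")
  cat(sprintf("  STEN: a1s=%.3g a2s=%.3g a3s=%.3g a4s=%.3g a5s=%.3g eps_s=%.3g c1s=%.3g\n",
              object@sten@a1s, object@sten@a2s, object@sten@a3s,
              object@sten@a4s, object@sten@a5s, object@sten@eps_s,
              object@sten@c1s))
  cat(sprintf("        D_F=%.3g D_R=%.3g u_b=%.3g r0=%.4g\n",
              object@sten@d_fs, object@sten@d_rs, object@sten@u_b,
              object@sten@r0))
  cat(sprintf("  CEN:  a1c=%.3g a2c=%.3g a3c=%.3g a4c=%.3g a5c=%.3g eps_c=%.3g c1c=%.3g\n",
              object@cen@a1c, object@cen@a2c, object@cen@a3c, object@cen@a4c,
              object@cen@a5c, object@cen@eps_c, object@cen@c1c))
  cat(sprintf("        D_F=%.3g D_R=%.3g s_c=%.3g sigma_c=%.3g\n",
              object@cen@d_fc, object@cen@d_rc, object@cen@s_c,
              object@cen@sigma_c))
  cat(sprintf("  feedback: p1=%.3g p2=%.3g p3=%.3g p4=%.3g d_zc=%.3g d_wc=%.3g\n",
              object@feedback@p1, object@feedback@p2, object@feedback@p3,
              object@feedback@p4, object@feedback@d_zc, object@feedback@d_wc))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %s, spacing %.3g, %s boundary\n",
              paste(object@shape, collapse = " x "), object@spacing,
              object@boundary))
})
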