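#' Construct an rstDDM parameter set
#'
#' The relative-starting-time DDM has seven free parameters; the decision
#' thresholds are fixed at \code{[-1, +1]} and are not estimated.
#'
#' @param noise Diffusion standard deviation (a.u. per sqrt-second); must be
#'   positive. Because the thresholds are fixed, \code{noise} sets the scale
#'   of the accumulation process.
#' @param sp_bias Starting-point bias in (0, 1); 0.5 starts the accumulator
#'   midway between the bounds (mapped affinely onto \code{[-1, 1]}).
#' @param ndt Non-decision time in seconds (encoding + motor), >= 0.
#' @param rst Relative start time in seconds: onset of the health attribute
#'   minus onset of the taste attribute. Positive values mean taste is
#'   considered first.
#' @param w_taste,w_health Drift weights (a.u. per rating unit) applied to the
#'   left-minus-right taste and health rating differences.
#' @param drift_bias Constant drift intercept (a.u./s) independent of either
#'   attribute.
#' @return An object of class \code{rst_params} (a named list).
#' @examples
#' p <- rst_params(noise = 1, ndt = 0.6, rst = 0.18, w_taste = 0.89,
#'                 w_health = -0.13, drift_bias = 0.02)
#' p
#' @export
rst_params <- function(noise = 1, sp_bias = 0.5, ndt = 0.5, rst = 0,
                       w_taste = 0, w_health = 0, drift_bias = 0) {
  p <- list(noise = noise, sp_bias = sp_bias, ndt = ndt, rst = rst,
            w_taste = w_taste, w_health = w_health, drift_bias = drift_bias)
  validate_rst_params(p)
  structure(p, class = "rst_params")
}

validate_rst_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("noise", "sp_bias", "ndt", "rst", "w_taste", "w_health",
               "drift_bias")) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar",
                             call. = FALSE)
  }
  if (p$noise <= 0) stop("'noise' must be > 0", call. = FALSE)
  if (p$sp_bias <= 0 || p$sp_bias >= 1)
    stop("'sp_bias' must lie strictly in (0, 1)", call. = FALSE)
  if (p$ndt < 0) stop("'ndt' must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.rst_params <- function(x, ...) {
  cat("rstDDM parameters (thresholds fixed at [-1, +1]):\n")
  v <- unlist(x)
  for (nm in names(v)) cat(sprintf("  %-10s %8.4f\n", nm, v[nm]))
  invisible(x)
}

# internal: ordered numeric vector used by the C++ routines
par_vec <- function(p) {
  as.numeric(c(p$noise, p$sp_bias, p$ndt, p$rst, p$w_taste, p$w_health,
               p$drift_bias))
}

par_names <- c("noise", "sp_bias", "ndt", "rst", "w_taste", "w_health",
               "drift_bias")

#' Serialize / deserialize rstDDM parameter sets as JSON
#'
#' Field names match the model's standard labels so parameter files are
#' self-describing.
#'
#' @param params An \code{rst_params} object.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return \code{params_to_json}: a JSON string (invisibly, if written to
#'   file). \code{params_from_json}: an \code{rst_params} object.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "rst_params"))
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname params_to_json
#' @param json A JSON string or path to a JSON file produced by
#'   \code{params_to_json}.
#' @export
params_from_json <- function(json) {
  x <- if (file.exists(json)) jsonlite::fromJSON(json) else
    jsonlite::fromJSON(txt = json)
  do.call(rst_params, x[par_names])
}
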