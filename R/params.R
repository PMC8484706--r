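#' Morphological parameter ranges for side-wall aneurysm models
#'
#' Default sampling ranges for the five morphological parameters: sac
#' diameter `DA` (mm), sac-center-to-centerline distance `CC` (mm), parent
#' artery diameter `DP` (mm), parent artery centerline curvature `CP`
#' (1/mm, curved arteries only) and the angular location `LA` of the sac
#' along the curved artery (degrees).
#'
#' @return named list of length-2 numeric ranges.
#' @export
default_param_ranges <- function() {
  list(
    DA = c(8.0, 12.0),
    CC = c(6.0, 8.0),
    DP = c(8.0, 12.0),
    CP = c(0.01, 0.033),
    LA = c(0, 180)
  )
}

#' Construct a set of aneurysm morphological parameters
#'
#' `model_type` `"type1"` is a straight parent artery (`CP = 0`, sac at a
#' fixed canonical station); `"type2"` is a constant-curvature curved parent
#' artery. All lengths in mm, curvature in 1/mm, `LA` in degrees.
#'
#' @param model_type `"type1"` or `"type2"`.
#' @param DA,CC,DP,CP,LA numeric scalars, see [default_param_ranges()].
#' @param validate check the geometric-validity inequalities (default TRUE).
#' @return object of class `aneurysm_params`.
#' @export
aneurysm_params <- function(model_type, DA, CC, DP, CP = 0, LA = 90,
                            validate = TRUE) {
  model_type <- match.arg(model_type, c("type1", "type2"))
  p <- structure(
    list(model_type = model_type, DA = DA, CC = CC, DP = DP, CP = CP, LA = LA),
    class = "aneurysm_params"
  )
  if (model_type == "type1" && CP != 0)
    stop("type1 (straight) parent artery requires CP = 0")
  if (validate) validate_params(p)
  p
}

#' Check geometric validity of a parameter draw
#'
#' The sac sphere must intersect the artery wall without being swallowed by
#' the lumen: `CC < (DA + DP)/2` (sphere reaches the wall) and
#' `CC + DA/2 > DP/2` (sphere pokes out of the lumen).
#'
#' @param p an `aneurysm_params` object.
#' @param ranges optional ranges to check against (NULL skips range checks).
#' @return invisibly TRUE, or an error describing the violation.
#' @export
validate_params <- function(p, ranges = NULL) {
  stopifnot(inherits(p, "aneurysm_params"))
  if (!params_valid(p))
    stop("degenerate parameters: need CC < (DA+DP)/2 and CC + DA/2 > DP/2 ",
         sprintf("(DA=%.3f CC=%.3f DP=%.3f)", p$DA, p$CC, p$DP))
  if (!is.null(ranges)) {
    for (nm in c("DA", "CC", "DP")) {
      r <- ranges[[nm]]
      if (p[[nm]] < r[1] || p[[nm]] > r[2])
        stop(sprintf("%s = %.4f outside range [%g, %g]", nm, p[[nm]], r[1], r[2]))
    }
    if (p$model_type == "type2") {
      for (nm in c("CP", "LA")) {
        r <- ranges[[nm]]
        if (p[[nm]] < r[1] || p[[nm]] > r[2])
          stop(sprintf("%s = %.4f outside range [%g, %g]", nm, p[[nm]], r[1], r[2]))
      }
    }
  }
  invisible(TRUE)
}

params_valid <- function(p) {
  (p$CC < (p$DA + p$DP) / 2) && (p$CC + p$DA / 2 > p$DP / 2)
}

#' Sample morphological parameters
#'
#' Draws each parameter independently and uniformly from its range and
#' rejects draws that violate the geometric-validity inequalities
#' (resampling up to `max_attempts` times). For `"type1"` the artery is
#' straight (`CP = 0`) and `LA` is fixed at 90 degrees (canonical sac
#' placement); for `"type2"` both `CP` and `LA` are sampled.
#'
#' @param model_type `"type1"` or `"type2"`.
#' @param seed integer seed; identical seeds give identical draws.
#' @param ranges parameter ranges, defaults to [default_param_ranges()].
#' @param max_attempts rejection-sampling bound.
#' @return an `aneurysm_params` object.
#' @export
sample_params <- function(model_type, seed = NULL,
                          ranges = default_param_ranges(),
                          max_attempts = 1000L) {
  model_type <- match.arg(model_type, c("type1", "type2"))
  local_seed(seed, {
    for (i in seq_len(max_attempts)) {
      DA <- stats::runif(1, ranges$DA[1], ranges$DA[2])
      CC <- stats::runif(1, ranges$CC[1], ranges$CC[2])
      DP <- stats::runif(1, ranges$DP[1], ranges$DP[2])
      if (model_type == "type2") {
        CP <- stats::runif(1, ranges$CP[1], ranges$CP[2])
        LA <- stats::runif(1, ranges$LA[1], ranges$LA[2])
      } else {
        CP <- 0; LA <- 90
      }
      p <- aneurysm_params(model_type, DA, CC, DP, CP, LA, validate = FALSE)
      if (params_valid(p)) return(p)
    }
    stop("sample_params: exceeded max_attempts rejection resampling; ",
         "check that the configured ranges admit valid geometries")
  })
}

#' @export
print.aneurysm_params <- function(x, ...) {
  cat(sprintf(
    "aneurysm_params [%s]: DA=%.3f mm  CC=%.3f mm  DP=%.3f mm  CP=%.4f 1/mm  LA=%.1f deg\n",
    x$model_type, x$DA, x$CC, x$DP, x$CP, x$LA))
  invisible(x)
}
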