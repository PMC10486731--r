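#' @keywords internal
"_PACKAGE"

#' @useDynLib octafusion, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom median approx
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Severity grade labels
#'
#' The six-level ordinal severity scale used as labels: 0 absence of DR,
#' 1 mild NPDR, 2 moderate NPDR, 3 severe NPDR, 4 PDR, 5 PRP (eyes treated
#' by panretinal photocoagulation, ranked above PDR and grouped with it for
#' the most severe binary task).
#'
#' @return Character vector of length 6 named by grade `0:5`.
#' @export
severity_levels <- function() {
  stats::setNames(c("no DR", "mild NPDR", "moderate NPDR", "severe NPDR",
                    "PDR", "PRP"), 0:5)
}

validate_grade <- function(grade) {
  if (!is.numeric(grade) || length(grade) != 1 || is.na(grade) ||
      grade != as.integer(grade) || grade < 0 || grade > 5)
    stop("'grade' must be a single integer in 0..5")
  as.integer(grade)
}

validate_prob <- function(p, tol = 1e-6) {
  if (!is.numeric(p) || anyNA(p))
    stop("probability vector must be numeric without NA")
  if (any(p < -tol))
    stop("probability vector has negative entries")
  if (abs(sum(p) - 1) > tol)
    stop("probability vector must sum to 1 (got ", format(sum(p)), ")")
  invisible(p)
}

# Acquisition geometry: lateral pixels at scale 1, field of view in mm and
# raw (pre-flattening) depth samples.
acq_geometry <- function(acquisition) {
  switch(acquisition,
    hr6 = list(lateral = 500L, fov_mm = 6, raw_depth = 1536L, n_crops = 10L),
    uwf15 = list(lateral = 834L, fov_mm = 15, raw_depth = 3072L, n_crops = 20L),
    stop("unknown acquisition: ", acquisition, " (expected 'hr6' or 'uwf15')"))
}

NOMINAL_DEPTH_TARGET <- 224L
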