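#' Fractional change in LV end-systolic volume index
#'
#' `fc = (post - pre) / pre`; negative values are favorable (reverse
#' remodeling). Responder status uses the conventional -0.15 cutoff,
#' boundary inclusive (`fc <= cutoff`).
#'
#' @param pre,post LVESVI before and after CRT, mL/m2 (vectorized).
#' @param cutoff responder threshold on the fractional change.
#' @return list with numeric `fc` and logical `responder`.
#' @export
lvesvi_fractional_change <- function(pre, post, cutoff = -0.15) {
  if (any(!is.finite(pre)) || any(!is.finite(post)))
    stop("'pre' and 'post' must be finite")
  if (any(pre <= 0)) stop("'pre' LVESVI must be positive")
  fc <- (post - pre) / pre
  list(fc = fc, responder = fc <= cutoff)
}

#' Youden-index optimal cutoff on a grid of multiples of a step
#'
#' Scans candidate cutoffs `c = step, 2*step, ..., max(values)` where a
#' value at or above the cutoff is the favorable test result, computes
#' `J(c) = sensitivity + specificity - 1` against a binary outcome
#' (1 = favorable outcome, e.g. alive at 4 years), and returns the argmax.
#' Ties go to the smallest cutoff. The natural step for activation times
#' is the frame interval of the acquisition (17 ms), making the selected
#' cutoff an exact multiple of the temporal resolution.
#'
#' @param values numeric measurements (e.g. TOS at the LV lead, ms).
#' @param outcome binary vector (0/1) of the same length; both classes
#'   must be present.
#' @param step positive grid step in the units of `values`.
#' @return list with `cutoff`, `J`, and the full scan `grid` (data.frame
#'   of cutoff, sensitivity, specificity, J).
#' @export
youden_optimal_cutoff <- function(values, outcome, step = 17) {
  if (length(values) != length(outcome))
    stop("'values' and 'outcome' must have equal length")
  if (step <= 0) stop("'step' must be positive")
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2)
    stop("both outcome classes must be present to define a cutoff")
  if (length(unique(values)) < 2)
    stop("all measurements identical: cutoff undefined")
  grid <- seq(step, max(values), by = step)
  if (length(grid) == 0)
    stop("no grid point at or below max(values); decrease 'step'")
  pos <- outcome == 1
  scan <- vapply(grid, function(cc) {
    pred <- values >= cc
    sens <- mean(pred[pos])
    spec <- mean(!pred[!pos])
    c(sens, spec, sens + spec - 1)
  }, numeric(3))
  j <- scan[3, ]
  i <- which.max(j)  # which.max returns the first (smallest cutoff) on ties
  list(cutoff = grid[i], J = j[i],
       grid = data.frame(cutoff = grid, sensitivity = scan[1, ],
                         specificity = scan[2, ], J = j))
}
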