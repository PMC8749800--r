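#' Build a triangle-thresholding query
#'
#' The triangle thresholding algorithm (TTA) localises a gradient turning
#' point (GTP) — a sample where a curve's slope changes abruptly — as the
#' point of the curve farthest from the chord joining two reference points.
#' A query holds the two reference points `P_A = (t1, u1)` and
#' `P_B = (t2, u2)` and the sampled curve segment `Q` covering every sample in
#' the closed interval between them. Reference points may be given in either
#' temporal order; the segment is always stored ordered by time.
#'
#' @param time,value The sampled curve: times in ms and values; must cover the
#'   closed interval between `t1` and `t2`.
#' @param t1,t2 Times (ms) of the two reference points; must differ and lie on
#'   the sample grid of `time`.
#' @param u1,u2 Values at the reference points; default to the curve values at
#'   `t1` and `t2`.
#' @return An object of class `tta_query`.
#' @export
tta_query <- function(time, value, t1, t2, u1 = NULL, u2 = NULL) {
  stopifnot(length(time) == length(value))
  if (t1 == t2) stop("t1 and t2 must differ (the chord is undefined)")
  lo <- min(t1, t2); hi <- max(t1, t2)
  keep <- time >= lo & time <= hi
  if (sum(keep) < 3L) stop("segment between t1 and t2 has fewer than 3 samples")
  at <- function(tt) {
    i <- which.min(abs(time - tt))
    value[i]
  }
  structure(list(t1 = t1, u1 = u1 %||% at(t1),
                 t2 = t2, u2 = u2 %||% at(t2),
                 t = time[keep], q = value[keep]),
            class = "tta_query")
}

#' Locate a gradient turning point by triangle thresholding
#'
#' Constructs the chord `U(T)` through the reference points, computes the
#' perpendicular distance `D(T)` from every sample of the segment `Q` to the
#' chord, and returns the time of the maximal distance. Ties are broken by the
#' earliest time. The result is invariant under a common positive rescaling of
#' the curve and reference values.
#'
#' @param query A [tta_query()].
#' @return A list of class `tta_result`: `T_GTP` (ms), `D_max`, and the full
#'   distance profile `D` with its times `t`.
#' @export
tta_gtp <- function(query) {
  stopifnot(inherits(query, "tta_query"))
  slope <- (query$u2 - query$u1) / (query$t2 - query$t1)
  u_line <- slope * (query$t - query$t1) + query$u1
  d <- abs(u_line - query$q) / sqrt(1 + slope^2)
  i <- which.max(d)  # which.max returns the first maximum: earliest-time tie rule
  structure(list(T_GTP = query$t[i], D_max = d[i], D = d, t = query$t),
            class = "tta_result")
}

#' @export
print.tta_result <- function(x, ...) {
  cat(sprintf("<tta_result> T_GTP = %g ms (D_max = %.4g over %d samples)\n",
              x$T_GTP, x$D_max, length(x$D)))
  invisible(x)
}
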