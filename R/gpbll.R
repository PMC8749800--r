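#' Event times relative to the stride's reference heel strike
#'
#' Expresses the opposite-heel-strike and opposite-toe-off timestamps of a
#' stride relative to a reference heel-strike time, the form in which the two
#' measurement systems are compared. On healthy gait OHS falls roughly 550 ms
#' and OTO roughly 120 ms after heel strike.
#'
#' @param events One stride's events: a list or one-row data frame with
#'   `T_OHS` and `T_OTO` (ms; may be `NA`).
#' @param T_HS_ref Reference heel-strike time in ms.
#' @return A list with `T_OHS_0` and `T_OTO_0` (ms; `NA` when the event is
#'   absent).
#' @export
relative_times <- function(events, T_HS_ref) {
  get <- function(name) {
    v <- events[[name]]
    if (is.null(v) || !length(v)) NA_real_ else as.numeric(v[1L])
  }
  list(T_OHS_0 = get("T_OHS") - T_HS_ref,
       T_OTO_0 = get("T_OTO") - T_HS_ref)
}

#' Temporal gait parameters of bilateral lower limbs for one stride
#'
#' From one stride's events (and the next stride's heel strike, OHS and OTO)
#' computes the nine bilateral temporal parameters:
#' \itemize{
#'   \item `DST1 = T_OTO - T_HS` (loading response double support),
#'   \item `DST2 = T_TO - T_OHS` (pre-swing double support),
#'   \item `DSTt = DST1 + DST2` (total double support),
#'   \item `T_sta_L = T_OTO' - T_OHS`, `T_str_L = T_OHS' - T_OHS`
#'     (opposite-foot stance and stride, spanning into the next cycle),
#'   \item `T_sta_R = T_TO - T_HS`, `T_str_R = T_HS' - T_HS`
#'     (instrumented-foot stance and stride),
#'   \item `SIS_ta`, `SIS_tr`: signed symmetry indexes
#'     `(L - R) / (0.5 (L + R))` of stance and stride time. Signs are kept so
#'     that both the degree and the direction of asymmetry are expressed;
#'     swapping the limbs negates them.
#' }
#'
#' @param events A list or one-row data frame with `T_HS`, `T_TO`, `T_OHS`,
#'   `T_OTO`, `T_HS_next`, `T_OHS_next`, `T_OTO_next` (ms).
#' @return A one-row data frame of class `gpbll_record`, or `NULL` with a
#'   warning naming the missing event when the record cannot be formed.
#' @export
compute_gpbll <- function(events) {
  need <- c("T_HS", "T_TO", "T_OHS", "T_OTO", "T_HS_next", "T_OHS_next",
            "T_OTO_next")
  vals <- lapply(need, function(nm) {
    v <- events[[nm]]
    if (is.null(v) || !length(v)) NA_real_ else as.numeric(v[1L])
  })
  names(vals) <- need
  miss <- need[vapply(vals, is.na, logical(1))]
  if (length(miss)) {
    warning("record absent: missing event(s) ", paste(miss, collapse = ", "))
    return(NULL)
  }
  dst1 <- vals$T_OTO - vals$T_HS
  dst2 <- vals$T_TO - vals$T_OHS
  sta_l <- vals$T_OTO_next - vals$T_OHS
  str_l <- vals$T_OHS_next - vals$T_OHS
  sta_r <- vals$T_TO - vals$T_HS
  str_r <- vals$T_HS_next - vals$T_HS
  out <- data.frame(DST1 = dst1, DST2 = dst2, DSTt = dst1 + dst2,
                    T_str_L = str_l, T_str_R = str_r,
                    T_sta_L = sta_l, T_sta_R = sta_r,
                    SIS_tr = (str_l - str_r) / (0.5 * (str_l + str_r)),
                    SIS_ta = (sta_l - sta_r) / (0.5 * (sta_l + sta_r)))
  class(out) <- c("gpbll_record", "data.frame")
  out
}

#' Gait-parameter table for a whole trial
#'
#' Applies [compute_gpbll()] to every stride of an event table that has a
#' complete set of events (each stride is paired with its successor for the
#' opposite foot's stance and stride times). Strides with missing events are
#' dropped silently; the stride index is kept so runs of consecutive
#' effective strides can be averaged.
#'
#' @param events A `gait_events` table from [detect_all_events()].
#' @return A data frame: `stride_index` plus the nine parameters, one row per
#'   complete stride.
#' @export
compute_gpbll_table <- function(events) {
  rows <- lapply(seq_len(nrow(events)), function(i) {
    rec <- suppressWarnings(compute_gpbll(events[i, ]))
    if (is.null(rec)) return(NULL)
    cbind(stride_index = events$stride_index[i], as.data.frame(rec))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(stride_index = integer(0), DST1 = numeric(0),
                      DST2 = numeric(0), DSTt = numeric(0),
                      T_str_L = numeric(0), T_str_R = numeric(0),
                      T_sta_L = numeric(0), T_sta_R = numeric(0),
                      SIS_tr = numeric(0), SIS_ta = numeric(0))
    return(out)
  }
  do.call(rbind, rows)
}

#' Average gait parameters over runs of consecutive strides
#'
#' Walking roughly 5 m (about five strides) is a common minimal assessment
#' window, so parameters are summarised as the field-wise arithmetic mean over
#' each run of `k` consecutive strides. Runs are non-overlapping by default;
#' set `overlap = TRUE` for a sliding window. Consecutiveness is judged on
#' `stride_index`, so gaps (non-effective or failed strides) break runs.
#'
#' @param records A gait-parameter table ([compute_gpbll_table()]); a
#'   `stride_index` column is used when present, otherwise rows are assumed
#'   consecutive.
#' @param k Number of consecutive strides per average (default 5).
#' @param overlap Use a sliding window instead of non-overlapping runs.
#' @return A data frame with one row per run: `stride_first`, `stride_last`
#'   and the averaged parameters. Empty when fewer than `k` consecutive
#'   records exist.
#' @export
average_records <- function(records, k = 5L, overlap = FALSE) {
  stopifnot(k >= 1L)
  idx <- records$stride_index %||% seq_len(nrow(records))
  params <- setdiff(names(records), "stride_index")
  out <- list()
  n <- nrow(records)
  i <- 1L
  while (i + k - 1L <= n) {
    span <- i:(i + k - 1L)
    if (idx[span[k]] - idx[span[1L]] == k - 1L) {
      means <- as.data.frame(lapply(records[span, params, drop = FALSE], mean))
      out[[length(out) + 1L]] <-
        cbind(data.frame(stride_first = idx[span[1L]],
                         stride_last = idx[span[k]]), means)
      i <- i + if (overlap) 1L else k
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(cbind(data.frame(stride_first = integer(0), stride_last = integer(0)),
                 stats::setNames(as.data.frame(matrix(numeric(0), 0, length(params))),
                                 params)))
  }
  do.call(rbind, out)
}
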