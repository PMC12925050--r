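# Online rejection of gross 2D segmentation outliers by superior-inferior
# deviation from an iteratively updated mean, supporting real-time use:
# segmentations are processed in projection order and only accepted ones
# update the running mean.

#' Streaming SI outlier-filter state
#'
#' State of the online filter: running mean of the accepted superior-inferior
#' (row) pixel values, the acceptance count, the rejection threshold
#' (default 25 pixels, i.e. 20 mm at the default 0.8 mm pixel spacing) and a
#' warm-up count during which segmentations are accepted unconditionally
#' while the mean initializes.
#'
#' @param threshold_px Rejection threshold in pixels.
#' @param warmup Number of initial segmentations accepted unconditionally.
#' @return An object of class `si_filter_state`.
#' @export
si_filter_state <- function(threshold_px = 25, warmup = 10) {
  stopifnot(threshold_px > 0, warmup >= 0)
  structure(
    list(sum_si = 0, n_accepted = 0L, threshold_px = threshold_px,
         warmup = warmup),
    class = "si_filter_state"
  )
}

#' @export
print.si_filter_state <- function(x, ...) {
  m <- if (x$n_accepted > 0) sprintf("%.2f", x$sum_si / x$n_accepted) else "undefined"
  cat(sprintf("<si_filter_state> mean SI %s px over %d accepted (threshold %g px)\n",
              m, x$n_accepted, x$threshold_px))
  invisible(x)
}

#' Process one segmentation through the online SI filter
#'
#' During warm-up (fewer than `warmup` accepted so far) the segmentation is
#' accepted and the running mean updated. Afterwards it is accepted iff its
#' SI (row) pixel value deviates from the running mean by at most the
#' threshold; only accepted values update the mean.
#'
#' @param state A [si_filter_state()].
#' @param row_px SI (row) pixel value of the incoming segmentation.
#' @return A list with `accepted` (logical) and `state` (updated).
#' @export
update_and_filter <- function(state, row_px) {
  stopifnot(inherits(state, "si_filter_state"), is.finite(row_px))
  accepted <- if (state$n_accepted < state$warmup) {
    TRUE
  } else {
    abs(row_px - state$sum_si / state$n_accepted) <= state$threshold_px
  }
  if (accepted) {
    state$sum_si <- state$sum_si + row_px
    state$n_accepted <- state$n_accepted + 1L
  }
  list(accepted = accepted, state = state)
}

#' Filter a scan's segmentations
#'
#' Sequential replay of [update_and_filter()] over the segmentations in
#' projection order. Rejected rows are flagged, never altered, and do not
#' influence the running mean.
#'
#' @param segs Segmentations tibble from [segment_scan()] (needs `row_px`;
#'   rows must be in projection order).
#' @param threshold_px,warmup See [si_filter_state()].
#' @return The input tibble with its `accepted` column set; the rejection
#'   rate (rejected / total) is attached as attribute `rejection_rate` and
#'   readable with [rejection_rate()].
#' @export
filter_scan <- function(segs, threshold_px = 25, warmup = 10) {
  if (!is.data.frame(segs) || nrow(segs) == 0) {
    abort("`segs` must be a non-empty segmentations data frame.")
  }
  if (!"row_px" %in% names(segs)) abort("`segs` needs a `row_px` column.")
  state <- si_filter_state(threshold_px, warmup)
  acc <- logical(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    step <- update_and_filter(state, segs$row_px[i])
    acc[i] <- step$accepted
    state <- step$state
  }
  segs$accepted <- acc
  attr(segs, "rejection_rate") <- mean(!acc)
  segs
}

#' @rdname filter_scan
#' @export
rejection_rate <- function(segs) {
  r <- attr(segs, "rejection_rate")
  if (is.null(r)) {
    if (!"accepted" %in% names(segs) || anyNA(segs$accepted)) {
      abort("segmentations have not been filtered yet.")
    }
    r <- mean(!segs$accepted)
  }
  r
}
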