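# False detection events ratio (FDER): the detector's event-level error
# rate against a ground-truth annotation,
#   FDER = (N_FP + N_FN) / N_all,
# where N_all is the number of events the detector reported.

#' False detection events ratio
#'
#' Matches detected events to ground-truth events greedily and
#' one-to-one: detected events are scanned in start order and each takes
#' the nearest unmatched truth event whose midpoint lies within `tol`
#' samples of its own midpoint. Unmatched detected events are false
#' positives (they contain no tapping activity); unmatched truth events
#' are false negatives (taps the detector missed). The ratio can exceed
#' 1 when misses dominate and few events were detected.
#'
#' @param detected,truth [event_table()]s.
#' @param tol Midpoint matching tolerance in samples (default 400, i.e.
#'   400 ms at 1 kHz).
#' @return List with `fder` (NA with a `note` when nothing was detected
#'   but truth events exist), `n_fp`, `n_fn`, `n_all`, and `matches`
#'   (data.frame of matched detected/truth row indices).
#' @export
#' @examples
#' truth <- event_table(c(100, 900), c(500, 1300), c("thumb", "index"))
#' compute_fder(truth, truth, tol = 100)$fder  # 0
compute_fder <- function(detected, truth, tol = 400L) {
  if (tol < 0) stop_("`tol` must be >= 0")
  n_all <- nrow(detected)
  mid_d <- (detected$start_sample + detected$end_sample) / 2
  mid_t <- (truth$start_sample + truth$end_sample) / 2
  used <- rep(FALSE, length(mid_t))
  m_d <- integer(); m_t <- integer()
  for (i in seq_along(mid_d)) {
    cand <- which(!used & abs(mid_t - mid_d[i]) <= tol)
    if (length(cand) > 0) {
      j <- cand[which.min(abs(mid_t[cand] - mid_d[i]))]
      used[j] <- TRUE
      m_d <- c(m_d, i); m_t <- c(m_t, j)
    }
  }
  n_fp <- n_all - length(m_d)
  n_fn <- length(mid_t) - length(m_t)
  out <- list(n_fp = n_fp, n_fn = n_fn, n_all = n_all,
              matches = data.frame(detected = m_d, truth = m_t))
  if (n_all == 0 && length(mid_t) > 0) {
    out$fder <- NA_real_
    out$note <- sprintf("no events detected; %d truth events missed", n_fn)
  } else if (n_all == 0) {
    out$fder <- 0
  } else {
    out$fder <- (n_fp + n_fn) / n_all
  }
  out
}
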