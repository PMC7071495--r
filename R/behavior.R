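#' Signal-detection metrics for a go/no-go block
#'
#' Equal-variance Gaussian model: \eqn{d' = \Phi^{-1}(hit) - \Phi^{-1}(fa)},
#' \eqn{c = -(\Phi^{-1}(hit) + \Phi^{-1}(fa))/2}.  Extreme rates (exactly 0
#' or 1) are replaced by the 1/(2N) correction when the corresponding trial
#' count is supplied; without a count they raise an error instructing the
#' caller to supply one.
#'
#' @param hit hit proportion in [0, 1].
#' @param fa false-alarm proportion in [0, 1].
#' @param n_target,n_distractor trial counts, needed only for extreme rates.
#' @return named list: \code{d_prime}, \code{c}.
#' @examples
#' sdt_metrics(0.775, 0.0607)  # d' ~ 2.30, c ~ 0.40
#' @export
sdt_metrics <- function(hit, fa, n_target = NULL, n_distractor = NULL) {
  if (hit < 0 || hit > 1 || fa < 0 || fa > 1) {
    stop("hit and false-alarm rates must lie in [0, 1]")
  }
  fix <- function(rate, n, what) {
    if (rate > 0 && rate < 1) return(rate)
    if (is.null(n)) {
      stop(what, " rate of ", rate, " is extreme; supply the trial count ",
           "so the 1/(2N) correction can be applied")
    }
    min(max(rate, 1 / (2 * n)), 1 - 1 / (2 * n))
  }
  hit <- fix(hit, n_target, "hit")
  fa <- fix(fa, n_distractor, "false-alarm")
  zh <- stats::qnorm(hit); zf <- stats::qnorm(fa)
  list(d_prime = zh - zf, c = -(zh + zf) / 2)
}

#' Response window bounding motor confounds
#'
#' The interval mean +/- 2 standard deviations of the response-time
#' distribution; ERP effects outside it are unconfounded by manual response.
#'
#' @param mean_rt grand mean RT, ms.
#' @param sd_rt RT standard deviation, ms (>= 0).
#' @return numeric c(low, high), ms.
#' @examples
#' response_window(685, 130)  # 425..945 ms
#' @export
response_window <- function(mean_rt, sd_rt) {
  if (sd_rt < 0) stop("sd_rt must be >= 0")
  c(low = mean_rt - 2 * sd_rt, high = mean_rt + 2 * sd_rt)
}

#' Accuracy summary across subjects
#'
#' Per-subject percent correct, averaged; the standard error is
#' sd/sqrt(n_subjects) across subjects.
#'
#' @param records data.frame with columns \code{subject} and \code{correct}
#'   (logical); one row per trial.
#' @return named list: \code{mean_pct}, \code{se_pct}, \code{n_subjects}.
#' @export
accuracy_summary <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no behavior records")
  if (!all(c("subject", "correct") %in% names(records))) {
    stop("records need columns 'subject' and 'correct'")
  }
  per <- tapply(records$correct, records$subject, function(x) 100 * mean(x))
  n <- length(per)
  se <- if (n > 1) stats::sd(per) / sqrt(n) else 0
  list(mean_pct = mean(per), se_pct = se, n_subjects = n)
}

#' Full behavioral summary for one or more subjects
#'
#' Aggregates accuracy, hit/false-alarm proportions, d' and criterion,
#' response-time statistics and the +/- 2 SD response window from a trial-level
#' behavior table.
#'
#' @param records data.frame with columns subject, stimulus, responded,
#'   rt_ms, correct.
#' @return one-row data.frame of class \code{"behavior_summary"}.
#' @export
behavior_summary <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no behavior records")
  if (!"subject" %in% names(records)) records$subject <- "S01"
  acc <- accuracy_summary(records)
  is_t <- records$stimulus == "target"
  hit <- mean(records$responded[is_t])
  fa <- mean(records$responded[!is_t])
  sdt <- sdt_metrics(hit, fa, n_target = sum(is_t), n_distractor = sum(!is_t))
  rts <- records$rt_ms[records$responded & is_t & !is.na(records$rt_ms)]
  mean_rt <- if (length(rts)) mean(rts) else NA_real_
  sd_rt <- if (length(rts) > 1) stats::sd(rts) else 0
  se_rt <- if (length(rts) > 1) sd_rt / sqrt(length(rts)) else NA_real_
  win <- if (is.na(mean_rt)) c(NA_real_, NA_real_) else response_window(mean_rt, sd_rt)
  out <- data.frame(accuracy_pct = acc$mean_pct, accuracy_se_pct = acc$se_pct,
                    hit_rate = hit, fa_rate = fa, d_prime = sdt$d_prime,
                    criterion = sdt$c, mean_rt_ms = mean_rt, se_rt_ms = se_rt,
                    sd_rt_ms = sd_rt, window_low_ms = win[1],
                    window_high_ms = win[2])
  class(out) <- c("behavior_summary", "data.frame")
  out
}
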