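#' Omnibus split-plot ANOVA on a vincentized bin table
#'
#' Classical sums-of-squares decomposition, computed from first principles,
#' for the stated mixed design: the observational unit is the subject-by-bin
#' "case", interval bin (12 levels) is a between-case factor, electrode (12)
#' and condition (2) are within-case factors.  Each within effect is tested
#' against its own case-interaction error stratum; the error term for the
#' electrode x condition interaction (the focused-contrast MSE) is exposed
#' via [mse_within()].  The design must be balanced: exactly one value per
#' (subject, bin, electrode, condition).
#'
#' Note: the degrees of freedom follow from the data shape; they do not (and
#' cannot) reproduce error df printed for raw-EEG-scale analyses.
#'
#' @param bins a \code{bin_table} (long: subject, condition, electrode, bin,
#'   value) from [vincentize_epochs()], or any data.frame with those columns.
#' @return data.frame of class \code{"anova_result"}: effect, ss, df, ms, f,
#'   p, partial_eta2, error_term.
#' @export
omnibus_anova <- function(bins) {
  need <- c("subject", "condition", "electrode", "bin", "value")
  miss <- setdiff(need, names(bins))
  if (length(miss)) stop("bin table missing column(s): ", paste(miss, collapse = ", "))
  S <- factor(bins$subject); B <- factor(bins$bin)
  E <- factor(bins$electrode); C <- factor(bins$condition)
  y <- bins$value
  nS <- nlevels(S); nB <- nlevels(B); nE <- nlevels(E); nC <- nlevels(C)
  counts <- table(S, B, E, C)
  if (any(counts != 1)) {
    stop("unbalanced design: need exactly one value per ",
         "subject x bin x electrode x condition cell")
  }
  M <- mean(y)
  ss <- function(dev, reps) reps * sum(dev^2)
  # cell-mean arrays; index order matches the list() order
  A_b <- tapply(y, list(B), mean)
  A_e <- tapply(y, list(E), mean)
  A_c <- tapply(y, list(C), mean)
  A_sb <- tapply(y, list(S, B), mean)
  A_eb <- tapply(y, list(E, B), mean)
  A_cb <- tapply(y, list(C, B), mean)
  A_ec <- tapply(y, list(E, C), mean)
  A_esb <- tapply(y, list(E, S, B), mean)
  A_csb <- tapply(y, list(C, S, B), mean)
  A_ecb <- tapply(y, list(E, C, B), mean)
  expand <- function(v, dims, margin) {
    # broadcast array v (over `margin` of dims) to the full dims
    aperm(array(v, c(dims[margin], dims[-margin])),
          order(c(margin, seq_along(dims)[-margin])))
  }
  ss_b <- ss(A_b - M, nS * nE * nC)
  ss_case <- ss(sweep(A_sb, 2, A_b), nE * nC)
  ss_e <- ss(A_e - M, nS * nB * nC)
  ss_c <- ss(A_c - M, nS * nB * nE)
  ss_eb <- ss(sweep(sweep(A_eb, 1, A_e), 2, A_b) + M, nS * nC)
  ss_cb <- ss(sweep(sweep(A_cb, 1, A_c), 2, A_b) + M, nS * nE)
  ss_ec <- ss(sweep(sweep(A_ec, 1, A_e), 2, A_c) + M, nS * nB)
  d_esb <- c(nE, nS, nB)
  dev_es <- A_esb - expand(A_sb, d_esb, c(2, 3)) -
    expand(A_eb, d_esb, c(1, 3)) + expand(A_b, d_esb, 3)
  ss_es <- ss(dev_es, nC)
  d_csb <- c(nC, nS, nB)
  dev_cs <- A_csb - expand(A_sb, d_csb, c(2, 3)) -
    expand(A_cb, d_csb, c(1, 3)) + expand(A_b, d_csb, 3)
  ss_cs <- ss(dev_cs, nE)
  d_ecb <- c(nE, nC, nB)
  dev_ecb <- A_ecb - expand(A_eb, d_ecb, c(1, 3)) -
    expand(A_cb, d_ecb, c(2, 3)) - expand(A_ec, d_ecb, c(1, 2)) +
    expand(A_e, d_ecb, 1) + expand(A_c, d_ecb, 2) + expand(A_b, d_ecb, 3) - M
  ss_ecb <- ss(dev_ecb, nS)
  ss_tot <- sum((y - M)^2)
  ss_ecs <- ss_tot - (ss_b + ss_case + ss_e + ss_eb + ss_es +
                        ss_c + ss_cb + ss_cs + ss_ec + ss_ecb)
  ss_ecs <- max(ss_ecs, 0)

  df_case <- nB * (nS - 1)
  eff <- data.frame(
    effect = c("bin", "case(bin)",
               "electrode", "electrode:bin", "electrode:case(bin)",
               "condition", "condition:bin", "condition:case(bin)",
               "electrode:condition", "electrode:condition:bin",
               "electrode:condition:case(bin)"),
    ss = c(ss_b, ss_case, ss_e, ss_eb, ss_es, ss_c, ss_cb, ss_cs,
           ss_ec, ss_ecb, ss_ecs),
    df = c(nB - 1, df_case,
           nE - 1, (nE - 1) * (nB - 1), (nE - 1) * df_case,
           nC - 1, (nC - 1) * (nB - 1), (nC - 1) * df_case,
           (nE - 1) * (nC - 1), (nE - 1) * (nC - 1) * (nB - 1),
           (nE - 1) * (nC - 1) * df_case),
    error_term = c("case(bin)", "", "electrode:case(bin)",
                   "electrode:case(bin)", "", "condition:case(bin)",
                   "condition:case(bin)", "", "electrode:condition:case(bin)",
                   "electrode:condition:case(bin)", ""),
    stringsAsFactors = FALSE
  )
  eff$ms <- ifelse(eff$df > 0, eff$ss / eff$df, NA_real_)
  err_ms <- eff$ms[match(eff$error_term, eff$effect)]
  eff$f <- ifelse(!is.na(err_ms) & err_ms > 0, eff$ms / err_ms, NA_real_)
  err_df <- eff$df[match(eff$error_term, eff$effect)]
  eff$p <- ifelse(is.na(eff$f), NA_real_,
                  stats::pf(eff$f, eff$df, err_df, lower.tail = FALSE))
  err_ss <- eff$ss[match(eff$error_term, eff$effect)]
  eff$partial_eta2 <- ifelse(is.na(err_ss) | (eff$ss + err_ss) == 0, NA_real_,
                             eff$ss / (eff$ss + err_ss))
  class(eff) <- c("anova_result", "data.frame")
  eff
}

#' Error mean square for the electrode x condition interaction
#'
#' The within-case error term used by the focused contrasts (Eq. 3 threshold).
#' @param result an \code{anova_result} from [omnibus_anova()].
#' @return numeric MSE (0 when the stratum has zero variance).
#' @export
mse_within <- function(result) {
  ms <- result$ms[result$effect == "electrode:condition:case(bin)"]
  if (!length(ms)) stop("not an anova_result from omnibus_anova()")
  if (is.na(ms)) 0 else ms
}

#' Bonferroni-corrected two-tailed t critical value
#'
#' Student-t quantile at family-wise two-tailed level \code{p} divided by the
#' number of comparisons \code{m}.
#'
#' @param p two-tailed family alpha (default 0.05).
#' @param m family size (default 12 electrodes); \code{m = 1} evaluates
#'   \code{p} as an already-corrected level.
#' @param df degrees of freedom (>= 1).
#' @return positive t value.
#' @examples
#' bonferroni_tcrit(1e-4, m = 1, df = 12)  # ~ 5.69
#' @export
bonferroni_tcrit <- function(p = 0.05, m = 12, df) {
  if (missing(df) || !is.finite(df) || df < 1) stop("df must be >= 1")
  stopifnot(m >= 1, p > 0, p < 1)
  stats::qt(1 - (p / m) / 2, df)
}

#' Minimum significant amplitude difference (focused contrast threshold)
#'
#' \eqn{t_{crit} \sqrt{MSE \sum_j \lambda_j^2 / n_j}}: the smallest absolute
#' target minus distractor cell difference that reaches significance under
#' the focused t-contrast with the omnibus within-error.
#'
#' @param t_crit critical t value (see [bonferroni_tcrit()]).
#' @param mse_within error mean square for the electrode x condition
#'   interaction (>= 0).
#' @param lambda contrast weights, must sum to 0 (default c(1, -1)).
#' @param n per-condition cell sizes (default 13 subjects each; recycled).
#' @return threshold in uV.
#' @examples
#' min_sig_diff(5.69, 0.132)  # ~ 0.81 uV
#' @export
min_sig_diff <- function(t_crit, mse_within, lambda = c(1, -1),
                         n = c(13, 13)) {
  if (mse_within < 0) stop("mse_within must be >= 0")
  n <- rep_len(n, length(lambda))
  if (any(n < 1)) stop("cell sizes must be >= 1")
  if (abs(sum(lambda)) > 1e-9) stop("contrast weights must sum to 0")
  t_crit * sqrt(mse_within * sum(lambda^2 / n))
}

# core classification rule: T iff the signed difference has the polarity of
# the dominant peak (so a more-negative target at a negative-going peak is a
# target advantage), D otherwise
classify_diffs <- function(diffs, threshold, polarity) {
  if (threshold < 0) stop("threshold must be >= 0")
  sig <- abs(diffs$diff_uv) >= threshold
  flag <- rep("", nrow(diffs))
  if (any(sig)) {
    pol <- polarity[sig]
    if (anyNA(pol)) {
      bad <- which(sig)[is.na(pol)]
      stop("missing polarity for significant cell(s): ",
           paste(diffs$electrode[bad], "bin", diffs$bin[bad], collapse = "; "))
    }
    flag[sig] <- ifelse(sign(diffs$diff_uv[sig]) == sign(pol), "T", "D")
  }
  out <- diffs
  out$significant <- sig
  out$flag <- flag
  class(out) <- c("significance_table", "data.frame")
  out
}

#' Classify target/distractor advantage cells
#'
#' Applies the minimum-significant-difference threshold to per-cell signed
#' target minus distractor differences within the pre-response analysis
#' window (default 0-700 ms, seven bins) and assigns the advantage to the
#' condition with the larger absolute peak amplitude, using per-cell polarity
#' metadata (sign of the dominant peak) to interpret signed differences at
#' negative-going peaks.
#'
#' @param bins either a \code{bin_table} (per-subject values; differences are
#'   computed and the window applied, with bins re-indexed 1..K inside it) or
#'   a data.frame already holding columns electrode, bin, diff_uv.
#' @param threshold non-negative uV threshold from [min_sig_diff()].
#' @param polarity dominant-peak signs: a data.frame (electrode, bin,
#'   polarity), a single number recycled to all cells, or NULL to use a
#'   \code{polarity} column of \code{bins}.  Missing polarity at a
#'   significant cell is an error.
#' @param window analysis window c(low, high) ms applied when \code{bins} is
#'   a \code{bin_table}.
#' @return data.frame of class \code{"significance_table"}: electrode, bin,
#'   bin_start_ms, bin_end_ms, diff_uv, significant, flag ("T"/"D"/"").
#' @export
classify_cells <- function(bins, threshold, polarity = NULL,
                           window = c(0, 700)) {
  if (inherits(bins, "bin_table") ||
      all(c("subject", "value", "condition") %in% names(bins))) {
    d <- bin_differences(bins)
    keep <- d$bin_start_ms >= window[1] & d$bin_end_ms <= window[2]
    d <- d[keep, , drop = FALSE]
    relabel <- sort(unique(d$bin))
    d$bin <- match(d$bin, relabel)
  } else {
    d <- as.data.frame(bins)
    if (!all(c("electrode", "bin", "diff_uv") %in% names(d))) {
      stop("need electrode, bin and diff_uv columns")
    }
  }
  pol <- if (is.null(polarity)) {
    if (!"polarity" %in% names(d)) stop("no polarity metadata supplied")
    d$polarity
  } else if (is.data.frame(polarity)) {
    polarity$polarity[match(paste(d$electrode, d$bin),
                            paste(polarity$electrode, polarity$bin))]
  } else {
    rep_len(polarity, nrow(d))
  }
  classify_diffs(d, threshold, pol)
}

#' Enhancement-proportion chi-square test
#'
#' Compares the proportion of target-advantage cells against the proportion
#' of distractor-advantage cells among \code{n_cells} comparisons, as a 2x2
#' table \{(n_T, n_cells - n_T), (n_D, n_cells - n_D)\} with Yates continuity
#' correction (|ad - bc| - N/2, clamped at 0) by default.
#'
#' @param n_t number of target-advantage significant cells.
#' @param n_d number of distractor-advantage significant cells.
#' @param n_cells total comparisons (e.g. 84 = 12 electrodes x 7 bins).
#' @param correct apply the continuity correction (default TRUE).
#' @return list: \code{chisq} (1 df), \code{p}.
#' @examples
#' enhancement_test(46, 5, 84)  # chi^2 ~ 45.05
#' @export
enhancement_test <- function(n_t, n_d, n_cells, correct = TRUE) {
  stopifnot(n_t >= 0, n_d >= 0, n_t <= n_cells, n_d <= n_cells)
  a <- n_t; b <- n_cells - n_t; c0 <- n_d; d <- n_cells - n_d
  N <- a + b + c0 + d
  if ((a + c0) == 0 || (b + d) == 0 || (a + b) == 0 || (c0 + d) == 0) {
    stop("degenerate 2x2 table: zero margin")
  }
  num <- abs(a * d - b * c0)
  if (correct) num <- max(num - N / 2, 0)
  chisq <- N * num^2 / ((a + b) * (c0 + d) * (a + c0) * (b + d))
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

#' Write a significance table
#' @param sig a \code{significance_table}.
#' @param path file path.
#' @export
write_significance_table <- function(sig, path) {
  data.table::fwrite(as.data.frame(sig), path)
  invisible(path)
}
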