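#' Left-continuous empirical quantile
#'
#' Generalized inverse of the empirical CDF: the smallest sample value v with
#' F(v) >= alpha, i.e. the ceiling(alpha * n)-th order statistic.
#'
#' @param values numeric sample (any order).
#' @param alpha probability in (0, 1); vectorised.
#' @return quantile value(s).
#' @examples
#' empirical_quantile(c(1, 2, 3, 4), 0.5)  # 2
#' @export
empirical_quantile <- function(values, alpha) {
  if (length(values) == 0) stop("empty sample")
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie strictly in (0, 1)")
  s <- sort(values)
  s[ceiling(alpha * length(s))]
}

#' Mid-point quantile function of a sample
#'
#' Evaluates the empirical quantile at the q equal-probability bin mid-points
#' alpha_j = (j - 1/2)/q.  With q equal to the sample size this is exactly
#' the sorted sample, which keeps data density equal across bins.
#'
#' @param values numeric sample.
#' @param q number of probability bins (default: sample size).
#' @return data.frame of class \code{"quantile_function"}: alpha, value
#'   (non-decreasing in alpha).
#' @export
quantile_midpoints <- function(values, q = length(values)) {
  if (length(values) == 0) stop("empty sample")
  stopifnot(q >= 1)
  alpha <- (seq_len(q) - 0.5) / q
  out <- data.frame(alpha = alpha, value = empirical_quantile(values, alpha))
  class(out) <- c("quantile_function", "data.frame")
  out
}

#' Vincent average of quantile functions
#'
#' Pointwise weighted average of quantile functions evaluated on a shared
#' alpha grid; weights must be non-negative and sum to 1 (within 1e-9).
#' Equal weights (the default) give the arithmetic mean of quantiles, which
#' preserves distribution shape within location-scale families.
#'
#' @param fns list of \code{quantile_function}s on identical alpha grids.
#' @param weights numeric weights, one per function; default equal.
#' @return a \code{quantile_function} on the shared grid.
#' @export
vincent_average <- function(fns, weights = NULL) {
  n <- length(fns)
  if (n == 0) stop("no quantile functions supplied")
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("one weight per quantile function required")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1")
  }
  grid <- fns[[1]]$alpha
  for (f in fns) {
    if (length(f$alpha) != length(grid) || any(abs(f$alpha - grid) > 1e-12)) {
      stop("quantile functions must share one alpha grid")
    }
  }
  v <- rowSums(mapply(function(f, w) w * f$value, fns, weights))
  out <- data.frame(alpha = grid, value = v)
  class(out) <- c("quantile_function", "data.frame")
  out
}

bin_edges <- function(epoch_ms, n_bins) {
  seq(epoch_ms[1], epoch_ms[2], length.out = n_bins + 1)
}

#' Vincentize an epoch set into quantile-bin averages
#'
#' Divides each epoch into \code{n_bins} equal 100 ms intervals (half-open
#' [t, t+width)), sorts the within-bin amplitude samples per subject,
#' condition and electrode, takes the mid-point quantiles, and
#' Vincent-averages across subjects with the given weights.  The per-subject
#' cell value is the mean of that subject's mid-point quantiles; the cell
#' value is the weighted average across subjects.  Distractor binning uses
#' the same bins as target.
#'
#' @param epochs an \code{epoch_set} (validated).
#' @param n_bins number of bins (default 12 over -200..1000 ms).
#' @param weights per-subject Vincent weights; default equal (1/n).
#' @param baseline if TRUE, subtract the pre-stimulus (t < 0) mean per
#'   subject/condition/electrode before binning.  Off by default.
#' @return long data.frame of class \code{"bin_table"}: subject, condition,
#'   electrode, bin, bin_start_ms, bin_end_ms, value; attribute
#'   \code{weights}.
#' @export
vincentize_epochs <- function(epochs, n_bins = 12, weights = NULL,
                              baseline = FALSE) {
  validate_epochs(epochs)
  nS <- length(epochs$subjects)
  if (is.null(weights)) weights <- rep(1 / nS, nS)
  if (length(weights) != nS || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative, one per subject, and sum to 1")
  }
  epoch_ms <- c(epochs$times[1],
                epochs$times[length(epochs$times)] +
                  (epochs$times[2] - epochs$times[1]))
  edges <- bin_edges(epoch_ms, n_bins)
  binof <- findInterval(epochs$times, edges, rightmost.closed = FALSE,
                        left.open = FALSE)
  binof[binof > n_bins] <- n_bins
  amp <- epochs$amplitude
  if (baseline) {
    pre <- epochs$times < 0
    if (any(pre)) {
      bl <- apply(amp[, , , pre, drop = FALSE], 1:3, mean)
      amp <- sweep(amp, 1:3, bl)
    }
  }
  cells <- expand.grid(subject = epochs$subjects,
                       condition = epochs$conditions,
                       electrode = epochs$electrodes,
                       bin = seq_len(n_bins),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  val <- numeric(nrow(cells))
  idx <- 0L
  for (b in seq_len(n_bins)) {
    sel <- binof == b
    # mean of the sorted mid-point quantiles == mean of the within-bin sample
    block <- apply(amp[, , , sel, drop = FALSE], 1:3, function(x) {
      mean(quantile_midpoints(x)$value)
    })
    n_block <- length(block)
    val[idx + seq_len(n_block)] <- as.vector(block)
    idx <- idx + n_block
  }
  cells$bin_start_ms <- edges[cells$bin]
  cells$bin_end_ms <- edges[cells$bin + 1]
  cells$value <- val
  structure(cells, weights = weights, class = c("bin_table", "data.frame"))
}

#' Cell means of a bin table
#'
#' Vincent-weighted average across subjects per (condition, electrode, bin).
#' @param bins a \code{bin_table}.
#' @return data.frame: condition, electrode, bin, bin_start_ms, bin_end_ms,
#'   value.
#' @export
bin_means <- function(bins) {
  subj <- unique(bins$subject)
  w <- attr(bins, "weights")
  if (is.null(w)) w <- rep(1 / length(subj), length(subj))
  wv <- w[match(bins$subject, subj)]
  g <- interaction(bins$condition, bins$electrode, bins$bin, drop = TRUE,
                   lex.order = TRUE)
  num <- rowsum(wv * bins$value, g)
  den <- rowsum(wv, g)
  first <- !duplicated(g)
  out <- data.frame(condition = bins$condition[first],
                    electrode = bins$electrode[first],
                    bin = bins$bin[first],
                    bin_start_ms = bins$bin_start_ms[first],
                    bin_end_ms = bins$bin_end_ms[first],
                    stringsAsFactors = FALSE)
  out$value <- (num / den)[match(as.character(g[first]), rownames(num)), 1]
  out[order(out$condition, out$electrode, out$bin), ]
}

#' Target minus distractor cell differences
#'
#' @param bins a \code{bin_table}.
#' @return data.frame: electrode, bin, bin_start_ms, bin_end_ms, diff_uv.
#' @export
bin_differences <- function(bins) {
  m <- bin_means(bins)
  t <- m[m$condition == "target", ]
  d <- m[m$condition == "distractor", ]
  key <- function(x) paste(x$electrode, x$bin)
  d <- d[match(key(t), key(d)), ]
  data.frame(electrode = t$electrode, bin = t$bin,
             bin_start_ms = t$bin_start_ms, bin_end_ms = t$bin_end_ms,
             diff_uv = t$value - d$value, stringsAsFactors = FALSE)
}

#' Write / read a bin table
#'
#' Wide delimited text: condition, electrode, bin, bin_start_ms, bin_end_ms,
#' value_uV (the Vincent average), plus one column per subject.
#' @param bins a \code{bin_table}.
#' @param path file path.
#' @rdname bin_table_io
#' @export
write_bin_table <- function(bins, path) {
  d <- data.table::as.data.table(bins)
  wide <- data.table::dcast(d, condition + electrode + bin + bin_start_ms +
                              bin_end_ms ~ subject, value.var = "value")
  mean_tab <- data.table::as.data.table(bin_means(bins))
  data.table::setnames(mean_tab, "value", "value_uV")
  out <- merge(mean_tab, wide,
               by = c("condition", "electrode", "bin", "bin_start_ms",
                      "bin_end_ms"))
  data.table::setorder(out, condition, electrode, bin)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname bin_table_io
#' @export
read_bin_table <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  fixed <- c("condition", "electrode", "bin", "bin_start_ms", "bin_end_ms",
             "value_uV")
  miss <- setdiff(fixed, names(d))
  if (length(miss)) stop("bin table missing column(s): ", paste(miss, collapse = ", "))
  subj <- setdiff(names(d), fixed)
  long <- data.table::melt(data.table::as.data.table(d[, c(fixed[1:5], subj)]),
                           id.vars = fixed[1:5], variable.name = "subject",
                           value.name = "value", variable.factor = FALSE)
  out <- as.data.frame(long[, c("subject", "condition", "electrode", "bin",
                                "bin_start_ms", "bin_end_ms", "value"),
                            with = FALSE])
  structure(out, weights = rep(1 / length(subj), length(subj)),
            class = c("bin_table", "data.frame"))
}
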