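#' z-scores of localization search ranges
#'
#' Standardizes grey-matter search ranges (mm) to mean 0 and unit sample
#' (n - 1) standard deviation.  Fewer than two values, or zero spread, yields
#' an all-zero vector flagged degenerate.
#'
#' @param ranges numeric mm values (non-empty).
#' @return numeric z-scores; attribute \code{degenerate} (logical).
#' @export
z_ranges <- function(ranges) {
  if (length(ranges) == 0) stop("empty range list")
  if (length(ranges) < 2 || stats::sd(ranges) == 0) {
    return(structure(rep(0, length(ranges)), degenerate = TRUE))
  }
  structure((ranges - mean(ranges)) / stats::sd(ranges), degenerate = FALSE)
}

#' Compare localization-range variation between two sources
#'
#' Two-sample comparison of the (standardized) localization ranges of the
#' child data versus the simulated adult data: Welch t by default,
#' Mann-Whitney behind the \code{method} flag.
#'
#' @param child,sim numeric vectors (length >= 2 each).
#' @param alpha decision level (default 0.05).
#' @param method "welch" or "mann-whitney".
#' @return list: statistic, p, significant, method.
#' @export
compare_z_ranges <- function(child, sim, alpha = 0.05,
                             method = c("welch", "mann-whitney")) {
  method <- match.arg(method)
  if (length(child) < 2 || length(sim) < 2) {
    stop("each group needs at least two values")
  }
  if (stats::sd(child) == 0 && stats::sd(sim) == 0) {
    # identical-spread degenerate case: no evidence of difference
    eq <- isTRUE(all.equal(mean(child), mean(sim)))
    return(list(statistic = 0, p = if (eq) 1 else NA_real_,
                significant = FALSE, method = method))
  }
  res <- if (method == "welch") {
    stats::t.test(child, sim, var.equal = FALSE)
  } else {
    stats::wilcox.test(child, sim, exact = FALSE)
  }
  list(statistic = unname(res$statistic), p = res$p.value,
       significant = res$p.value < alpha, method = method)
}

#' Regression fit between an actual and a simulated topographic map
#'
#' Ordinary least squares of the actual per-electrode values on the simulated
#' ones over the shared electrode set; R-squared, slope, intercept, F with
#' (1, n - 2) df and p.  A zero-variance simulated map is an error.
#'
#' @param actual,simulated either numeric vectors on the same electrodes or
#'   single \code{topo_maps} entries (data.frames with electrode, value_uv).
#' @return list of class \code{"topo_fit"}: slope, intercept, r2, f, df1,
#'   df2, p, n.
#' @export
topo_fit <- function(actual, simulated) {
  get_vals <- function(m) {
    if (is.data.frame(m)) {
      stats::setNames(m$value_uv, m$electrode)
    } else m
  }
  a <- get_vals(actual); s <- get_vals(simulated)
  if (!is.null(names(a)) && !is.null(names(s))) {
    if (!setequal(names(a), names(s))) stop("electrode sets differ")
    s <- s[names(a)]
  } else if (length(a) != length(s)) stop("map lengths differ")
  if (stats::sd(s) == 0) stop("zero-variance simulated map")
  n <- length(a)
  # closed-form simple OLS (avoids lm's perfect-fit warnings on exact maps)
  sc <- s - mean(s); ac <- a - mean(a)
  slope <- sum(sc * ac) / sum(sc^2)
  intercept <- mean(a) - slope * mean(s)
  ss_tot <- sum(ac^2)
  ss_res <- sum((ac - slope * sc)^2)
  r2 <- if (ss_tot == 0) NaN else 1 - ss_res / ss_tot
  f <- if (is.nan(r2)) NaN else if (r2 >= 1) Inf else r2 * (n - 2) / (1 - r2)
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 r2 = r2, f = f, df1 = 1, df2 = n - 2, p = p, n = n),
            class = "topo_fit")
}

#' Structural and functional homology report
#'
#' Functional part: per-bin regressions of the actual maps on the matched
#' simulated maps (matched by condition and bin; a mismatch is an error),
#' with min/max R-squared per condition.  Structural part (when localization
#' ranges are given): child and simulated ranges are standardized against
#' their pooled mean and sd (so group differences remain visible) and
#' compared with [compare_z_ranges()].
#'
#' @param actual,simulated lists of map entries (as in \code{topo_maps});
#'   attributes \code{condition} and \code{bin} on each entry identify the
#'   match.
#' @param child_ranges,sim_ranges optional numeric localization ranges, mm.
#' @param alpha level for the structural test.
#' @return list of class \code{"homology_report"}: \code{fits} (data.frame:
#'   condition, bin, slope, intercept, r2, f, p), \code{r2_range} (per
#'   condition min/max), \code{structural} (test result or NULL).
#' @export
homology_report <- function(actual, simulated, child_ranges = NULL,
                            sim_ranges = NULL, alpha = 0.05) {
  key <- function(m) paste(attr(m, "condition"), attr(m, "bin"))
  ka <- vapply(actual, key, ""); ks <- vapply(simulated, key, "")
  if (!setequal(ka, ks) || anyDuplicated(ka) || anyDuplicated(ks)) {
    stop("actual and simulated maps must match one-to-one on condition x bin")
  }
  simulated <- simulated[match(ka, ks)]
  fits <- do.call(rbind, lapply(seq_along(actual), function(i) {
    ft <- topo_fit(actual[[i]], simulated[[i]])
    data.frame(condition = attr(actual[[i]], "condition"),
               bin = attr(actual[[i]], "bin"), slope = ft$slope,
               intercept = ft$intercept, r2 = ft$r2, f = ft$f, p = ft$p,
               stringsAsFactors = FALSE)
  }))
  r2_range <- do.call(rbind, lapply(split(fits, fits$condition), function(d) {
    data.frame(condition = d$condition[1], min_r2 = min(d$r2),
               max_r2 = max(d$r2), stringsAsFactors = FALSE)
  }))
  structural <- NULL
  if (!is.null(child_ranges) && !is.null(sim_ranges)) {
    pooled <- c(child_ranges, sim_ranges)
    ps <- stats::sd(pooled)
    if (is.na(ps) || ps == 0) {
      zc <- rep(0, length(child_ranges)); zs <- rep(0, length(sim_ranges))
    } else {
      zc <- (child_ranges - mean(pooled)) / ps
      zs <- (sim_ranges - mean(pooled)) / ps
    }
    structural <- compare_z_ranges(zc, zs, alpha = alpha)
  }
  structure(list(fits = fits, r2_range = r2_range, structural = structural),
            class = "homology_report")
}

#' @export
print.homology_report <- function(x, ...) {
  cat("Functional homology (per-bin map regressions):\n")
  print(x$fits, row.names = FALSE)
  cat("\nR-squared range per condition:\n")
  print(x$r2_range, row.names = FALSE)
  if (!is.null(x$structural)) {
    cat(sprintf("\nStructural test (%s): statistic %.3f, p = %.4f (%s)\n",
                x$structural$method, x$structural$statistic, x$structural$p,
                if (x$structural$significant) "significant" else
                  "not significant"))
  }
  invisible(x)
}

#' Read a localization-range table
#'
#' Delimited text: label, range_mm, source (child/simulated), condition.
#' @param path file path.
#' @return data.frame.
#' @export
read_ranges <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  need <- c("label", "range_mm", "source", "condition")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("range table missing column(s): ", paste(miss, collapse = ", "))
  bad <- d$range_mm < 1 | d$range_mm > 5
  if (any(bad)) {
    warning("range(s) outside the 1-5 mm search bounds flagged: ",
            paste(d$label[bad], collapse = ", "))
  }
  d
}
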