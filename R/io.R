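#' Read an epoched ERP file
#'
#' Long-format delimited text with header
#' \code{subject,condition,electrode,time_ms,amplitude_uV}.  The grid must be
#' complete (every subject x condition x electrode carries the same time
#' samples, no duplicates) and amplitudes numeric and finite; violations
#' raise specific errors naming the offending cell.
#'
#' @param path file path.
#' @return an \code{epoch_set}.
#' @export
read_epochs <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  need <- c("subject", "condition", "electrode", "time_ms", "amplitude_uV")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("epoch file missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(d$amplitude_uV)) stop("non-numeric amplitude_uV column")
  if (anyNA(d$amplitude_uV) || any(!is.finite(d$amplitude_uV))) {
    stop("missing or non-finite amplitudes in epoch file")
  }
  subjects <- unique(d$subject); conds <- unique(d$condition)
  elecs <- unique(d$electrode); times <- sort(unique(d$time_ms))
  counts <- table(d$subject, d$condition, d$electrode)
  if (any(counts > length(times))) {
    i <- which(counts > length(times), arr.ind = TRUE)[1, ]
    stop("duplicate samples for cell ", dimnames(counts)[[1]][i[1]], "/",
         dimnames(counts)[[2]][i[2]], "/", dimnames(counts)[[3]][i[3]])
  }
  if (any(counts < length(times))) {
    i <- which(counts < length(times), arr.ind = TRUE)[1, ]
    stop("incomplete grid: cell ", dimnames(counts)[[1]][i[1]], "/",
         dimnames(counts)[[2]][i[2]], "/", dimnames(counts)[[3]][i[3]],
         " lacks samples")
  }
  amp <- array(NA_real_, dim = c(length(subjects), length(conds),
                                 length(elecs), length(times)),
               dimnames = list(subjects, conds, elecs, NULL))
  idx <- cbind(match(d$subject, subjects), match(d$condition, conds),
               match(d$electrode, elecs), match(d$time_ms, times))
  amp[idx] <- d$amplitude_uV
  out <- structure(list(amplitude = amp, subjects = subjects,
                        conditions = conds, electrodes = elecs,
                        times = times), class = "epoch_set")
  validate_epochs(out)
  out
}

#' Write an epoched ERP set
#'
#' Long-format delimited text (see [read_epochs()]); round-trips losslessly
#' at full float precision.
#'
#' @param epochs an \code{epoch_set}.
#' @param path file path.
#' @export
write_epochs <- function(epochs, path) {
  validate_epochs(epochs)
  data.table::fwrite(as.data.frame(epochs), path)
  invisible(path)
}
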