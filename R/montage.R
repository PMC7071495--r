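#' Built-in 10-20 electrode position table
#'
#' Unit-sphere scalp coordinates for the extended 10-20 system under a fixed
#' geometric convention: +x toward the right ear, +y toward the nasion, +z up,
#' Cz at the pole.  The circumferential ring (Fp1/2, F7/8, T7/8, P7/8, O1/2,
#' Fpz, Oz) sits at 72 degrees of inclination from the vertex (the 10% line);
#' midline Fz and Pz sit at 36 degrees anterior/posterior (30%/70% of the
#' nasion-inion arc); intermediate electrodes (F3/4, C3/4, P3/4) are the
#' great-circle midpoints of their midline and ring neighbours.  Only relative
#' geometry matters for the forward model, so any fixed convention serves.
#'
#' @return data.frame with columns \code{label}, \code{x}, \code{y}, \code{z};
#'   every row is a unit vector.
#' @export
ten_twenty_table <- function() {
  deg <- pi / 180
  ring <- function(az) {
    # az: azimuth in degrees, clockwise from nasion; negative = left
    c(sin(72 * deg) * sin(az * deg), sin(72 * deg) * cos(az * deg), cos(72 * deg))
  }
  mid <- function(incl_deg, posterior = FALSE) {
    s <- if (posterior) -1 else 1
    c(0, s * sin(incl_deg * deg), cos(incl_deg * deg))
  }
  gc_mid <- function(a, b) {
    v <- a + b
    v / sqrt(sum(v^2))
  }
  pos <- list(
    Cz  = c(0, 0, 1),
    Fz  = mid(36), Pz = mid(36, posterior = TRUE),
    Fpz = ring(0), Fp1 = ring(-18), Fp2 = ring(18),
    F7  = ring(-54), F8 = ring(54),
    T7  = ring(-90), T8 = ring(90),
    P7  = ring(-126), P8 = ring(126),
    O1  = ring(-162), O2 = ring(162), Oz = ring(180)
  )
  pos$F3 <- gc_mid(pos$Fz, pos$F7)
  pos$F4 <- gc_mid(pos$Fz, pos$F8)
  pos$C3 <- gc_mid(pos$Cz, pos$T7)
  pos$C4 <- gc_mid(pos$Cz, pos$T8)
  pos$P3 <- gc_mid(pos$Pz, pos$P7)
  pos$P4 <- gc_mid(pos$Pz, pos$P8)
  m <- do.call(rbind, pos)
  data.frame(label = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' The 12-channel montage used throughout the package
#' @export
MONTAGE_12 <- c("F3", "Fz", "F4", "Cz", "T7", "T8",
                "P7", "Pz", "P8", "O1", "Oz", "O2")

#' Construct an electrode montage
#'
#' Looks up unit-sphere positions for the requested channels in the built-in
#' 10-20 table ([ten_twenty_table()]).  Deterministic; unknown labels raise an
#' error naming the offending label.
#'
#' @param labels character vector of 10-20 channel names (default: the
#'   12-channel montage \code{MONTAGE_12}).
#' @return data.frame of class \code{"montage"} with columns
#'   \code{label}, \code{x}, \code{y}, \code{z}.
#' @examples
#' standard_montage(c("Cz", "Pz"))
#' @export
standard_montage <- function(labels = MONTAGE_12) {
  stopifnot(is.character(labels), length(labels) >= 1)
  if (anyDuplicated(labels)) {
    stop("duplicate electrode label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  tab <- ten_twenty_table()
  miss <- setdiff(labels, tab$label)
  if (length(miss)) {
    stop("unknown electrode label(s): ", paste(miss, collapse = ", "))
  }
  out <- tab[match(labels, tab$label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("montage", "data.frame")
  out
}

montage_matrix <- function(montage) {
  m <- as.matrix(montage[, c("x", "y", "z")])
  rownames(m) <- montage$label
  m
}

#' Read / write a montage file
#'
#' Delimited text with header \code{label,x,y,z}; positions must be unit
#' vectors (|pos| = 1 within 1e-6).
#'
#' @param path file path.
#' @rdname montage_io
#' @export
read_montage <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  need <- c("label", "x", "y", "z")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("montage file missing column(s): ", paste(miss, collapse = ", "))
  r <- sqrt(d$x^2 + d$y^2 + d$z^2)
  if (any(abs(r - 1) > 1e-6)) {
    stop("montage positions not on the unit sphere: ",
         paste(d$label[abs(r - 1) > 1e-6], collapse = ", "))
  }
  if (anyDuplicated(d$label)) stop("duplicate electrode labels in montage file")
  out <- d[, need]
  class(out) <- c("montage", "data.frame")
  out
}

#' @param montage montage data.frame.
#' @rdname montage_io
#' @export
write_montage <- function(montage, path) {
  data.table::fwrite(as.data.frame(montage)[, c("label", "x", "y", "z")], path)
  invisible(path)
}
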