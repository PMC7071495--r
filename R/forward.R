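#' Current-dipole configuration
#'
#' Builds and validates a dipole table for the spherical-head forward model.
#' Each dipole has a position strictly inside the unit sphere, a unit moment
#' direction (default: radial, i.e. along the position vector), a relative
#' strength \code{p}, a triangular spike peak time and width (ms), and the
#' stimulus condition it belongs to.
#'
#' @param label character anatomical tags.
#' @param position n x 3 matrix (|row| < 1).
#' @param moment n x 3 matrix of directions, or NULL for radial moments.
#' @param p relative strengths (>= 0).
#' @param peak_ms spike peak times, ms.
#' @param width_ms spike widths, ms (> 0); default 100 (one bin).
#' @param condition "target" or "distractor" per dipole.
#' @return data.frame of class \code{"dipole_config"} with columns
#'   \code{label,x,y,z,mx,my,mz,p,peak_ms,width_ms,condition}.
#' @export
dipole_config <- function(label, position, moment = NULL, p = 1,
                          peak_ms, width_ms = 100, condition = "target") {
  position <- matrix(as.numeric(position), ncol = 3)
  n <- nrow(position)
  r <- sqrt(rowSums(position^2))
  if (any(r >= 1)) stop("dipole position(s) not strictly inside the unit sphere")
  if (is.null(moment)) {
    moment <- position / ifelse(r > 0, r, 1)
    moment[r == 0, ] <- rep(c(0, 0, 1), each = sum(r == 0))
  } else {
    moment <- matrix(as.numeric(moment), ncol = 3)
    mn <- sqrt(rowSums(moment^2))
    if (any(mn == 0)) stop("zero-length dipole moment")
    moment <- moment / mn
  }
  p <- rep_len(p, n); width_ms <- rep_len(width_ms, n)
  condition <- rep_len(condition, n)
  if (any(p < 0)) stop("dipole strength p must be >= 0")
  if (any(width_ms <= 0)) stop("spike width must be > 0")
  stopifnot(length(label) == n, length(peak_ms) == n,
            all(condition %in% c("target", "distractor")))
  out <- data.frame(label = label, x = position[, 1], y = position[, 2],
                    z = position[, 3], mx = moment[, 1], my = moment[, 2],
                    mz = moment[, 3], p = p, peak_ms = peak_ms,
                    width_ms = width_ms, condition = condition,
                    stringsAsFactors = FALSE)
  class(out) <- c("dipole_config", "data.frame")
  out
}

#' Default dipole configuration for the simulated task
#'
#' Synthetic stand-in coordinates: approximate stereotaxic positions (mm) for
#' the anatomical sources active in the simulated go/no-go task, normalized by
#' a nominal 90 mm head radius.  Target sequence: precuneus 150 ms, left
#' supramarginal gyrus 250 ms, right middle frontal gyrus 350 ms, right insula
#' 450 ms, right medial-dorsal thalamus 550 ms, right caudate body 650 ms.
#' Distractor sequence: right middle temporal gyrus 250 ms, left claustrum
#' 550 ms.  Positions are editable configuration, not computed facts; they are
#' also shipped as the plain-text fixture
#' \code{system.file("extdata", "dipoles_synthetic.csv", package = "erpactr")}.
#'
#' @return a \code{dipole_config} with 8 rows.
#' @export
default_dipoles <- function() {
  mm <- rbind(
    precuneus        = c(0, -60, 45),
    supramarginal_L  = c(-55, -40, 30),
    middle_frontal_R = c(34, 48, 12),
    insula_R         = c(38, 0, 5),
    thalamus_MD_R    = c(4, -15, 8),
    caudate_body_R   = c(14, 2, 16),
    middle_temporal_R = c(50, -60, 5),
    claustrum_L      = c(-32, 2, 2)
  )
  dipole_config(
    label = rownames(mm),
    position = mm / 90,
    p = 1,
    peak_ms = c(150, 250, 350, 450, 550, 650, 250, 550),
    width_ms = 100,
    condition = c(rep("target", 6), rep("distractor", 2))
  )
}

#' Read / write dipole configuration files
#'
#' Delimited text with header
#' \code{label,x,y,z,mx,my,mz,p,peak_ms,width_ms,condition}.
#' @param path file path.
#' @rdname dipole_io
#' @export
read_dipoles <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  need <- c("label", "x", "y", "z", "mx", "my", "mz", "p",
            "peak_ms", "width_ms", "condition")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("dipole file missing column(s): ", paste(miss, collapse = ", "))
  dipole_config(d$label, as.matrix(d[, c("x", "y", "z")]),
                as.matrix(d[, c("mx", "my", "mz")]), d$p, d$peak_ms,
                d$width_ms, d$condition)
}

#' @param dipoles a \code{dipole_config}.
#' @rdname dipole_io
#' @export
write_dipoles <- function(dipoles, path) {
  data.table::fwrite(as.data.frame(dipoles), path)
  invisible(path)
}

#' Scalp potential of a single dipole at a single electrode
#'
#' Quasi-static point-dipole field on a relative scale:
#' \eqn{V = k\,p\,\cos\theta / r^2}, where \eqn{r} is the Euclidean distance
#' from dipole to electrode and \eqn{\theta} the angle between the dipole
#' moment and the dipole-to-electrode direction.  \code{k} is an arbitrary
#' gain (default 1) because only relative magnitudes are used downstream.
#'
#' @param dipole one-row \code{dipole_config} (or list with the same fields).
#' @param electrode one-row montage data.frame (or list with x,y,z).
#' @param k field constant (default 1).
#' @return signed relative voltage (sign follows \eqn{\cos\theta}).
#' @export
dipole_potential <- function(dipole, electrode, k = 1) {
  dp <- c(dipole$x[1], dipole$y[1], dipole$z[1])
  mo <- c(dipole$mx[1], dipole$my[1], dipole$mz[1])
  el <- c(electrode$x[1], electrode$y[1], electrode$z[1])
  d <- el - dp
  r2 <- sum(d^2)
  if (r2 == 0) stop("degenerate geometry: electrode coincides with dipole")
  r <- sqrt(r2)
  k * dipole$p[1] * sum(mo * d) / r / r2
}

# vectorised field of all dipoles at all electrodes: n_elec x n_dip matrix
field_matrix <- function(dipoles, montage, k = 1) {
  E <- montage_matrix(montage)
  D <- as.matrix(dipoles[, c("x", "y", "z")])
  M <- as.matrix(dipoles[, c("mx", "my", "mz")])
  out <- matrix(0, nrow(E), nrow(D), dimnames = list(rownames(E), dipoles$label))
  for (j in seq_len(nrow(D))) {
    diff <- sweep(E, 2, D[j, ])
    r2 <- rowSums(diff^2)
    if (any(r2 == 0)) stop("degenerate geometry: electrode coincides with dipole")
    out[, j] <- k * dipoles$p[j] * (diff %*% M[j, ]) / (r2 * sqrt(r2))
  }
  out
}

#' Triangular spike time course
#'
#' Piecewise-linear rise and fall peaking at \code{peak_time} with value
#' \code{amplitude}; zero for |t - peak_time| >= width/2.
#'
#' @param t time(s), ms (vectorised).
#' @param peak_time spike peak, ms.
#' @param width total support width, ms (> 0).
#' @param amplitude peak value (default 1).
#' @export
triangular_spike <- function(t, peak_time, width, amplitude = 1) {
  if (width <= 0) stop("spike width must be > 0")
  amplitude * pmax(0, 1 - abs(t - peak_time) / (width / 2))
}

#' Project a dipole set onto the scalp over time
#'
#' Superposes per-dipole contributions: entry (e, t) is the sum over dipoles
#' of \code{dipole_potential(d, e)} times a unit-amplitude triangular spike at
#' the dipole's peak time and width.  With the default 100 ms width and the
#' 100 ms production spacing, spike supports of consecutive dipoles touch but
#' do not overlap, so at most one dipole is active at any instant.
#'
#' @param dipoles \code{dipole_config} (may have zero rows).
#' @param montage montage data.frame.
#' @param times sorted numeric time grid, ms.
#' @param k field constant.
#' @return electrode x time matrix (dimnames: labels, times).
#' @export
scalp_projection <- function(dipoles, montage, times, k = 1) {
  stopifnot(!is.unsorted(times))
  out <- matrix(0, nrow(montage), length(times),
                dimnames = list(montage$label, times))
  if (nrow(dipoles) == 0) return(out)
  G <- field_matrix(dipoles, montage, k = k)
  for (j in seq_len(nrow(dipoles))) {
    s <- triangular_spike(times, dipoles$peak_ms[j], dipoles$width_ms[j])
    out <- out + outer(G[, j], s)
  }
  out
}

#' Write a scalp projection matrix
#'
#' Delimited matrix: rows = electrodes (first column \code{electrode}),
#' remaining columns the time samples (header row of times).
#' @param proj matrix from [scalp_projection()].
#' @param path file path.
#' @export
write_projection <- function(proj, path) {
  d <- data.table::data.table(electrode = rownames(proj))
  d <- cbind(d, data.table::as.data.table(proj))
  data.table::fwrite(d, path)
  invisible(path)
}
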