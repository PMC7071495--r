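#' Scalp grid used by the movement constraints
#'
#' Row/column semantics of the 12-channel montage: rows run
#' frontal (1) -> central (2) -> parietal (3) -> occipital (4); columns run
#' left (1) -> midline (2) -> right (3).  "Forward" means decreasing row
#' (toward frontal).
#' @return data.frame: electrode, row, col.
#' @export
electrode_grid <- function() {
  data.frame(
    electrode = c("F3", "Fz", "F4", "T7", "Cz", "T8",
                  "P7", "Pz", "P8", "O1", "Oz", "O2"),
    row = rep(1:4, each = 3),
    col = rep(1:3, times = 4),
    stringsAsFactors = FALSE
  )
}

# is the move a -> b legal under the wiring-minimization constraints?
# occipital-origin moves may only go forward or lateral; frontal-origin only
# backward or lateral; lateral components from a left-column origin must go
# rightward, from a right-column origin leftward; midline lateral moves are
# unrestricted
legal_move <- function(a, b, grid = electrode_grid()) {
  ga <- grid[match(a, grid$electrode), ]
  gb <- grid[match(b, grid$electrode), ]
  if (anyNA(ga$row) || anyNA(gb$row)) stop("electrode not in the 12-channel grid")
  if (ga$row == 4 && gb$row > ga$row) return(FALSE)   # occipital: no backward
  if (ga$row == 1 && gb$row < ga$row) return(FALSE)   # frontal: no forward
  if (gb$col != ga$col) {
    if (ga$col == 1 && gb$col < ga$col) return(FALSE) # left: rightward only
    if (ga$col == 3 && gb$col > ga$col) return(FALSE) # right: leftward only
  }
  TRUE
}

scalp_distance <- function(a, b, montage) {
  pa <- unlist(montage[match(a, montage$label), c("x", "y", "z")])
  pb <- unlist(montage[match(b, montage$label), c("x", "y", "z")])
  sqrt(sum((pa - pb)^2))
}

#' Electrodes of maximum target-distractor difference in a bin
#'
#' Among cells flagged for the requested condition in the given analysis bin,
#' returns the electrodes whose absolute difference lies within
#' \code{tolerance} of the maximum (simultaneous activation), capped at 3,
#' largest first.  Empty when the bin holds no flagged cell.
#'
#' @param sig a \code{significance_table}.
#' @param bin analysis bin index.
#' @param condition "target" or "distractor".
#' @param tolerance non-negative uV simultaneity tolerance.
#' @return character vector (possibly empty) of electrode labels.
#' @export
max_diff_electrodes <- function(sig, bin, condition = c("target", "distractor"),
                                tolerance = 0) {
  condition <- match.arg(condition)
  if (tolerance < 0) stop("tolerance must be >= 0")
  want <- if (condition == "target") "T" else "D"
  cells <- sig[sig$bin == bin & sig$flag == want, , drop = FALSE]
  if (nrow(cells) == 0) return(character(0))
  a <- abs(cells$diff_uv)
  keep <- a >= max(a) - tolerance
  out <- cells$electrode[keep][order(-a[keep])]
  utils::head(out, 3)
}

#' Order simultaneously active electrodes into a least path
#'
#' Exhaustive search over visiting orders of 1-3 electrodes: orderings whose
#' every consecutive move satisfies the movement constraints are kept; among
#' those the minimum total scalp (Euclidean chord) distance wins.  Ties break
#' deterministically: the ordering starting at the most posterior row first,
#' then lexicographic label sequence.  If no ordering is fully legal the
#' distance-minimal ordering is returned annotated \code{legal = FALSE}
#' (never silently dropped).
#'
#' @param electrodes character vector of 1-3 distinct labels.
#' @param montage montage for distances (default [standard_montage()]).
#' @return list: \code{order} (labels), \code{legal} (logical),
#'   \code{distance}.
#' @export
order_simultaneous <- function(electrodes, montage = standard_montage()) {
  electrodes <- unique(electrodes)
  n <- length(electrodes)
  if (n < 1 || n > 3) stop("need 1-3 distinct electrodes")
  if (n == 1) return(list(order = electrodes, legal = TRUE, distance = 0))
  perms <- if (n == 2) list(1:2, 2:1) else {
    list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  }
  grid <- electrode_grid()
  cand <- lapply(perms, function(p) {
    ord <- electrodes[p]
    legal <- all(vapply(seq_len(n - 1), function(i) {
      legal_move(ord[i], ord[i + 1], grid)
    }, logical(1)))
    dist <- sum(vapply(seq_len(n - 1), function(i) {
      scalp_distance(ord[i], ord[i + 1], montage)
    }, numeric(1)))
    list(order = ord, legal = legal, distance = dist)
  })
  pick <- function(cands) {
    d <- vapply(cands, `[[`, numeric(1), "distance")
    cands <- cands[d <= min(d) + 1e-12]
    start_row <- vapply(cands, function(x) {
      grid$row[match(x$order[1], grid$electrode)]
    }, numeric(1))
    cands <- cands[start_row == max(start_row)]  # most posterior start
    key <- vapply(cands, function(x) paste(x$order, collapse = " "), "")
    cands[[order(key)[1]]]
  }
  legal_cand <- Filter(function(x) x$legal, cand)
  if (length(legal_cand)) pick(legal_cand) else pick(cand)
}

#' Build per-condition ERP activity paths
#'
#' For each analysis bin: take the maximum-difference electrode set
#' ([max_diff_electrodes()]), order it under the movement constraints
#' ([order_simultaneous()]), and concatenate over bins.  Between-step
#' transitions (last electrode of one step to first of the next) are
#' annotated with their legality but not filtered.
#'
#' @param sig a \code{significance_table}.
#' @param montage montage (default [standard_montage()]).
#' @param tolerance simultaneity tolerance, uV; the natural default is the
#'   minimum-significant-difference threshold.
#' @param conditions which conditions to build (default both).
#' @return list of class \code{"activity_paths"}: per condition a list with
#'   \code{steps} (bin, electrodes, legal) and \code{edges} (data.frame:
#'   condition, bin, from, to, type within/between, legal).
#' @export
build_paths <- function(sig, montage = standard_montage(), tolerance = 0,
                        conditions = c("target", "distractor")) {
  grid <- electrode_grid()
  out <- list()
  for (cond in conditions) {
    steps <- list()
    edges <- data.frame(condition = character(0), bin = integer(0),
                        from = character(0), to = character(0),
                        type = character(0), legal = logical(0),
                        stringsAsFactors = FALSE)
    prev_last <- NULL; prev_bin <- NA_integer_
    for (b in sort(unique(sig$bin))) {
      els <- max_diff_electrodes(sig, b, cond, tolerance)
      if (!length(els)) next
      o <- order_simultaneous(els, montage)
      steps[[length(steps) + 1]] <- list(bin = b, electrodes = o$order,
                                         legal = o$legal)
      if (!is.null(prev_last)) {
        edges <- rbind(edges, data.frame(
          condition = cond, bin = b, from = prev_last, to = o$order[1],
          type = "between", legal = legal_move(prev_last, o$order[1], grid),
          stringsAsFactors = FALSE))
      }
      if (length(o$order) > 1) {
        for (i in seq_len(length(o$order) - 1)) {
          edges <- rbind(edges, data.frame(
            condition = cond, bin = b, from = o$order[i], to = o$order[i + 1],
            type = "within", legal = legal_move(o$order[i], o$order[i + 1], grid),
            stringsAsFactors = FALSE))
        }
      }
      prev_last <- o$order[length(o$order)]; prev_bin <- b
    }
    out[[cond]] <- list(steps = steps, edges = edges)
  }
  class(out) <- "activity_paths"
  out
}

#' Replay-validate an activity path
#'
#' Re-checks every within-step move of every step against the movement
#' constraints; returns TRUE only if all steps marked legal actually are.
#' @param paths an \code{activity_paths}.
#' @return logical.
#' @export
replay_paths <- function(paths) {
  grid <- electrode_grid()
  for (cond in names(paths)) {
    for (st in paths[[cond]]$steps) {
      e <- st$electrodes
      ok <- length(e) < 2 ||
        all(vapply(seq_len(length(e) - 1), function(i) {
          legal_move(e[i], e[i + 1], grid)
        }, logical(1)))
      if (ok != st$legal) return(FALSE)
    }
  }
  TRUE
}

#' Human-readable narration of activity paths
#' @param paths an \code{activity_paths}.
#' @return character vector, one line per condition.
#' @export
path_narration <- function(paths) {
  vapply(names(paths), function(cond) {
    st <- paths[[cond]]$steps
    if (!length(st)) return(paste0(cond, ": no significant activity"))
    parts <- vapply(st, function(s) {
      sprintf("bin %d (%s)%s", s$bin, paste(s$electrodes, collapse = " -> "),
              if (s$legal) "" else " [constraint-violating]")
    }, "")
    paste0(cond, ": ", paste(parts, collapse = "; "))
  }, "")
}

#' Write the path edge list
#' @param paths an \code{activity_paths}.
#' @param path file path.
#' @export
write_paths <- function(paths, path) {
  edges <- do.call(rbind, lapply(paths, `[[`, "edges"))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(condition = character(0), bin = integer(0),
                        from = character(0), to = character(0),
                        type = character(0), legal = logical(0))
  }
  data.table::fwrite(edges, path)
  invisible(path)
}
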