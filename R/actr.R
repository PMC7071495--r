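#' Default module sequence of the production model
#'
#' Module order and brain regions of the six-production schedule: visual
#' (occipital), spatial attention (parietal), declarative (temporal),
#' executive (frontal), procedural (basal ganglia), manual (parietal).
#' @return data.frame: module, region.
#' @export
default_modules <- function() {
  data.frame(
    module = c("visual", "spatial", "declarative", "executive",
               "procedural", "manual"),
    region = c("occipital", "parietal", "temporal", "frontal",
               "basal_ganglia", "parietal"),
    stringsAsFactors = FALSE
  )
}

#' Build the production schedule
#'
#' Production k completes at k * bin_ms + cycle_ms: the base
#' production-completion constant equals the vincentized bin width (100 ms)
#' plus the 50 ms cognitive-cycle constant, giving 150, 250, ... 650 ms at
#' defaults.
#'
#' @param bin_ms bin width, ms (> 0).
#' @param cycle_ms cognitive-cycle constant, ms (>= 0).
#' @param modules data.frame with columns module, region (default
#'   [default_modules()]); must be non-empty.
#' @return data.frame of class \code{"production_schedule"}: production,
#'   module, region, completion_ms.
#' @export
build_schedule <- function(bin_ms = 100, cycle_ms = 50,
                           modules = default_modules()) {
  if (bin_ms <= 0 || cycle_ms < 0) stop("durations must be positive")
  if (is.null(modules) || nrow(modules) == 0) stop("empty module list")
  k <- seq_len(nrow(modules))
  out <- data.frame(production = paste0("p", k, "_", modules$module),
                    module = modules$module, region = modules$region,
                    completion_ms = k * bin_ms + cycle_ms,
                    stringsAsFactors = FALSE)
  class(out) <- c("production_schedule", "data.frame")
  out
}

#' Activation profile parameters
#'
#' Ex-Gaussian rise (mu, sigma, tau, ms) toward the task level, exponential
#' decay after firing with the given half-life, and a resting level as a
#' fraction of the task level.  Faster productions (shorter inter-firing
#' duration) get proportionally more intense and more quickly decaying
#' spikes: intensity scales as base duration / actual duration and the decay
#' rate scales with intensity.
#'
#' @param rest_level resting activation (fraction of task level).
#' @param task_level activation at firing.
#' @param mu,sigma,tau ex-Gaussian rise parameters, ms.
#' @param decay_half_life_ms post-firing decay half-life, ms.
#' @return list of class \code{"activation_profile"}.
#' @export
activation_profile <- function(rest_level = 0.1, task_level = 1,
                               mu = 30, sigma = 10, tau = 40,
                               decay_half_life_ms = 50) {
  stopifnot(rest_level >= 0, task_level >= 0, sigma >= 0, tau >= 0,
            decay_half_life_ms > 0)
  structure(list(rest_level = rest_level, task_level = task_level,
                 mu = mu, sigma = sigma, tau = tau,
                 decay_half_life_ms = decay_half_life_ms),
            class = "activation_profile")
}

# default production definitions: if-pattern over buffers, then-effect.
# chunks are named character vectors; buffers hold at most one chunk.
default_productions <- function(stimulus) {
  duck <- c(`is-a` = "animal", name = "duckling", color = "yellow",
            size = "small")
  turtle <- c(`is-a` = "animal", name = "turtle", color = "green",
              size = "small")
  percept <- if (stimulus == "target") duck else turtle
  action <- if (stimulus == "target") "press" else "withhold"
  list(
    visual = list(
      match = function(buf) !is.null(buf$`visual-input`),
      act = function(buf) { buf$visual <- percept; buf }),
    spatial = list(
      match = function(buf) !is.null(buf$visual),
      act = function(buf) {
        buf$spatial <- c(location = "center", object = unname(buf$visual["name"]))
        buf }),
    declarative = list(
      match = function(buf) !is.null(buf$spatial),
      act = function(buf) {
        buf$retrieval <- c(object = unname(buf$spatial["object"]),
                           instruction = action)
        buf }),
    executive = list(
      match = function(buf) !is.null(buf$retrieval),
      act = function(buf) {
        buf$goal <- c(plan = unname(buf$retrieval["instruction"]))
        buf }),
    procedural = list(
      match = function(buf) !is.null(buf$goal),
      act = function(buf) {
        buf$goal <- c(buf$goal,
                      decision = if (buf$goal["plan"] == "press") "release"
                                 else "stop")
        buf }),
    manual = list(
      match = function(buf) !is.null(buf$goal) && "decision" %in% names(buf$goal),
      act = function(buf) {
        buf$manual <- c(response = if (buf$goal["decision"] == "release")
          "press" else "none")
        buf })
  )
}

#' Run the production-cycle model on one stimulus
#'
#' Minimal serial production engine: at each scheduled completion slot the
#' (single) production whose if-pattern matches the current buffer contents
#' fires and rewrites the buffers; no two firings share a time stamp.  A slot
#' with no matching production is a stall error.  Target runs end with the
#' motor program released, distractor runs with the response withheld.  Each
#' firing is stamped with its completion time, its activation level (from the
#' profile, scaled by production speed) and the dipole of the matching
#' condition whose peak time equals the completion time (NA when the
#' condition has no dipole there; the distractor schedule only has dipoles
#' at 250 and 550 ms).
#'
#' @param stimulus "target" or "distractor".
#' @param schedule a \code{production_schedule}.
#' @param profile an [activation_profile()].
#' @param dipoles a \code{dipole_config} (default [default_dipoles()]).
#' @return list of class \code{"firing_trace"}: \code{trace} (data.frame:
#'   time_ms, production, module, region, activation, decay_rate, dipole),
#'   \code{response} ("release"/"withhold"), \code{stimulus},
#'   \code{buffers} (final state).
#' @export
run_model <- function(stimulus = c("target", "distractor"),
                      schedule = build_schedule(),
                      profile = activation_profile(),
                      dipoles = default_dipoles()) {
  stimulus <- match.arg(stimulus)
  prods <- default_productions(stimulus)
  missing_mod <- setdiff(schedule$module, names(prods))
  if (length(missing_mod)) {
    stop("no production defined for module(s): ",
         paste(missing_mod, collapse = ", "))
  }
  buffers <- list(`visual-input` = c(stimulus = stimulus))
  durations <- diff(c(0, schedule$completion_ms))
  base_dur <- schedule$completion_ms[1]
  dcond <- dipoles[dipoles$condition == stimulus, , drop = FALSE]
  rows <- vector("list", nrow(schedule))
  for (k in seq_len(nrow(schedule))) {
    p <- prods[[schedule$module[k]]]
    if (!p$match(buffers)) {
      stop("stall: production '", schedule$production[k],
           "' does not match the buffer state at t = ",
           schedule$completion_ms[k], " ms")
    }
    buffers <- p$act(buffers)
    intensity <- profile$task_level * base_dur / durations[k]
    decay <- log(2) / profile$decay_half_life_ms *
      (intensity / max(profile$task_level, .Machine$double.eps))
    hit <- which(dcond$peak_ms == schedule$completion_ms[k])
    rows[[k]] <- data.frame(
      time_ms = schedule$completion_ms[k],
      production = schedule$production[k], module = schedule$module[k],
      region = schedule$region[k], activation = intensity,
      decay_rate = decay,
      dipole = if (length(hit)) dcond$label[hit[1]] else NA_character_,
      stringsAsFactors = FALSE)
  }
  trace <- do.call(rbind, rows)
  response <- if (!is.null(buffers$manual) &&
                  buffers$manual["response"] == "press") "release" else "withhold"
  structure(list(trace = trace, response = response, stimulus = stimulus,
                 buffers = buffers, profile = profile),
            class = "firing_trace")
}

# activation level of one dipole at time t given the trace: task intensity at
# its firing instant, exponential decay afterwards (floored at rest), rest
# level before it fires or if it never fires
dipole_level_at <- function(t, dipole_label, trace, profile) {
  rest <- profile$rest_level * profile$task_level
  i <- which(trace$trace$dipole == dipole_label)
  if (!length(i)) return(rest)
  t0 <- trace$trace$time_ms[i[1]]
  if (t < t0) return(rest)
  if (t == t0) return(trace$trace$activation[i[1]])
  max(rest, trace$trace$activation[i[1]] *
        exp(-trace$trace$decay_rate[i[1]] * (t - t0)))
}

#' Polyspiking patterns per electrode
#'
#' One spike per production completion time and electrode: the firing
#' production's dipole contributes its task-level field (via the forward
#' model), while all other dipoles of the condition contribute resting or
#' decaying background activation.  The six-production default guarantees at
#' least six spikes per electrode.  Firings with no mapped dipole contribute
#' background only; a firing referencing a dipole absent from the
#' configuration is an error.
#'
#' @param trace a \code{firing_trace} from [run_model()].
#' @param dipoles a \code{dipole_config}.
#' @param montage montage (default [standard_montage()]).
#' @return list of class \code{"spike_patterns"}: per electrode a data.frame
#'   (time_ms, amplitude, source); attr \code{condition}.
#' @export
polyspike <- function(trace, dipoles, montage = standard_montage()) {
  dcond <- dipoles[dipoles$condition == trace$stimulus, , drop = FALSE]
  fired <- trace$trace$dipole[!is.na(trace$trace$dipole)]
  bad <- setdiff(fired, dcond$label)
  if (length(bad)) {
    stop("firing references dipole(s) absent from the configuration: ",
         paste(bad, collapse = ", "))
  }
  G <- if (nrow(dcond)) field_matrix(dcond, montage) else
    matrix(0, nrow(montage), 0, dimnames = list(montage$label, NULL))
  times <- trace$trace$time_ms
  out <- list()
  for (e in montage$label) {
    amp <- vapply(times, function(t) {
      if (!ncol(G)) return(0)
      sum(vapply(seq_len(nrow(dcond)), function(j) {
        dipole_level_at(t, dcond$label[j], trace, trace$profile) * G[e, j]
      }, numeric(1)))
    }, numeric(1))
    src <- ifelse(is.na(trace$trace$dipole), "background", trace$trace$dipole)
    out[[e]] <- data.frame(time_ms = times, amplitude = amp, source = src,
                           stringsAsFactors = FALSE)
  }
  structure(out, condition = trace$stimulus, class = "spike_patterns")
}

#' Coarse-code spike amplitudes onto the relative voltage scale
#'
#' Linearly maps relative amplitudes onto \code{n_levels} ordered intensity
#' categories spanning \code{scale} (default -6..+6 uV, 13 levels so zero
#' sits in the middle category).  With \code{normalize = TRUE} (default) a
#' symmetric gain first maps the largest absolute amplitude to the scale
#' bound, preserving sign and zero; values landing outside the scale are
#' clipped and counted.
#'
#' @param amplitudes numeric vector (or \code{spike_patterns}; then all
#'   patterns are coded jointly and returned per electrode).
#' @param scale c(low, high), low < high.
#' @param n_levels number of categories (>= 2).
#' @param normalize apply the symmetric max-|amplitude| gain.
#' @return for a numeric input: data.frame (amplitude, code, value_uv) with
#'   attributes \code{gain} and \code{n_clipped}; for \code{spike_patterns}:
#'   list of coded data.frames per electrode with the same attributes.
#' @export
coarse_code <- function(amplitudes, scale = c(-6, 6), n_levels = 13,
                        normalize = TRUE) {
  if (n_levels < 2) stop("n_levels must be >= 2")
  if (scale[2] <= scale[1]) stop("degenerate scale")
  if (inherits(amplitudes, "spike_patterns")) {
    all_amp <- unlist(lapply(amplitudes, `[[`, "amplitude"))
    gain <- code_gain(all_amp, scale, normalize)
    out <- lapply(amplitudes, function(p) {
      cc <- code_values(p$amplitude * gain, scale, n_levels)
      cbind(p, cc[c("code", "value_uv")])
    })
    cc_all <- code_values(all_amp * gain, scale, n_levels)
    return(structure(out, gain = gain,
                     n_clipped = attr(cc_all, "n_clipped"),
                     condition = attr(amplitudes, "condition"),
                     class = "coded_patterns"))
  }
  gain <- code_gain(amplitudes, scale, normalize)
  code_values(amplitudes * gain, scale, n_levels, gain = gain)
}

code_gain <- function(amplitudes, scale, normalize) {
  if (!normalize) return(1)
  m <- max(abs(amplitudes))
  if (m == 0) 1 else min(abs(scale)) / m
}

code_values <- function(x, scale, n_levels, gain = NULL) {
  lo <- scale[1]; hi <- scale[2]
  n_clipped <- sum(x < lo | x > hi)
  xc <- pmin(pmax(x, lo), hi)
  code <- pmin(pmax(1L + floor((xc - lo) / (hi - lo) * n_levels), 1L),
               as.integer(n_levels))
  width <- (hi - lo) / n_levels
  value <- lo + (code - 0.5) * width
  structure(data.frame(amplitude = x, code = as.integer(code),
                       value_uv = value),
            n_clipped = n_clipped, gain = gain)
}

#' Simulated field value at arbitrary times
#'
#' Evaluates the condition's aggregate dipole field (task / decaying /
#' resting levels times forward gains) at the requested times for every
#' electrode; used to assemble per-bin topographic maps at bin mid-points.
#'
#' @param trace a \code{firing_trace}.
#' @param dipoles a \code{dipole_config}.
#' @param montage montage.
#' @param times numeric times, ms.
#' @return electrode x time matrix.
#' @export
field_at_times <- function(trace, dipoles, montage = standard_montage(),
                           times) {
  dcond <- dipoles[dipoles$condition == trace$stimulus, , drop = FALSE]
  out <- matrix(0, nrow(montage), length(times),
                dimnames = list(montage$label, times))
  if (!nrow(dcond)) return(out)
  G <- field_matrix(dcond, montage)
  for (ti in seq_along(times)) {
    lev <- vapply(dcond$label, dipole_level_at, numeric(1),
                  t = times[ti], trace = trace, profile = trace$profile)
    out[, ti] <- G %*% lev
  }
  out
}

#' Simulated topographic maps at bin mid-points
#'
#' Runs the model for a condition, evaluates the simulated field at the
#' mid-points of the post-stimulus analysis bins, and coarse-codes the values
#' onto the relative -6..+6 uV scale (one joint gain across the condition's
#' maps so relative structure is preserved).
#'
#' @param stimulus "target" or "distractor".
#' @param bins analysis bin indices (default 1:7, 0-700 ms).
#' @param bin_ms bin width (default 100).
#' @param schedule,profile,dipoles,montage model configuration.
#' @param scale,n_levels coarse-coding parameters.
#' @return list of class \code{"topo_maps"}: per bin a data.frame
#'   (electrode, raw, value_uv, code) with attrs bin, midpoint_ms, condition,
#'   provenance = "simulated".
#' @export
simulate_topomaps <- function(stimulus = c("target", "distractor"),
                              bins = 1:7, bin_ms = 100,
                              schedule = build_schedule(),
                              profile = activation_profile(),
                              dipoles = default_dipoles(),
                              montage = standard_montage(),
                              scale = c(-6, 6), n_levels = 13) {
  stimulus <- match.arg(stimulus)
  trace <- run_model(stimulus, schedule, profile, dipoles)
  mids <- (bins - 0.5) * bin_ms
  raw <- field_at_times(trace, dipoles, montage, mids)
  gain <- code_gain(as.vector(raw), scale, TRUE)
  out <- lapply(seq_along(bins), function(i) {
    cc <- code_values(raw[, i] * gain, scale, n_levels)
    # value_uv is the continuous rescaled field; `code` holds the
    # coarse-coded intensity category
    structure(data.frame(electrode = montage$label, raw = raw[, i],
                         value_uv = raw[, i] * gain, code = cc$code,
                         stringsAsFactors = FALSE),
              bin = bins[i], midpoint_ms = mids[i], condition = stimulus,
              provenance = "simulated")
  })
  names(out) <- paste0("bin", bins)
  structure(out, condition = stimulus, gain = gain, class = "topo_maps")
}

#' Write topographic maps as a delimited grid
#'
#' Long format: condition, provenance, bin, midpoint_ms, electrode, value_uv.
#' @param maps a \code{topo_maps} list.
#' @param path file path.
#' @export
write_topomaps <- function(maps, path) {
  rows <- lapply(maps, function(m) {
    data.frame(condition = attr(m, "condition"),
               provenance = attr(m, "provenance"),
               bin = attr(m, "bin"), midpoint_ms = attr(m, "midpoint_ms"),
               electrode = m$electrode, value_uv = m$value_uv,
               stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}
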