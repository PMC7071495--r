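#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs \code{code}, then restores the caller's RNG state.
#' With \code{seed = NULL} the code runs on the current stream.
#' @param seed integer or NULL.
#' @param code expression.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reference target-distractor peak-difference table
#'
#' The published mean target minus distractor peak-amplitude differences (uV)
#' with their advantage labels ("T" target-larger, "D" distractor-larger) for
#' the 12-channel montage over seven 100 ms post-stimulus bins (0-700 ms).
#' Used as the worked example for cell classification and as the default
#' effect structure of the synthetic generator.  A \code{polarity} column is
#' derived from the labels: the sign of the dominant peak at each cell
#' (\code{sign(diff)} for target-advantage cells, \code{-sign(diff)} for
#' distractor-advantage cells, \code{sign(diff)} assumed elsewhere).
#'
#' @return data.frame: electrode, bin, bin_start_ms, bin_end_ms, diff_uv,
#'   flag ("T"/"D"/""), polarity (+1/-1).
#' @export
reference_differences <- function() {
  path <- system.file("extdata", "target_distractor_differences.csv",
                      package = "erpactr")
  d <- as.data.frame(data.table::fread(path, colClasses = list(character = "flag")))
  d$flag[is.na(d$flag)] <- ""
  s <- sign(d$diff_uv)
  d$polarity <- ifelse(d$flag == "D", -s, ifelse(s == 0, 1, s))
  d
}

# default electrode x 12-epoch-bin enhancement matrix (uV): reference
# differences in post-stimulus bins 1..7 (epoch bins 3..9), zero elsewhere
default_enhancement <- function() {
  ref <- reference_differences()
  m <- matrix(0, 12, 12, dimnames = list(MONTAGE_12, paste0("bin", 1:12)))
  m[cbind(match(ref$electrode, MONTAGE_12), ref$bin + 2L)] <- ref$diff_uv
  m
}

#' Configuration for the synthetic-data generator
#'
#' Defaults are the stated experimental conditions: 13 subjects, a 150-trial
#' block with 37 targets, hit rate 0.775, false-alarm rate 0.0607,
#' ex-Gaussian response times with mean 685 ms (mu 485, sigma 50, tau 200),
#' epochs spanning -200..+1000 ms at 1000 Hz (1200 samples), Gaussian AR(1)
#' background noise (phi 0.95, innovation sd 2 uV), and an enhancement table
#' equal to the reference difference table on the 0-700 ms bins.
#'
#' @param n_subjects,n_trials,n_targets design sizes.
#' @param hit_rate,fa_rate response probabilities for targets/distractors.
#' @param rt_mu,rt_sigma,rt_tau ex-Gaussian RT parameters, ms.
#' @param sampling_rate Hz.
#' @param epoch_ms epoch limits c(start, end), ms; samples are
#'   \code{seq(start, end - 1000/sampling_rate, by = 1000/sampling_rate)}.
#' @param ar_phi,ar_sd AR(1) coefficient and innovation sd (uV).
#' @param subject_sd sd of the per-subject additive offset (uV).
#' @param enhancement electrode x epoch-bin matrix of signed target minus
#'   distractor mean offsets (uV); NULL for the default table.
#' @param reject_fraction fraction of trials marked artifact-rejected
#'   (default 0; exposed only as a knob, the epochs are per-subject averages).
#' @param seed default seed used by the generators when their own
#'   \code{seed} argument is missing.
#' @return list of class \code{"generator_config"}.
#' @export
generator_config <- function(n_subjects = 13, n_trials = 150, n_targets = 37,
                             hit_rate = 0.775, fa_rate = 0.0607,
                             rt_mu = 485, rt_sigma = 50, rt_tau = 200,
                             sampling_rate = 1000, epoch_ms = c(-200, 1000),
                             ar_phi = 0.95, ar_sd = 2, subject_sd = 1,
                             enhancement = NULL, reject_fraction = 0,
                             seed = NULL) {
  if (n_targets > n_trials) stop("n_targets must be <= n_trials")
  stopifnot(hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1,
            ar_sd >= 0, rt_sigma >= 0, rt_tau >= 0, subject_sd >= 0,
            reject_fraction >= 0, reject_fraction < 1,
            length(epoch_ms) == 2, epoch_ms[1] < epoch_ms[2])
  if (is.null(enhancement)) enhancement <- default_enhancement()
  structure(list(n_subjects = n_subjects, n_trials = n_trials,
                 n_targets = n_targets, hit_rate = hit_rate, fa_rate = fa_rate,
                 rt_mu = rt_mu, rt_sigma = rt_sigma, rt_tau = rt_tau,
                 sampling_rate = sampling_rate, epoch_ms = epoch_ms,
                 ar_phi = ar_phi, ar_sd = ar_sd, subject_sd = subject_sd,
                 enhancement = enhancement, reject_fraction = reject_fraction,
                 seed = seed),
            class = "generator_config")
}

#' Generate a pseudo-random trial sequence
#'
#' Exact stimulus counts (\code{n_targets} targets, the rest distractors) in
#' a seeded random order.  Each trial: 500 ms stimulus followed by a 500 ms
#' fixation cross; onsets are consecutive.
#'
#' @param cfg a [generator_config()].
#' @param seed integer; default \code{cfg$seed}.
#' @return data.frame: trial, stimulus, stimulus_onset_ms,
#'   stimulus_duration_ms, fixation_duration_ms, rejected.
#' @export
generate_trials <- function(cfg = generator_config(), seed = cfg$seed) {
  with_seed(seed, {
    stim <- rep("distractor", cfg$n_trials)
    stim[sample.int(cfg$n_trials, cfg$n_targets)] <- "target"
    rejected <- stats::runif(cfg$n_trials) < cfg$reject_fraction
    data.frame(trial = seq_len(cfg$n_trials), stimulus = stim,
               stimulus_onset_ms = (seq_len(cfg$n_trials) - 1) * 1000,
               stimulus_duration_ms = 500, fixation_duration_ms = 500,
               rejected = rejected, stringsAsFactors = FALSE)
  })
}

# ex-Gaussian draw; tau = 0 degenerates to Gaussian
rexgauss <- function(n, mu, sigma, tau) {
  g <- stats::rnorm(n, mu, sigma)
  if (tau > 0) g <- g + stats::rexp(n, rate = 1 / tau)
  g
}

#' Generate behavioral responses for a trial sequence
#'
#' Bernoulli responses at \code{hit_rate} on targets and \code{fa_rate} on
#' distractors; response times drawn from the configured ex-Gaussian.
#' \code{correct} is TRUE for target-with-response and
#' distractor-without-response trials.
#'
#' @param trials output of [generate_trials()].
#' @param cfg a [generator_config()].
#' @param seed integer; default \code{cfg$seed}.
#' @return data.frame: trial, stimulus, responded, rt_ms (NA when no
#'   response), correct.
#' @export
generate_behavior <- function(trials, cfg = generator_config(), seed = cfg$seed) {
  with_seed(seed, {
    is_t <- trials$stimulus == "target"
    p <- ifelse(is_t, cfg$hit_rate, cfg$fa_rate)
    responded <- stats::runif(nrow(trials)) < p
    rt <- rep(NA_real_, nrow(trials))
    n_resp <- sum(responded)
    if (n_resp > 0) {
      draw <- rexgauss(n_resp, cfg$rt_mu, cfg$rt_sigma, cfg$rt_tau)
      rt[responded] <- pmax(draw, 1)  # RTs must be positive
    }
    data.frame(trial = trials$trial, stimulus = trials$stimulus,
               responded = responded, rt_ms = rt,
               correct = is_t == responded, stringsAsFactors = FALSE)
  })
}

epoch_times <- function(cfg) {
  step <- 1000 / cfg$sampling_rate
  seq(cfg$epoch_ms[1], cfg$epoch_ms[2] - step, by = step)
}

# shared child-ERP-like base morphology: early posterior positivity, a
# mid-latency negativity and a late slow positivity, scaled per electrode by
# scalp height so the maps are not flat
base_waveform <- function(times, montage) {
  g <- function(t, m, s) exp(-((t - m) / s)^2 / 2)
  shape <- 3 * g(times, 150, 40) - 2 * g(times, 300, 60) + 4 * g(times, 600, 120)
  gain <- 0.5 + montage$z / 2
  outer(gain, shape)
}

# smooth per-bin raised-cosine bumps whose within-bin mean equals the
# configured offset; zero at bin edges so the profile is continuous
enhancement_waveform <- function(times, enhancement, epoch_ms, n_bins = 12) {
  width <- (epoch_ms[2] - epoch_ms[1]) / n_bins
  out <- matrix(0, nrow(enhancement), length(times))
  for (b in seq_len(n_bins)) {
    lo <- epoch_ms[1] + (b - 1) * width
    inb <- times >= lo & times < lo + width
    if (!any(inb)) next
    u <- (times[inb] - lo) / width
    bump <- 1 - cos(2 * pi * u)  # mean 1 over the bin
    out[, inb] <- out[, inb] + outer(enhancement[, b], bump)
  }
  out
}

#' Generate a multi-subject epoched ERP set
#'
#' Amplitude(subject, condition, electrode, t) = AR(1) noise + subject offset
#' + condition waveform.  Two condition-waveform modes: (a) default, a shared
#' smooth base morphology plus per-bin raised-cosine enhancement bumps on the
#' target condition whose within-bin means equal the configured enhancement
#' table; (b) with \code{dipoles} supplied, the forward scalp projection of
#' each condition's dipoles (for recovery tests; with zero noise the epochs
#' equal the projection exactly).
#'
#' @param cfg a [generator_config()].
#' @param dipoles optional \code{dipole_config}; switches on mode (b).
#' @param seed integer; default \code{cfg$seed}.
#' @return object of class \code{"epoch_set"}: list with \code{amplitude}
#'   (4-d array subject x condition x electrode x time), \code{subjects},
#'   \code{conditions}, \code{electrodes}, \code{times}.
#' @export
generate_epochs <- function(cfg = generator_config(), dipoles = NULL,
                            seed = cfg$seed) {
  times <- epoch_times(cfg)
  montage <- standard_montage()
  conds <- c("target", "distractor")
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  nt <- length(times)
  wave <- list()
  if (is.null(dipoles)) {
    base <- base_waveform(times, montage)
    enh <- enhancement_waveform(times, cfg$enhancement, cfg$epoch_ms)
    wave$target <- base + enh
    wave$distractor <- base
  } else {
    for (cn in conds) {
      wave[[cn]] <- scalp_projection(dipoles[dipoles$condition == cn, ],
                                     montage, times)
    }
  }
  amp <- array(0, dim = c(cfg$n_subjects, 2, 12, nt),
               dimnames = list(subjects, conds, MONTAGE_12, NULL))
  with_seed(seed, {
    offs <- stats::rnorm(cfg$n_subjects, 0, cfg$subject_sd)
    for (s in seq_len(cfg$n_subjects)) {
      for (ci in seq_along(conds)) {
        for (e in seq_len(12)) {
          noise <- if (cfg$ar_sd > 0) {
            innov <- stats::rnorm(nt, 0, cfg$ar_sd)
            init <- stats::rnorm(1, 0, cfg$ar_sd / sqrt(1 - cfg$ar_phi^2))
            as.numeric(stats::filter(innov, cfg$ar_phi, method = "recursive",
                                     init = init))
          } else numeric(nt)
          amp[s, ci, e, ] <- wave[[conds[ci]]][e, ] + offs[s] + noise
        }
      }
    }
  })
  structure(list(amplitude = amp, subjects = subjects, conditions = conds,
                 electrodes = MONTAGE_12, times = times),
            class = "epoch_set")
}

#' Validate an epoch set
#'
#' Checks grid completeness, dimension consistency and finiteness.
#' @param epochs an \code{epoch_set}.
#' @return the input, invisibly; errors describe the failure.
#' @export
validate_epochs <- function(epochs) {
  if (!inherits(epochs, "epoch_set")) stop("not an epoch_set")
  d <- dim(epochs$amplitude)
  if (!identical(d, c(length(epochs$subjects), length(epochs$conditions),
                      length(epochs$electrodes), length(epochs$times)))) {
    stop("epoch_set dimensions inconsistent with its labels")
  }
  if (anyNA(epochs$amplitude) || any(!is.finite(epochs$amplitude))) {
    stop("epoch_set contains missing or non-finite amplitudes")
  }
  invisible(epochs)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("epoch_set:", length(x$subjects), "subjects x",
      length(x$conditions), "conditions x", length(x$electrodes),
      "electrodes x", length(x$times), "samples\n")
  cat("time grid:", min(x$times), "..", max(x$times), "ms\n")
  invisible(x)
}

#' Convert an epoch set to the long format
#' @param x an \code{epoch_set}.
#' @param ... unused.
#' @return data.frame: subject, condition, electrode, time_ms, amplitude_uV.
#' @export
as.data.frame.epoch_set <- function(x, ...) {
  g <- expand.grid(subject = x$subjects, condition = x$conditions,
                   electrode = x$electrodes, time_ms = x$times,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$amplitude_uV <- as.vector(x$amplitude)
  g
}
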