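# small seeded configurations used across the suite; sampling is scaled down
# from 1000 Hz to keep the default test run fast (the vincentization and
# ANOVA are invariant to the within-bin sample count for constant signals)

tiny_config <- function(..., n_subjects = 4, sampling_rate = 100, seed = 11) {
  generator_config(n_subjects = n_subjects, sampling_rate = sampling_rate,
                   seed = seed, ...)
}

zero_enhancement <- function() {
  m <- matrix(0, 12, 12, dimnames = list(MONTAGE_12, paste0("bin", 1:12)))
  m
}

# enhancement matrix with a single configured cell (analysis bin 1..7 maps to
# epoch bin + 2)
spot_enhancement <- function(electrode, analysis_bin, uv) {
  m <- zero_enhancement()
  m[electrode, analysis_bin + 2] <- uv
  m
}

# independent legality checker used by the path replay tests: re-derives the
# movement rules from the published wording, without calling package internals
oracle_legal <- function(a, b) {
  rows <- list(F3 = 1, Fz = 1, F4 = 1, T7 = 2, Cz = 2, T8 = 2,
               P7 = 3, Pz = 3, P8 = 3, O1 = 4, Oz = 4, O2 = 4)
  cols <- list(F3 = 1, Fz = 2, F4 = 3, T7 = 1, Cz = 2, T8 = 3,
               P7 = 1, Pz = 2, P8 = 3, O1 = 1, Oz = 2, O2 = 3)
  ra <- rows[[a]]; rb <- rows[[b]]; ca <- cols[[a]]; cb <- cols[[b]]
  if (ra == 4 && rb > ra) return(FALSE)
  if (ra == 1 && rb < ra) return(FALSE)
  if (cb != ca) {
    if (ca == 1 && cb < ca) return(FALSE)
    if (ca == 3 && cb > ca) return(FALSE)
  }
  TRUE
}
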