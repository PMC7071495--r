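# independent oracles shared across test files

aov_oracle <- function(d) {
  # independent brute-force decomposition via R's projection-based aov
  d$case <- interaction(d$subject, d$bin)
  d$B <- factor(d$bin); d$E <- factor(d$electrode); d$C <- factor(d$condition)
  fit <- stats::aov(value ~ B * E * C + Error(case / (E * C)), data = d)
  s <- summary(fit)
  get <- function(stratum, row) {
    tab <- s[[stratum]][[1]]
    ss <- tab[trimws(rownames(tab)) == row, "Sum Sq"]
    if (length(ss)) ss else NA_real_
  }
  c(bin = get("Error: case", "B"),
    case = get("Error: case", "Residuals"),
    electrode = get("Error: case:E", "E"),
    electrode_bin = get("Error: case:E", "B:E"),
    electrode_case = get("Error: case:E", "Residuals"),
    condition = get("Error: case:C", "C"),
    condition_bin = get("Error: case:C", "B:C"),
    condition_case = get("Error: case:C", "Residuals"),
    ec = get("Error: case:E:C", "E:C"),
    ecb = get("Error: case:E:C", "B:E:C"),
    ec_case = get("Error: case:E:C", "Residuals"))
}

rand_design <- function(seed, nS = 3, nB = 2, nE = 3, nC = 2) {
  set.seed(seed)
  d <- expand.grid(subject = paste0("s", seq_len(nS)), bin = seq_len(nB),
                   electrode = letters[seq_len(nE)],
                   condition = c("t", "d")[seq_len(nC)],
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d), sd = 2) + 0.5 * (d$condition == "t") +
    as.numeric(factor(d$electrode)) * 0.3
  d
}

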