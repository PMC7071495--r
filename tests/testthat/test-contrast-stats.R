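test_that("omnibus ANOVA equals the projection oracle on random designs", {
  for (seed in c(1, 2, 3, 4, 5)) {
    d <- rand_design(seed)
    res <- omnibus_anova(d)
    o <- aov_oracle(d)
    got <- setNames(res$ss, res$effect)
    expect_equal(unname(got[c("bin", "case(bin)", "electrode",
                              "electrode:bin", "electrode:case(bin)",
                              "condition", "condition:bin",
                              "condition:case(bin)", "electrode:condition",
                              "electrode:condition:bin",
                              "electrode:condition:case(bin)")]),
                 unname(o), tolerance = 1e-8)
  }
  # larger asymmetric design
  d <- rand_design(9, nS = 4, nB = 3, nE = 4)
  expect_equal(unname(setNames(omnibus_anova(d)$ss, NULL)),
               unname(aov_oracle(d)), tolerance = 1e-8)
})

test_that("omnibus ANOVA hand-computed toy and degenerate input", {
  # 2 subjects x 1 bin x 2 electrodes x 2 conditions with known values
  d <- expand.grid(subject = c("s1", "s2"), bin = 1,
                   electrode = c("a", "b"), condition = c("t", "d"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$value <- c(1, 2, 3, 4, 5, 6, 7, 8)
  res <- omnibus_anova(d)
  g <- function(e) res$ss[res$effect == e]
  # hand decomposition: grand mean 4.5; subject means 4,5 -> case SS = 4*0.5
  expect_equal(g("case(bin)"), 2)
  # electrode means 3.5, 5.5 -> SS = 4 * (1 + 1) = 8; condition means 2.5,6.5
  expect_equal(g("electrode"), 8)
  expect_equal(g("condition"), 32)
  expect_equal(g("electrode:condition"), 0)
  expect_equal(sum(res$ss), sum((d$value - 4.5)^2), tolerance = 1e-12)
  expect_equal(mse_within(res), 0)
  # zero-variance data: every SS is 0
  d0 <- d; d0$value <- 3
  expect_true(all(omnibus_anova(d0)$ss == 0))
  # unbalanced input errors
  expect_error(omnibus_anova(d[-1, ]), "unbalanced")
})

test_that("Bonferroni t critical values", {
  expect_equal(bonferroni_tcrit(1e-4, m = 1, df = 12), 5.69, tolerance = 0.01)
  expect_equal(bonferroni_tcrit(0.05, m = 1, df = 10000), 1.96,
               tolerance = 0.005)
  expect_equal(bonferroni_tcrit(0.5, m = 1, df = 1), 1.0, tolerance = 1e-9)
  # family division: m = 12 equals the corrected level directly
  expect_equal(bonferroni_tcrit(0.05, m = 12, df = 20),
               qt(1 - (0.05 / 12) / 2, 20), tolerance = 1e-12)
  expect_error(bonferroni_tcrit(0.05, 12, df = 0), "df")
})

test_that("minimum significant difference", {
  expect_equal(min_sig_diff(5.69, 0.132, c(1, -1), c(13, 13)), 0.80,
               tolerance = 0.02)
  expect_equal(min_sig_diff(5.69, 0), 0)
  expect_equal(min_sig_diff(2, 0.5, c(1, -1), c(4, 4)), 1.0, tolerance = 1e-12)
  # homogeneity: scaling lambda by s scales the threshold by |s|
  for (s in c(0.5, 2, -3)) {
    expect_equal(min_sig_diff(3, 0.7, s * c(1, -1), c(5, 5)),
                 abs(s) * min_sig_diff(3, 0.7, c(1, -1), c(5, 5)),
                 tolerance = 1e-12)
  }
  expect_error(min_sig_diff(2, -0.1), "mse")
  expect_error(min_sig_diff(2, 0.1, c(1, 1)), "sum to 0")
})

test_that("cell classification on the reference difference table", {
  ref <- reference_differences()
  sig <- classify_cells(ref, 0.80)
  expect_s3_class(sig, "significance_table")
  expect_equal(nrow(sig), 84)
  # reproduces the printed advantage labels exactly
  expect_identical(sig$flag, ref$flag)
  expect_equal(sum(sig$flag == "D"), 5)
  expect_equal(sum(sig$flag == "T"), 50)
  # negative differences at negative-going peaks are target advantages
  t7b1 <- sig[sig$electrode == "T7" & sig$bin == 1, ]
  expect_true(t7b1$diff_uv < 0 && t7b1$flag == "T")
})

test_that("classification rule on constructed tables", {
  d <- data.frame(electrode = c("Pz", "Cz"), bin = c(1, 1),
                  diff_uv = c(1, 0.2), stringsAsFactors = FALSE)
  sig <- classify_cells(d, 0.5, polarity = 1)
  expect_equal(sig$flag, c("T", ""))
  sigD <- classify_cells(d, 0.5, polarity = -1)
  expect_equal(sigD$flag, c("D", ""))
  # zero threshold flags every cell
  expect_equal(classify_cells(d, 0, polarity = 1)$flag, c("T", "T"))
  # polarity metadata is mandatory once a cell is significant
  expect_error(classify_cells(d, 0.5, polarity = NULL), "polarity")
  zero <- data.frame(electrode = "Pz", bin = 1, diff_uv = 0)
  expect_equal(classify_cells(zero, 0.5, polarity = 1)$flag, "")
  pol_na <- data.frame(electrode = "Pz", bin = 1, diff_uv = 2,
                       polarity = NA_real_)
  expect_error(classify_cells(pol_na, 0.5), "missing polarity")
})

test_that("enhancement proportion chi-square", {
  e <- enhancement_test(46, 5, 84)
  expect_equal(e$chisq, 45.05, tolerance = 0.05)
  expect_lt(e$p, 1e-4)
  expect_equal(enhancement_test(7, 7, 30)$chisq, 0)
  # independent textbook oracle for another table
  a <- 20; b <- 20; c0 <- 5; d <- 35; N <- a + b + c0 + d
  oracle <- N * (abs(a * d - b * c0) - N / 2)^2 /
    ((a + b) * (c0 + d) * (a + c0) * (b + d))
  expect_equal(enhancement_test(20, 5, 40)$chisq, oracle, tolerance = 1e-12)
  # matches stats::chisq.test with continuity correction
  ct <- suppressWarnings(stats::chisq.test(rbind(c(20, 20), c(5, 35))))
  expect_equal(enhancement_test(20, 5, 40)$chisq, unname(ct$statistic),
               tolerance = 1e-9)
  # symmetric under swapping the rows
  expect_equal(enhancement_test(5, 20, 40)$chisq,
               enhancement_test(20, 5, 40)$chisq, tolerance = 1e-12)
  expect_error(enhancement_test(0, 0, 0), "margin")
})
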