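test_that("left-continuous empirical quantile", {
  expect_equal(empirical_quantile(c(4, 2, 1, 3), 0.5), 2)
  expect_equal(empirical_quantile(c(4, 2, 1, 3), 1e-9), 1)
  expect_equal(empirical_quantile(7, 0.42), 7)
  # enumeration oracle: smallest v with F(v) >= alpha
  set.seed(1)
  x <- rnorm(17)
  for (a in c(0.05, 0.3, 0.5, 0.77, 0.99)) {
    oracle <- min(x[vapply(x, function(v) mean(x <= v) >= a, logical(1))])
    expect_equal(empirical_quantile(x, a), oracle)
  }
  expect_error(empirical_quantile(numeric(0), 0.5), "empty")
  expect_error(empirical_quantile(1:3, 0), "alpha")
})

test_that("quantile mid-points are the sorted sample at q = n", {
  x <- c(5, 1, 4, 2, 3)
  qf <- quantile_midpoints(x)
  expect_equal(qf$value, sort(x))
  expect_equal(qf$alpha, (1:5 - 0.5) / 5)
  expect_false(is.unsorted(qf$value))
})

test_that("vincent averaging", {
  qf <- quantile_midpoints(c(2, 4, 6, 8))
  same <- vincent_average(list(qf, qf, qf))
  expect_equal(same$value, qf$value)
  # point masses at a and b with equal weights -> constant (a+b)/2
  a <- quantile_midpoints(rep(3, 4)); b <- quantile_midpoints(rep(7, 4))
  expect_equal(vincent_average(list(a, b))$value, rep(5, 4))
  # closed form: U(0,1) and U(1,2) average to U(0.5, 1.5)
  alpha <- (1:100 - 0.5) / 100
  u01 <- structure(data.frame(alpha = alpha, value = alpha),
                   class = c("quantile_function", "data.frame"))
  u12 <- structure(data.frame(alpha = alpha, value = 1 + alpha),
                   class = c("quantile_function", "data.frame"))
  avg <- vincent_average(list(u01, u12))
  expect_equal(avg$value, 0.5 + alpha, tolerance = 1e-12)
  expect_error(vincent_average(list(u01, u12), c(0.6, 0.6)), "sum to 1")
  expect_error(vincent_average(list(u01, u12), c(1.5, -0.5)), "non-negative")
})

test_that("vincentized epochs: constants, shifts, degenerate averages", {
  cfg <- tiny_config(n_subjects = 1, ar_sd = 0, subject_sd = 0,
                     enhancement = zero_enhancement())
  ep <- generate_epochs(cfg)
  ep$amplitude[] <- 4.25
  bt <- vincentize_epochs(ep)
  expect_equal(nrow(bt), 1 * 2 * 12 * 12)
  expect_true(all(bt$value == 4.25))
  # one subject: cell equals that subject's within-bin mid-point quantile mean
  ep1 <- generate_epochs(tiny_config(n_subjects = 1, seed = 21))
  bt1 <- vincentize_epochs(ep1)
  sel <- bt1$condition == "target" & bt1$electrode == "Pz" & bt1$bin == 5
  inbin <- ep1$times >= -200 + 4 * 100 & ep1$times < -200 + 5 * 100
  manual <- mean(quantile_midpoints(
    ep1$amplitude[1, 1, match("Pz", ep1$electrodes), inbin])$value)
  expect_equal(bt1$value[sel], manual, tolerance = 1e-12)
  # two subjects differing by a pure +2 uV shift: cells = single + 1
  ep2 <- ep1
  ep2$amplitude <- array(0, dim = c(2, dim(ep1$amplitude)[-1]),
                         dimnames = c(list(c("S01", "S02")),
                                      dimnames(ep1$amplitude)[-1]))
  ep2$amplitude[1, , , ] <- ep1$amplitude[1, , , ]
  ep2$amplitude[2, , , ] <- ep1$amplitude[1, , , ] + 2
  ep2$subjects <- c("S01", "S02")
  bt2 <- vincentize_epochs(ep2)
  m1 <- bin_means(bt1); m2 <- bin_means(bt2)
  expect_equal(m2$value, m1$value + 1, tolerance = 1e-12)
})

test_that("shape preservation within a location-scale family", {
  # subjects are affine transforms of a common base sample; the Vincent
  # average must standardize back to the base shape
  set.seed(77)
  base <- sort(rexp(60) - 1)
  a <- c(-1, 0.5, 2); b <- c(0.5, 1.5, 3)
  fns <- lapply(1:3, function(i) quantile_midpoints(a[i] + b[i] * base))
  avg <- vincent_average(fns)
  std <- function(v) (v - mean(v)) / sd(v)
  expect_equal(std(avg$value), std(base), tolerance = 1e-9)
  expect_false(is.unsorted(avg$value))
})

test_that("unequal vincent weights and baseline flag", {
  ep <- generate_epochs(tiny_config(n_subjects = 2, seed = 31))
  w <- c(0.25, 0.75)
  bt <- vincentize_epochs(ep, weights = w)
  m <- bin_means(bt)
  # weighted average differs from equal weights and matches direct blending
  bt_eq <- vincentize_epochs(ep)
  per <- bt_eq[order(bt_eq$subject), ]
  s1 <- per$value[per$subject == "S01"]
  s2 <- per$value[per$subject == "S02"]
  blended <- 0.25 * s1 + 0.75 * s2
  key <- paste(per$condition, per$electrode, per$bin)[per$subject == "S01"]
  mk <- paste(m$condition, m$electrode, m$bin)
  expect_equal(m$value[match(key, mk)], blended, tolerance = 1e-12)
  # baseline subtraction zeroes the pre-stimulus mean
  bl <- vincentize_epochs(ep, baseline = TRUE)
  pre <- bl[bl$bin_end_ms <= 0, ]
  agg <- tapply(pre$value, paste(pre$subject, pre$condition, pre$electrode),
                mean)
  expect_equal(as.numeric(agg), rep(0, length(agg)), tolerance = 1e-9)
})
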