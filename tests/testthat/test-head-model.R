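test_that("standard montage geometry and symmetries", {
  m <- standard_montage()
  expect_equal(nrow(m), 12)
  expect_false(anyDuplicated(m$label) > 0)
  r <- sqrt(m$x^2 + m$y^2 + m$z^2)
  expect_equal(r, rep(1, 12), tolerance = 1e-9)
  pos <- function(l) unlist(m[m$label == l, c("x", "y", "z")], use.names = FALSE)
  expect_equal(pos("Cz"), c(0, 0, 1), tolerance = 1e-12)
  # anterior/posterior: Fz in front (y > 0), Oz behind (y < 0); Fz mirrors Pz
  # about the coronal plane under 10-20 geometry (Oz sits lower on the ring)
  expect_gt(pos("Fz")[2], 0)
  expect_lt(pos("Oz")[2], 0)
  expect_equal(pos("Fz") * c(1, -1, 1), pos("Pz"), tolerance = 1e-12)
  # left/right pairs mirror in x
  for (pair in list(c("F3", "F4"), c("T7", "T8"), c("P7", "P8"),
                    c("O1", "O2"))) {
    expect_equal(pos(pair[1]) * c(-1, 1, 1), pos(pair[2]), tolerance = 1e-12)
  }
  # 12 distinct unit vectors
  expect_equal(nrow(unique(round(m[, c("x", "y", "z")], 9))), 12)
})

test_that("unknown and duplicate montage labels are rejected by name", {
  expect_error(standard_montage(c("Cz", "XX9")), "XX9")
  expect_error(standard_montage(c("Cz", "Cz")), "duplicate")
})

test_that("dipole potential follows the three-step field rule", {
  el <- function(x, y, z) data.frame(label = "e", x = x, y = y, z = z)
  d0 <- dipole_config("d", matrix(c(0, 0, 0), 1),
                      moment = matrix(c(0, 0, 1), 1), p = 1, peak_ms = 0)
  expect_equal(dipole_potential(d0, el(0, 0, 1)), 1.0)
  expect_equal(dipole_potential(d0, el(1, 0, 0)), 0.0)
  # independent vector-arithmetic oracle for an off-axis geometry
  d1 <- dipole_config("d", matrix(c(0, 0, 0.5), 1),
                      moment = matrix(c(0, 0, 1), 1), p = 2, peak_ms = 0)
  dv <- c(0, 0.6, 0.8) - c(0, 0, 0.5)
  r <- sqrt(sum(dv^2))
  oracle <- 2 * (sum(c(0, 0, 1) * dv) / r) / r^2
  expect_equal(dipole_potential(d1, el(0, 0.6, 0.8)), oracle, tolerance = 1e-12)
  expect_error(dipole_potential(d1, el(0, 0, 0.5)), "degenerate")
})

test_that("inverse-square law and antisymmetry of the field", {
  d <- dipole_config("d", matrix(c(0, 0, 0), 1),
                     moment = matrix(c(0, 0, 1), 1), p = 1.7, peak_ms = 0)
  el <- function(v) data.frame(label = "e", x = v[1], y = v[2], z = v[3])
  u <- c(0.3, 0.2, 0.932737905308882)  # arbitrary direction (unit-ish)
  u <- u / sqrt(sum(u^2))
  v1 <- dipole_potential(d, el(0.4 * u))
  v2 <- dipole_potential(d, el(0.8 * u))  # doubled r, fixed angle
  expect_equal(abs(v1) / abs(v2), 4, tolerance = 1e-9)
  # reflecting the electrode through the plane normal to the moment flips sign
  refl <- c(0.4 * u[1], 0.4 * u[2], -0.4 * u[3])
  expect_equal(dipole_potential(d, el(refl)), -v1, tolerance = 1e-12)
})

test_that("triangular spike shape and energy", {
  expect_equal(triangular_spike(300, 300, 100, 2.5), 2.5)
  expect_equal(triangular_spike(c(250, 350), 300, 100, 2.5), c(0, 0))
  expect_equal(triangular_spike(275, 300, 100, 2.5), 1.25)
  expect_error(triangular_spike(0, 0, -1), "width")
  # time-integral equals amplitude * width / 2
  tt <- seq(199, 401, by = 0.001)
  integ <- sum(triangular_spike(tt, 300, 100, 3)) * 0.001
  expect_equal(integ, 3 * 100 / 2, tolerance = 1e-3)
})

test_that("scalp projection superposes per-dipole fields", {
  mon <- standard_montage()
  times <- seq(0, 700, by = 10)
  empty <- dipole_config(character(0), matrix(numeric(0), ncol = 3),
                         p = numeric(0), peak_ms = numeric(0),
                         width_ms = numeric(0), condition = character(0))
  expect_true(all(scalp_projection(empty, mon, times) == 0))
  dd <- default_dipoles()
  one <- dd[1, ]
  proj1 <- scalp_projection(one, mon, times)
  # composition: equals potential x unit spike curve
  g <- vapply(seq_len(12), function(i) dipole_potential(one, mon[i, ]),
              numeric(1))
  spike <- triangular_spike(times, one$peak_ms, one$width_ms)
  expect_equal(proj1, outer(g, spike), tolerance = 1e-12,
               ignore_attr = TRUE)
  # superposition over the full target set
  tgt <- dd[dd$condition == "target", ]
  total <- scalp_projection(tgt, mon, times)
  parts <- Reduce(`+`, lapply(seq_len(nrow(tgt)), function(j) {
    scalp_projection(tgt[j, ], mon, times)
  }))
  expect_equal(total, parts, tolerance = 1e-12)
})

test_that("montage and dipole files round-trip", {
  mp <- tempfile(fileext = ".csv")
  write_montage(standard_montage(), mp)
  m2 <- read_montage(mp)
  expect_equal(as.data.frame(m2), as.data.frame(standard_montage()),
               tolerance = 1e-12)
  dp <- tempfile(fileext = ".csv")
  write_dipoles(default_dipoles(), dp)
  expect_equal(as.data.frame(read_dipoles(dp)),
               as.data.frame(default_dipoles()), tolerance = 1e-12)
  # the shipped fixture equals the built-in configuration
  fix <- read_dipoles(system.file("extdata", "dipoles_synthetic.csv",
                                  package = "erpactr"))
  expect_equal(as.data.frame(fix), as.data.frame(default_dipoles()),
               tolerance = 1e-9)
})
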