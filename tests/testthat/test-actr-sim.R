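test_that("production schedule arithmetic", {
  s <- build_schedule()
  expect_equal(s$completion_ms, c(150, 250, 350, 450, 550, 650))
  expect_equal(s$completion_ms[s$module == "procedural"], 550)
  expect_equal(s$region, c("occipital", "parietal", "temporal", "frontal",
                           "basal_ganglia", "parietal"))
  expect_equal(build_schedule(cycle_ms = 0)$completion_ms, seq(100, 600, 100))
  m3 <- default_modules()[1:3, ]
  expect_equal(build_schedule(200, 50, m3)$completion_ms, c(250, 450, 650))
  expect_error(build_schedule(modules = default_modules()[0, ]), "empty")
  expect_error(build_schedule(bin_ms = -5), "positive")
})

test_that("model runs: serial firing, responses, dipole stamping", {
  tr <- run_model("target")
  expect_equal(nrow(tr$trace), 6)
  expect_equal(max(tr$trace$time_ms), 650)
  expect_equal(tr$response, "release")
  expect_false(anyDuplicated(tr$trace$time_ms) > 0)
  expect_equal(tr$trace$dipole,
               c("precuneus", "supramarginal_L", "middle_frontal_R",
                 "insula_R", "thalamus_MD_R", "caudate_body_R"))
  td <- run_model("distractor")
  expect_equal(td$response, "withhold")
  expect_equal(td$trace$dipole[td$trace$time_ms == 250], "middle_temporal_R")
  expect_equal(td$trace$dipole[td$trace$time_ms == 550], "claustrum_L")
  expect_equal(sum(!is.na(td$trace$dipole)), 2)
})

test_that("a production whose pattern cannot match stalls explicitly", {
  mods <- default_modules()[c(6, 1:5), ]  # manual first: goal buffer empty
  expect_error(run_model("target", build_schedule(modules = mods)), "stall")
})

test_that("polyspiking patterns", {
  dd <- default_dipoles()
  tr <- run_model("target")
  sp <- polyspike(tr, dd)
  expect_length(sp, 12)
  for (e in names(sp)) expect_gte(nrow(sp[[e]]), 6)
  # with rest level zero, spikes before any dipole has fired are zero:
  # distractor's first firing (150 ms) precedes both distractor dipoles
  pr0 <- activation_profile(rest_level = 0)
  td <- run_model("distractor", profile = pr0)
  sp0 <- polyspike(td, dd)
  expect_true(all(vapply(sp0, function(p) p$amplitude[p$time_ms == 150] == 0,
                         logical(1))))
  # oracle: per electrode, recompute each spike from the level model and the
  # independent field gains, then compare the maximal spike time
  dcond <- dd[dd$condition == "target", ]
  mon <- standard_montage()
  for (e in c("Pz", "F3", "O2")) {
    g <- vapply(seq_len(nrow(dcond)), function(j) {
      dipole_potential(dcond[j, ], mon[mon$label == e, ])
    }, numeric(1))
    amp <- vapply(tr$trace$time_ms, function(t) {
      lev <- vapply(seq_len(nrow(dcond)), function(j) {
        i <- which(tr$trace$dipole == dcond$label[j])
        t0 <- tr$trace$time_ms[i]
        if (t < t0) 0.1 * 1 else if (t == t0) tr$trace$activation[i]
        else max(0.1, tr$trace$activation[i] *
                   exp(-tr$trace$decay_rate[i] * (t - t0)))
      }, numeric(1))
      sum(lev * g)
    }, numeric(1))
    expect_equal(sp[[e]]$amplitude, amp, tolerance = 1e-12)
    expect_equal(sp[[e]]$time_ms[which.max(abs(sp[[e]]$amplitude))],
                 tr$trace$time_ms[which.max(abs(amp))])
  }
  # unmapped dipole labels error
  bad <- tr
  bad$trace$dipole[1] <- "nonexistent"
  expect_error(polyspike(bad, dd), "nonexistent")
})

test_that("coarse coding", {
  cc <- coarse_code(c(-10, -5, 0, 5, 10), n_levels = 13)
  expect_equal(cc$code[5], 13)       # max maps to the top category
  expect_equal(cc$code[1], 1)
  expect_equal(cc$code[3], 7)        # zero sits in the middle category
  expect_equal(cc$value_uv[3], 0)
  expect_equal(attr(cc, "gain"), 0.6)
  # order preservation and round-trip idempotence on random patterns
  set.seed(5)
  x <- rnorm(200, sd = 3)
  c1 <- coarse_code(x, n_levels = 13)
  expect_true(all(diff(c1$code[order(x)]) >= 0))
  c2 <- code_values(c1$value_uv, c(-6, 6), 13)
  expect_equal(c2$code, c1$code)
  expect_equal(c2$value_uv, c1$value_uv)
  # clipping is recorded when not normalizing
  craw <- coarse_code(c(-20, 0, 20), normalize = FALSE)
  expect_equal(attr(craw, "n_clipped"), 2)
  expect_error(coarse_code(1:3, scale = c(2, 2)), "scale")
  expect_error(coarse_code(1:3, n_levels = 1), "n_levels")
  # spike_patterns input codes all electrodes jointly
  sp <- polyspike(run_model("target"), default_dipoles())
  cp <- coarse_code(sp)
  expect_s3_class(cp, "coded_patterns")
  tops <- unlist(lapply(cp, `[[`, "code"))
  expect_equal(max(tops), 13)
})

test_that("simulated topographic maps and the noise-free fit identity", {
  maps_t <- simulate_topomaps("target")
  expect_length(maps_t, 7)
  expect_equal(attr(maps_t[[2]], "midpoint_ms"), 150)
  for (m in maps_t) {
    expect_true(all(abs(m$value_uv) <= 6 + 1e-12))
    expect_true(all(m$code >= 1 & m$code <= 13))
  }
  # noise-free end-to-end: maps regressed against maps generated from the
  # same dipoles give R^2 = 1
  tr <- run_model("target")
  raw <- field_at_times(tr, default_dipoles(), standard_montage(),
                        (1:7 - 0.5) * 100)
  for (i in seq_len(7)) {
    ft <- topo_fit(raw[, i], maps_t[[i]]$value_uv)
    expect_equal(ft$r2, 1, tolerance = 1e-9)
  }
})
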