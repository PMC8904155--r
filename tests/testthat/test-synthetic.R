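test_that("stylized morphologies match the specified gross geometry", {
  a2 <- generate_stylized_morphology(preset_cell_spec("A2"))
  ext <- vapply(a2$paths, function(p) max(sqrt(p[, 1]^2 + p[, 2]^2)),
                numeric(1))
  expect_equal(max(ext), 160, tolerance = 1)
  expect_identical(a2$stratification, "monostratified")
  d1 <- generate_stylized_morphology(preset_cell_spec("D1"))
  terminal <- setdiff(d1$sections$id, d1$sections$parent_id)
  terminal <- terminal[d1$sections$kind[match(terminal, d1$sections$id)] ==
                         "dendrite"]
  depths <- unique(round(vapply(terminal, function(id) {
    max(d1$paths[[as.character(id)]][, 3])
  }, numeric(1)), 6))
  expect_identical(sort(depths), c(10, 30))
  expect_identical(d1$stratification, "bistratified")
})

test_that("stylized generation is deterministic in the seed", {
  m1 <- generate_stylized_morphology(preset_cell_spec("A2", seed = 7))
  m2 <- generate_stylized_morphology(preset_cell_spec("A2", seed = 7))
  m3 <- generate_stylized_morphology(preset_cell_spec("A2", seed = 8))
  expect_identical(m1, m2)
  expect_false(identical(m1$paths, m3$paths))
  expect_error(stylized_cell_spec(20, 10), "field_diameter")
})

test_that("the reduced pair is a controlled comparison", {
  pair <- reduced_pair_cached(1)
  expect_identical(pair$a2$densities["soma", ],
                   preset_densities("A2")["soma", ])
  expect_identical(pair$d1$densities["soma", ],
                   preset_densities("D1")["soma", ])
  expect_identical(nrow(discretize_cell(pair$a2, NULL)), 1L)
  expect_identical(pair$a2$passive, pair$d1$passive)
  expect_identical(pair$a2$membrane, pair$d1$membrane)
  expect_equal(pair$a2$densities["soma", "g_Ca"] /
                 pair$d1$densities["soma", "g_Ca"],
               0.137 / 0.013)
  # with an axon budget, the axon geometry is shared exactly
  full <- reduced_pair_cached(12)
  ax_a <- full$a2$morphology$sections
  ax_d <- full$d1$morphology$sections
  ax_a <- ax_a[ax_a$kind %in% c("AH", "SOCB", "NS", "DA"), -1]
  ax_d <- ax_d[ax_d$kind %in% c("AH", "SOCB", "NS", "DA"), -1]
  expect_equal(ax_a$length, ax_d$length)
  expect_equal(ax_a$diameter, ax_d$diameter)
  # the documented differences: soma diameter and dendrite length only
  soma_a <- full$a2$morphology$sections[1, ]
  soma_d <- full$d1$morphology$sections[1, ]
  expect_identical(soma_a$diameter, 20)
  expect_identical(soma_d$diameter, 12)
})

test_that("planted spikes are recovered exactly at zero noise", {
  st <- solver_settings()
  tr <- make_synthetic_trace(c(10, 30, 70), duration = 100, dt = 0.01)
  det <- detect_spikes(tr$trace, tr$time, st)
  expect_length(det, 3)
  expect_true(all(abs(det - tr$true_times) <= 3 * 0.01))
  # small noise, no spikes: no detections at the -20 mV threshold
  quiet <- make_synthetic_trace(numeric(0), duration = 100, dt = 0.01,
                                noise_sd = 2, seed = 3)
  expect_length(detect_spikes(quiet$trace, quiet$time, st), 0)
  expect_error(make_synthetic_trace(c(10, 10.5), width = 2), "closer")
  expect_error(make_synthetic_trace(500, duration = 100), "within")
})
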