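test_that("presets reproduce every printed base conductance exactly", {
  a2 <- preset_densities("A2")
  d1 <- preset_densities("D1")
  # soma/dendrite base values
  expect_identical(a2["soma", "g_Na"], 0.35)
  expect_identical(a2["dendrite", "g_Na"], 0.1)
  expect_identical(a2["soma", "g_K"], 0.12)
  expect_identical(a2["dendrite", "g_K"], 0.05)
  expect_identical(a2["soma", "g_Ca"], 0.137)
  expect_identical(a2["dendrite", "g_Ca"], 0.05)
  expect_identical(a2["soma", "g_h"], 0)
  expect_identical(a2["dendrite", "g_h"], 0)
  expect_identical(a2["soma", "g_T"], 0.004)
  expect_identical(a2["dendrite", "g_T"], 0)
  expect_identical(d1["soma", "g_Na"], 0.2)
  expect_identical(d1["dendrite", "g_Na"], 0.08)
  expect_identical(d1["soma", "g_K"], 0.211)
  expect_identical(d1["dendrite", "g_K"], 0.08)
  expect_identical(d1["soma", "g_Ca"], 0.013)
  expect_identical(d1["dendrite", "g_Ca"], 0.01)
  expect_identical(d1["soma", "g_h"], 1e-4)
  expect_identical(d1["dendrite", "g_h"], 3e-5)
  expect_identical(d1["soma", "g_T"], 0.0024)
  expect_identical(d1["dendrite", "g_T"], 0.001)
  # axon bands (shared by both presets)
  for (p in list(a2, d1)) {
    expect_identical(p[c("AH", "SOCB", "NS", "DA"), "g_Na"],
                     c(AH = 0.8, SOCB = 2.4, NS = 0.9, DA = 0.8))
    expect_identical(p[c("AH", "SOCB", "NS", "DA"), "g_K"],
                     c(AH = 0.6, SOCB = 0.8, NS = 0.6, DA = 0.6))
  }
})

test_that("derived conductances follow the preset ratio laws exactly", {
  for (nm in c("A2", "D1")) {
    d <- preset_densities(nm)
    expect_identical(d[, "g_KA"], 3 * d[, "g_K"])
    expect_identical(d[, "g_KCa"], 0.004 * d[, "g_K"])
  }
})

test_that("preset cells carry table densities and honor overrides", {
  m <- soma_only_morph(12)
  d1 <- build_preset_cell("D1", m)
  expect_identical(d1$densities["soma", "g_h"], 1e-4)
  expect_identical(d1$densities["dendrite", "g_T"], 0.001)
  big <- build_preset_cell("D1", m, overrides = list(soma_diameter = 20))
  expect_identical(big$morphology$sections$diameter[1], 20)
  expect_identical(big$densities, d1$densities)
  expect_error(build_preset_cell("X9", m), "arg")
  expect_error(build_preset_cell("D1", m,
                                 overrides = list(densities = list(beak = list(g_K = 1)))),
               "unknown region")
  expect_error(build_preset_cell("D1", m,
                                 overrides = list(densities = list(soma = list(g_Q = 1)))),
               "unknown channel")
  expect_error(build_preset_cell("D1", m, overrides = list(bogus = 1)),
               "unknown override")
})

test_that("attach_axon appends the four bands in order with exact path length", {
  m <- soma_only_morph(20)
  ax <- attach_axon(m)
  s <- ax$sections
  expect_identical(s$kind, c("soma", "AH", "SOCB", "NS", "DA"))
  expect_identical(s$parent_id[-1], s$id[-nrow(s)])
  # path length from the soma surface to the distal axon tip
  tip <- ax$paths[[as.character(s$id[5])]]
  start <- ax$paths[[as.character(s$id[2])]]
  total <- tip[nrow(tip), 1] - start[1, 1]
  expect_equal(total, sum(default_axon_bands()$length), tolerance = 1e-9)
  expect_error(attach_axon(ax), "already has axon")
  bad <- default_axon_bands()
  bad$length[4] <- 0
  expect_error(attach_axon(m, bad), "length")
})

test_that("morphology invariants are enforced", {
  secs <- data.frame(id = 1:2, parent_id = c(NA, 1),
                     kind = c("soma", "dendrite"), length = c(20, 50),
                     diameter = c(20, 1), n_segments = NA_integer_)
  expect_s3_class(morphology(secs), "rgc_morphology")
  bad <- secs; bad$length[2] <- -1
  expect_error(morphology(bad), "length")
  two_roots <- secs; two_roots$parent_id <- c(NA, NA)
  expect_error(morphology(two_roots), "exactly one root")
  cyc <- data.frame(id = 1:3, parent_id = c(NA, 3, 2),
                    kind = c("soma", "dendrite", "dendrite"),
                    length = 10, diameter = 1, n_segments = NA_integer_)
  expect_error(morphology(cyc))
  # DA must be terminal
  da_child <- data.frame(id = 1:6, parent_id = c(NA, 1, 2, 3, 4, 5),
                         kind = c("soma", "AH", "SOCB", "NS", "DA", "DA"),
                         length = 10, diameter = 1, n_segments = NA_integer_)
  expect_error(morphology(da_child), "terminal")
  # bands must follow soma -> AH -> SOCB -> NS -> DA
  skip_band <- data.frame(id = 1:2, parent_id = c(NA, 1),
                          kind = c("soma", "SOCB"), length = 10,
                          diameter = 1, n_segments = NA_integer_)
  expect_error(morphology(skip_band), "order")
})
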