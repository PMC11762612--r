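test_that("stiffness catalogue reproduces the published values", {
  shi <- stiffness_catalog("shi")
  expect_equal(shi$k_low[shi$name == "ISL"], 2800)
  expect_equal(shi$k_low[shi$name == "ASL"], 700)
  expect_equal(shi$k_low[shi$name == "LPSL"], 1000)
  expect_true(all(shi$k_low == shi$k_high))
  yao <- stiffness_catalog("yao")
  expect_equal(yao$k_low[yao$name == "SS"], 12.6)
  expect_equal(yao$k_low[yao$name == "IP"], 12.0)
  dft <- stiffness_catalog()
  expect_identical(attr(dft, "source"), "eichenseer_shi")
  expect_equal(dft[dft$name == "ASL", c("k_low", "k_high")],
               data.frame(k_low = 39, k_high = 103),
               ignore_attr = TRUE)
  expect_equal(dft[dft$name == "SP", c("k_low", "k_high")],
               data.frame(k_low = 500, k_high = 500), ignore_attr = TRUE)
  expect_identical(nrow(dft), 8L)
})

test_that("springs attach one per ligament side with catalogue stiffness", {
  ph <- default_phantom()
  spr <- make_springs(ph$mesh, stiffness_catalog("shi"))
  expect_identical(nrow(spr), 14L)   # 6 bilateral x 2 + SP + IP
  expect_equal(spr$k_low[spr$name == "ISL_left"], 2800)
  expect_equal(spr$k_low[spr$name == "SS_right"],
               stiffness_catalog("shi")$k_low[5])
  expect_true(all(spr$rest_length > 0))
  expect_true(all(spr$tension_only))
  # bundles split the stiffness evenly
  spr2 <- make_springs(ph$mesh, stiffness_catalog("shi"), bundle = 2)
  expect_identical(nrow(spr2), 28L)
  expect_equal(sum(spr2$k_low[grepl("^ISL_left", spr2$name)]), 2800)
  # a missing attachment patch names the ligament
  broken <- ph$mesh
  broken$patches$lig_ASL_left_sacrum <- NULL
  expect_error(make_springs(broken), "ASL")
})

test_that("spring force law is tension-only, zero at rest and continuous", {
  s <- list(rest_length = 10, k_low = 700, k_high = 700,
            breakpoint_strain = NA_real_, tension_only = TRUE)
  expect_equal(spring_force(s, 10), 0)
  expect_equal(spring_force(s, 10.1), 70)
  expect_equal(spring_force(s, 9.5), 0)
  expect_equal(spring_force(s, 1e-6), 0)
  # elongation-defined law: secant stiffness k_low -> k_high over the
  # breakpoint strain, constant beyond
  e <- list(rest_length = 100, k_low = 39, k_high = 103,
            breakpoint_strain = 0.1, tension_only = TRUE)
  expect_equal(spring_force(e, 100), 0)
  expect_equal(spring_force(e, 105), (39 + (103 - 39) * 0.5) * 5)
  expect_equal(spring_force(e, 110), 103 * 10)
  expect_equal(spring_force(e, 120), 103 * 20)
  # continuity across the breakpoint
  expect_equal(spring_force(e, 110 - 1e-9), spring_force(e, 110 + 1e-9),
               tolerance = 1e-6)
  # force is non-negative over a sweep of lengths
  L <- seq(50, 150, by = 0.5)
  expect_true(all(vapply(L, function(l) spring_force(e, l), numeric(1)) >= 0))
})
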