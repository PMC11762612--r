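test_that("HU to density mapping matches the linear relation with cap", {
  expect_equal(hu_to_density(0), 1.0)
  expect_equal(hu_to_density(2000), 1.64724)
  # beyond the segmentation window the density cap takes over:
  # 0.00032362*3000 + 1 = 1.97086 > 1.8
  expect_equal(hu_to_density(3000), 1.8)
  expect_error(hu_to_density(NaN), "non-finite")
})

test_that("density to modulus follows the power law with clamping", {
  expect_equal(density_to_modulus(1.0), 1958.6)
  # frozen from an independent high-precision evaluation of
  # 1958.6 * 1.64724^2.33
  expect_equal(density_to_modulus(1.64724), 6265.98397620635,
               tolerance = 1e-10)
  # 1958.6 * 1.8^2.33 = 7704.26 exceeds the elderly-bone range -> clamp
  expect_equal(density_to_modulus(1.8), 6530)
  # low densities clamp at the floor
  expect_equal(density_to_modulus(0.1), 200)
  expect_error(density_to_modulus(-1), "positive")
  expect_error(density_to_modulus(0), "positive")
})

test_that("mapping is monotone and clamping idempotent", {
  hu <- sort(stats::runif(200, -500, 4000))
  rho <- hu_to_density(hu)
  expect_true(all(diff(rho) >= 0))
  E <- density_to_modulus(rho)
  expect_true(all(diff(E) >= 0))
  expect_identical(hu_to_density(hu_to_density(hu) * 0 + hu), rho)
  expect_identical(density_to_modulus(rho), pmin(pmax(E, 200), 6530))
})

test_that("material binning yields the documented catalogue and bin bound", {
  cst <- mapping_constants()
  expect_equal((cst$E_max - cst$E_min) / cst$bin_width, 1266)
  ph <- default_phantom()
  mf <- assign_materials(ph$mesh, ph$hu)
  expect_identical(attr(mf, "n_bins_available"), 1266)
  bone <- ph$mesh$region %in% bone_regions()
  expect_true(all(is.finite(mf$E[bone])))
  expect_true(all(is.na(mf$E[!bone])))
  expect_true(all(abs(mf$E[bone] - mf$E_exact[bone]) <= cst$bin_width / 2 + 1e-12))
  # same bin id -> identical binned modulus
  sp <- split(mf$E[bone], mf$bin_id[bone])
  expect_true(all(vapply(sp, function(x) diff(range(x)) == 0, logical(1))))
})

test_that("uniform HU input collapses to a single material bin", {
  ph <- default_phantom()
  hu0 <- ph$hu
  bone <- ph$mesh$region %in% bone_regions()
  hu0$hu[bone] <- 0
  mf <- assign_materials(ph$mesh, hu0)
  expect_identical(length(unique(mf$bin_id[bone])), 1L)
  expect_equal(unique(mf$E[bone]),
               200 + (unique(mf$bin_id[bone]) - 0.5) * 5)
  expect_lt(abs(unique(mf$E[bone]) - 1958.6), 2.5)
})

test_that("material assignment is order-independent and flags missing HU", {
  ph <- default_phantom()
  mf1 <- assign_materials(ph$mesh, ph$hu)
  shuf <- ph$hu[sample.int(nrow(ph$hu)), ]
  mf2 <- assign_materials(ph$mesh, shuf)
  expect_identical(mf1$E, mf2$E)
  miss <- ph$hu
  bone_el <- which(ph$mesh$region %in% bone_regions())
  miss$hu[bone_el[1:3]] <- NA
  expect_error(assign_materials(ph$mesh, miss), "missing HU for 3")
})

test_that("full material field covers soft tissue and implants", {
  ph <- default_phantom()
  cut <- cut_ffp2c(ph$mesh, "right")
  m <- place_screws(cut, fixation_construct("TSI", "right"))
  mf <- build_material_field(m, ph$hu)
  expect_true(all(is.finite(mf$E)))
  expect_equal(unique(mf$E[m$region == "symphysis"]), 50)
  expect_equal(unique(mf$nu[m$region == "cartilage_si_left"]), 0.45)
  expect_equal(unique(mf$E[m$region == "screw_tsi"]), 110000)
})
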