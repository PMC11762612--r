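test_that("load cases encode the published magnitudes and supports", {
  v <- make_load_case("validation_superior")
  expect_equal(v$magnitude, 294)
  expect_equal(v$direction, c(0, 0, 1))
  expect_setequal(v$fixed_patches, c("acetabulum_left", "acetabulum_right"))
  b <- make_load_case("bipedal")
  expect_equal(b$magnitude, 2048)
  expect_equal(b$per_side, 1024)
  expect_equal(b$per_side, b$magnitude / 2)
  r <- make_load_case("right_one_leg")
  expect_false("acetabulum_left" %in% r$fixed_patches)
  expect_true("acetabulum_right" %in% r$fixed_patches)
  expect_equal(r$magnitude, 2048)
  expect_error(make_load_case("moonwalk"), "unknown load case")
  # the nodal load vector integrates to the case magnitude
  ph <- default_phantom()
  f <- load_vector(ph$mesh, b)
  expect_equal(sum(f), -2048)
})

test_that("fracture gap is the projected mean relative face displacement", {
  ph <- default_phantom()
  cut <- cut_ffp2c(ph$mesh, "right")
  pr <- cut$fracture_pairs$posterior
  u0 <- matrix(0, nrow(cut$nodes), 3)
  expect_equal(fracture_gap(list(u = u0, mesh = cut), pr), 0)
  # rigid 1 mm translation of the lateral fragment along the axis
  u1 <- u0; u1[pr$node_b, 1] <- 1
  expect_equal(fracture_gap(list(u = u1, mesh = cut), pr), 1.0)
  # translation perpendicular to the measurement axis projects to zero
  u2 <- u0; u2[pr$node_b, 3] <- 1
  expect_equal(fracture_gap(list(u = u2, mesh = cut), pr), 0)
  # band restriction selects nodes by height
  zr <- range(cut$nodes[pr$node_a, 3])
  u3 <- u0; u3[pr$node_b[cut$nodes[pr$node_a, 3] > mean(zr)], 1] <- 2
  expect_equal(fracture_gap(list(u = u3, mesh = cut), pr,
                            band = c(zr[2], zr[2])), 2)
  expect_equal(fracture_gap(list(u = u3, mesh = cut), pr,
                            band = c(zr[1], zr[1])), 0)
  bad <- pr; bad$node_b <- bad$node_b[-1]
  expect_error(fracture_gap(list(u = u0, mesh = cut), bad), "unpaired")
})

test_that("regional stress takes the signed extremum with exclusions", {
  ph <- default_phantom()
  mesh <- ph$mesh
  m <- nrow(mesh$tets)
  zero <- data.frame(sxx = numeric(m), syy = numeric(m), szz = numeric(m),
                     sxy = numeric(m), syz = numeric(m), szx = numeric(m))
  sol <- list(u = matrix(0, nrow(mesh$nodes), 3), mesh = mesh, stress = zero)
  expect_equal(as.numeric(regional_stress(sol, "sacrum_S1_left")), 0)
  # uniform uniaxial field reports the field value
  s5 <- zero; s5$sxx <- 5
  sol$stress <- s5
  expect_equal(as.numeric(regional_stress(sol, "sacrum_S1_left")), 5)
  # mixed signs: largest magnitude wins, sign preserved
  el <- which(mesh$region == "sacrum_S1_left")
  smix <- zero
  smix$sxx[el[1]] <- -3
  smix$sxx[el[2]] <- 2
  sol$stress <- smix
  expect_equal(as.numeric(regional_stress(sol, "sacrum_S1_left",
                                          exclude_patches = character(0))),
               -3)
  expect_error(regional_stress(sol, "femur"), "empty")
})

test_that("intact symmetric phantom loads both sides equally", {
  ph <- noiseless_phantom()
  mat <- build_material_field(ph$mesh, ph$hu)
  spr <- make_springs(ph$mesh)
  sol <- run_load_case(ph$mesh, mat, "bipedal", spr)
  for (lev in c("S1", "S2")) {
    sl <- as.numeric(regional_stress(sol, paste0("sacrum_", lev, "_left")))
    sr <- as.numeric(regional_stress(sol, paste0("sacrum_", lev, "_right")))
    expect_equal(abs(sl), abs(sr), tolerance = 0.01)
  }
  # reactions split evenly between the two acetabula
  comp_z <- sol$reactions$force[(sol$reactions$dof - 1) %% 3 + 1 == 3]
  expect_equal(sum(comp_z), 2048, tolerance = 1e-6 * 2048)
})

test_that("convergence protocol reports changes and gates on the threshold", {
  # identical meshes: zero change, accepted
  cv0 <- convergence_study(edge_lengths = c(5, 5))
  expect_equal(cv0$change_tension[2], 0)
  expect_equal(cv0$change_compression[2], 0)
  expect_true(attr(cv0, "accepted"))
  expect_error(convergence_study(edge_lengths = 5), "at least two")
  expect_error(convergence_study(edge_lengths = c(3, 5)), "descending")
})

test_that("construct comparison is deterministic row for row", {
  cmp <- default_comparison()
  expect_identical(dim(cmp$gaps), c(6L, 5L))
  expect_identical(dim(cmp$stresses), c(12L, 5L))
  # re-running one variant/case reproduces the report bit for bit
  cmp2 <- compare_constructs(variants = "USI", cases = "bipedal")
  expect_identical(
    cmp2$gaps$USI,
    cmp$gaps$USI[cmp$gaps$load_case == "Bipedal stance"])
})
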