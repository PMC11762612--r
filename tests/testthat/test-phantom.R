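test_that("noiseless phantom is mirror-symmetric about the mid-sagittal plane", {
  ph <- noiseless_phantom()
  nd <- ph$mesh$nodes
  refl <- nd
  refl[, 1] <- -refl[, 1]
  a <- nd[order(nd[, 1], nd[, 2], nd[, 3]), ]
  b <- refl[order(refl[, 1], refl[, 2], refl[, 3]), ]
  expect_lt(max(abs(a - b)), 1e-9)
  # region volumes mirror exactly
  v <- tet_volumes(ph$mesh$nodes, ph$mesh$tets)
  vol <- tapply(v, ph$mesh$region, sum)
  for (r in c("ilium", "cartilage_si", "sacrum_S1", "sacrum_S2",
              "ramus_sup", "ramus_inf", "pubis")) {
    expect_equal(unname(vol[paste0(r, "_left")]),
                 unname(vol[paste0(r, "_right")]), tolerance = 1e-12)
  }
  # mirror symmetry extends to the noiseless HU field
  expect_true(all(is.finite(ph$hu$hu[ph$mesh$region %in% bone_regions()])))
})

test_that("phantom carries all named regions and surface patches, non-empty", {
  ph <- default_phantom()
  expect_setequal(unique(ph$mesh$region), c(bone_regions(), soft_regions()))
  expect_gte(length(unique(ph$mesh$region)), 15)
  expect_gte(length(ph$mesh$patches), 5)
  expect_true(all(lengths(ph$mesh$patches) > 0))
  # one ligament patch per end per side for the six bilateral groups + SP/IP
  lig <- grep("^lig_", names(ph$mesh$patches), value = TRUE)
  expect_length(lig, 6 * 2 * 2 + 4)
  # HU values clamped to the segmentation window
  hu <- ph$hu$hu[!is.na(ph$hu$hu)]
  expect_true(all(hu >= 220 & hu <= 2000))
})

test_that("phantom generation is deterministic for a fixed seed", {
  p <- phantom_params(rng_seed = 99)
  a <- build_phantom(p)
  b <- build_phantom(p)
  expect_identical(a$mesh$nodes, b$mesh$nodes)
  expect_identical(a$mesh$tets, b$mesh$tets)
  expect_identical(a$hu, b$hu)
  # different seed changes only the HU noise, not the geometry
  c3 <- build_phantom(phantom_params(rng_seed = 100))
  expect_identical(a$mesh$nodes, c3$mesh$nodes)
  expect_false(identical(a$hu$hu, c3$hu$hu))
})

test_that("phantom parameters are validated", {
  expect_error(phantom_params(sacrum_width = -1), "must be > 0")
  expect_error(phantom_params(target_edge_length = 0.5), "\\[1, 5\\]")
  expect_error(phantom_params(target_edge_length = 6), "\\[1, 5\\]")
  expect_error(phantom_params(si_wedge = 30), "si_wedge")
})

test_that("FFP IIc cut duplicates exactly the interface nodes and conserves volume", {
  ph <- default_phantom()
  cut <- cut_ffp2c(ph$mesh, "right")
  expect_length(cut$fracture_pairs, 3L)
  expect_setequal(names(cut$fracture_pairs),
                  c("posterior", "anterior_sup", "anterior_inf"))
  # derived oracle: count interface nodes on the intact mesh from the
  # registered plane positions
  k_expected <- 0L
  cen <- element_centroids(ph$mesh)
  for (fp in cut$fracture_pairs) {
    regions <- switch(fp$site,
      posterior = c("sacrum_S1_right", "sacrum_S2_right"),
      anterior_sup = "ramus_sup_right",
      anterior_inf = "ramus_inf_right")
    el <- which(ph$mesh$region %in% regions)
    tn <- unique(as.vector(ph$mesh$tets[el, ]))
    on_pl <- tn[abs(ph$mesh$nodes[tn, 1] - fp$plane_x) < 1e-9]
    med <- el[cen[el, 1] < fp$plane_x]
    lat <- el[cen[el, 1] > fp$plane_x]
    shared <- intersect(intersect(unique(as.vector(ph$mesh$tets[med, ])),
                                  unique(as.vector(ph$mesh$tets[lat, ]))),
                        on_pl)
    k_expected <- k_expected + length(shared)
  }
  expect_identical(nrow(cut$nodes), nrow(ph$mesh$nodes) + k_expected)
  expect_identical(nrow(cut$tets), nrow(ph$mesh$tets))
  expect_equal(sum(tet_volumes(cut$nodes, cut$tets)),
               sum(tet_volumes(ph$mesh$nodes, ph$mesh$tets)),
               tolerance = 1e-12)
  # pairs are bijections of duplicated nodes at identical coordinates
  for (fp in cut$fracture_pairs) {
    expect_identical(length(fp$node_a), length(fp$node_b))
    expect_equal(cut$nodes[fp$node_a, ], cut$nodes[fp$node_b, ],
                 ignore_attr = TRUE)
  }
})

test_that("left and right injuries produce mirror-equivalent cuts", {
  ph <- noiseless_phantom()
  cl <- cut_ffp2c(ph$mesh, "left")
  cr <- cut_ffp2c(ph$mesh, "right")
  expect_identical(nrow(cl$nodes), nrow(cr$nodes))
  expect_identical(sort(vapply(cl$fracture_pairs, function(p)
    length(p$node_a), integer(1))),
    sort(vapply(cr$fracture_pairs, function(p) length(p$node_a), integer(1))))
  expect_equal(cl$fracture_pairs$posterior$plane_x,
               -cr$fracture_pairs$posterior$plane_x)
})

test_that("cut mesh under zero load shows zero gap at all three sites", {
  ph <- default_phantom()
  cut <- cut_ffp2c(ph$mesh, "right")
  mat <- build_material_field(cut, ph$hu)
  fixed <- c(cut$patches$acetabulum_left, cut$patches$acetabulum_right)
  sol <- fem_solve(fem_assemble(cut, mat, fixed_nodes = fixed,
                                load = numeric(3 * nrow(cut$nodes))))
  for (site in names(cut$fracture_pairs)) {
    expect_equal(fracture_gap(sol, site), 0)
  }
})

test_that("screw constructs intersect the required regions", {
  ph <- default_phantom()
  cut <- cut_ffp2c(ph$mesh, "right")
  tsi <- place_screws(cut, fixation_construct("TSI", "right"))
  tn <- region_nodes(tsi, "screw_tsi")
  touches <- function(mesh, nodes, region) {
    el <- which(mesh$region == region)
    any(mesh$tets[el, ] %in% nodes)
  }
  for (r in c("sacrum_S1_left", "sacrum_S1_right", "ilium_left",
              "ilium_right")) {
    expect_true(touches(tsi, tn, r), label = paste("TSI touches", r))
  }
  bsi <- place_screws(cut, fixation_construct("BSI", "right"))
  scr <- grep("^screw_bsi", unique(bsi$region), value = TRUE)
  expect_length(scr, 2L)
  dirs <- lapply(pelvifem:::construct_screws(cut,
    fixation_construct("BSI", "right")), `[[`, "dir")
  ang <- acos(abs(sum(dirs[[1]] * dirs[[2]])))
  expect_gt(ang, 0)
  # separate implants never share mesh nodes
  expect_length(intersect(region_nodes(bsi, scr[1]),
                          region_nodes(bsi, scr[2])), 0L)
  # unilateral screw on a left-injured phantom stays off the right ilium
  cl <- cut_ffp2c(ph$mesh, "left")
  usi <- place_screws(cl, fixation_construct("USI", "left"))
  un <- region_nodes(usi, "screw_usi")
  expect_true(touches(usi, un, "ilium_left"))
  expect_true(touches(usi, un, "sacrum_S1_left"))
  expect_false(touches(usi, un, "ilium_right"))
})

test_that("screw placement changes only labels, ties and patches", {
  ph <- default_phantom()
  cut <- cut_ffp2c(ph$mesh, "right")
  m <- place_screws(cut, fixation_construct("USI", "right"))
  expect_identical(m$nodes, cut$nodes)
  expect_identical(m$tets, cut$tets)
  expect_gt(nrow(m$ties), 0)
  expect_true(all(m$ties$slave %in% cut$fracture_pairs$posterior$node_b))
  # the bridging screw crosses the posterior plane
  cx <- element_centroids(m)[m$region == "screw_usi", 1]
  px <- m$fracture_pairs$posterior$plane_x
  expect_true(any(cx < px) && any(cx > px))
})
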