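#' Parameters of the synthetic pelvis phantom
#'
#' The phantom is a simplified, mirror-symmetric pelvic ring: a sacrum block
#' joined to two innominate (ilium) blocks through sacroiliac cartilage
#' layers, closed anteriorly by superior and inferior pubic rami bars, pubic
#' bodies and a symphysis block. It preserves the mechanically relevant
#' topology of the pelvic ring — two load paths from the first sacral body to
#' the acetabula, compliant SI joints and symphysis — without anatomical
#' surface detail. All dimensions in millimetres.
#'
#' @param sacrum_width,sacrum_depth,sacrum_height sacrum block extents; the
#'   upper half is the S1 level, the lower half S2.
#' @param ilium_width lateral extent of each innominate block (depth and
#'   height follow the sacrum).
#' @param cartilage_thickness thickness of each SI cartilage layer.
#' @param ramus_section square cross-section of the pubic ramus bars.
#' @param pubis_width lateral extent of each pubic body block.
#' @param symphysis_width lateral extent of the midline symphysis block.
#' @param anterior_reach anterior extent of the ring in front of the sacrum.
#' @param si_wedge superior-inferior taper of the sacral half-width (mm):
#'   the sacrum is this much narrower at its inferior end than at the S1
#'   endplate, so the stepped sacroiliac joints are aggregately oblique and
#'   vertical load wedges the sacrum between the iliac wings (nutcracker
#'   load transfer). 0 gives parallel vertical joints.
#' @param hu_cortical,hu_trabecular Hounsfield units assigned to surface
#'   (cortical shell) and interior (trabecular) bone voxels before noise.
#' @param hu_noise_sd standard deviation of Gaussian HU noise per voxel
#'   (emulates CT heterogeneity); 0 gives an exactly symmetric field.
#' @param rng_seed integer seed governing only the HU noise.
#' @param target_edge_length voxel lattice edge length in \[1, 5\] mm, the
#'   converged tetrahedron size range.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(sacrum_width = 50, sacrum_depth = 30,
                           sacrum_height = 50, ilium_width = 30,
                           cartilage_thickness = 5, ramus_section = 15,
                           pubis_width = 10, symphysis_width = 10,
                           anterior_reach = 45, si_wedge = 10,
                           hu_cortical = 1400, hu_trabecular = 400,
                           hu_noise_sd = 50, rng_seed = 1L,
                           target_edge_length = 5) {
  p <- list(sacrum_width = sacrum_width, sacrum_depth = sacrum_depth,
            sacrum_height = sacrum_height, ilium_width = ilium_width,
            cartilage_thickness = cartilage_thickness,
            ramus_section = ramus_section, pubis_width = pubis_width,
            symphysis_width = symphysis_width, anterior_reach = anterior_reach,
            si_wedge = si_wedge,
            hu_cortical = hu_cortical, hu_trabecular = hu_trabecular,
            hu_noise_sd = hu_noise_sd, rng_seed = as.integer(rng_seed),
            target_edge_length = target_edge_length)
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

#' @rdname phantom_params
#' @param params a `phantom_params` object.
#' @export
validate_phantom_params <- function(params) {
  dims <- c("sacrum_width", "sacrum_depth", "sacrum_height", "ilium_width",
            "cartilage_thickness", "ramus_section", "pubis_width",
            "symphysis_width", "anterior_reach")
  for (d in dims) {
    if (!is.numeric(params[[d]]) || params[[d]] <= 0)
      stop(sprintf("phantom dimension '%s' must be > 0", d))
  }
  if (params$target_edge_length < 1 || params$target_edge_length > 5)
    stop("target_edge_length must lie in [1, 5] mm")
  if (params$hu_noise_sd < 0) stop("hu_noise_sd must be >= 0")
  if (params$si_wedge < 0 || params$si_wedge >= params$sacrum_width / 2)
    stop("si_wedge must lie in [0, sacrum_width/2)")
  invisible(params)
}

# Box layout of the phantom in the anatomical frame.  The sacrum is wider
# superiorly (si_wedge): the sacroiliac joint is a stepped, aggregately
# oblique compliant layer, so vertical settling of the sacrum between the
# iliac wings generates lateral thrust on the wings — the nutcracker load
# transfer of the pelvic ring.
phantom_boxes <- function(p) {
  xs <- p$sacrum_width / 2
  xc <- xs + p$cartilage_thickness
  xi <- xc + p$ilium_width
  xleg <- xc + p$ilium_width / 2          # medial face of leg1 bars
  xp0 <- p$symphysis_width / 2
  xp1 <- xp0 + p$pubis_width
  h <- p$sacrum_height
  ys0 <- -p$sacrum_depth; ys1 <- 0
  ya1 <- p$anterior_reach
  ya0 <- ya1 - p$ramus_section
  zs <- c(0.6 * h, 0.6 * h + p$ramus_section)   # superior ramus band
  zi <- c(0.1 * h, 0.1 * h + p$ramus_section)   # inferior ramus band
  zp <- c(zi[1L], zs[2L])
  side <- function(region, x0, x1, y0, y1, z0, z1) {
    rbind(data.frame(region = paste0(region, "_left"), x0 = -x1, x1 = -x0,
                     y0 = y0, y1 = y1, z0 = z0, z1 = z1),
          data.frame(region = paste0(region, "_right"), x0 = x0, x1 = x1,
                     y0 = y0, y1 = y1, z0 = z0, z1 = z1))
  }
  nsl <- 5L                                # wedge steps over the height
  slab <- h / nsl
  wedge_rows <- do.call(rbind, lapply(seq_len(nsl) - 1L, function(k) {
    xs_k <- xs - p$si_wedge * (1 - k / (nsl - 1))
    z0 <- k * slab; z1 <- z0 + slab
    zmid <- h / 2
    sac <- if (z0 >= zmid - 1e-9) {
      side("sacrum_S1", 0, xs_k, ys0, ys1, z0, z1)
    } else if (z1 <= zmid + 1e-9) {
      side("sacrum_S2", 0, xs_k, ys0, ys1, z0, z1)
    } else {
      rbind(side("sacrum_S2", 0, xs_k, ys0, ys1, z0, zmid),
            side("sacrum_S1", 0, xs_k, ys0, ys1, zmid, z1))
    }
    rbind(sac,
          side("cartilage_si", xs_k, xs_k + p$cartilage_thickness,
               ys0, ys1, z0, z1),
          side("ilium", xs_k + p$cartilage_thickness, xi, ys0, ys1, z0, z1))
  }))
  rbind(
    wedge_rows,
    side("ramus_sup", xleg, xi, ys1, ya1, zs[1L], zs[2L]),
    side("ramus_sup", xp1, xleg, ya0, ya1, zs[1L], zs[2L]),
    side("ramus_inf", xleg, xi, ys1, ya1, zi[1L], zi[2L]),
    side("ramus_inf", xp1, xleg, ya0, ya1, zi[1L], zi[2L]),
    side("pubis", xp0, xp1, ya0, ya1, zp[1L], zp[2L]),
    data.frame(region = "symphysis", x0 = -xp0, x1 = xp0, y0 = ya0, y1 = ya1,
               z0 = zp[1L], z1 = zp[2L])
  )
}

#' Bone region labels of the phantom
#' @return character vector of the bony (HU-mapped) region labels.
#' @export
bone_regions <- function() {
  c("sacrum_S1_left", "sacrum_S1_right", "sacrum_S2_left", "sacrum_S2_right",
    "ilium_left", "ilium_right",
    "ramus_sup_left", "ramus_sup_right", "ramus_inf_left", "ramus_inf_right",
    "pubis_left", "pubis_right")
}

#' Soft-tissue region labels of the phantom
#' @return character vector of the cartilage/symphysis region labels.
#' @export
soft_regions <- function() {
  c("cartilage_si_left", "cartilage_si_right", "symphysis")
}

# Named anchor points of the ligament attachment patches.  Each bilateral
# ligament has a sacral (or medial) and an iliac (or lateral) anchor; SP/IP
# run across the symphysis between the two pubic bodies.
ligament_anchor_table <- function(p) {
  xs <- p$sacrum_width / 2
  xc <- xs + p$cartilage_thickness
  h <- p$sacrum_height
  ys0 <- -p$sacrum_depth
  ya1 <- p$anterior_reach
  xp0 <- p$symphysis_width / 2
  zp_top <- 0.6 * h + p$ramus_section
  zp_bot <- 0.1 * h
  a <- rbind(
    data.frame(lig = "ASL",  end = "sacrum", x = xs - 1,  y = -1,       z = 0.7 * h,  region = "sacrum"),
    data.frame(lig = "ASL",  end = "ilium",  x = xc + 1,  y = -1,       z = 0.7 * h,  region = "ilium"),
    data.frame(lig = "SPSL", end = "sacrum", x = xs - 1,  y = ys0 + 1,  z = 0.8 * h,  region = "sacrum"),
    data.frame(lig = "SPSL", end = "ilium",  x = xc + 1,  y = ys0 + 1,  z = 0.8 * h,  region = "ilium"),
    data.frame(lig = "LPSL", end = "sacrum", x = 0.4 * xs, y = ys0 + 1, z = 0.2 * h,  region = "sacrum"),
    data.frame(lig = "LPSL", end = "ilium",  x = xc + 5,  y = ys0 + 1,  z = 0.7 * h,  region = "ilium"),
    data.frame(lig = "ISL",  end = "sacrum", x = xs - 1,  y = -p$sacrum_depth / 2, z = h - 2, region = "sacrum"),
    data.frame(lig = "ISL",  end = "ilium",  x = xc + 1,  y = -p$sacrum_depth / 2, z = h - 2, region = "ilium"),
    data.frame(lig = "SS",   end = "sacrum", x = 0.8 * xs, y = -5,      z = 2,        region = "sacrum"),
    data.frame(lig = "SS",   end = "ilium",  x = xc + 12, y = -5,       z = 2,        region = "ilium"),
    data.frame(lig = "ST",   end = "sacrum", x = 0.75 * xs, y = ys0 + 3, z = 2,       region = "sacrum"),
    data.frame(lig = "ST",   end = "ilium",  x = xc + 18, y = ys0 + 3,  z = 2,        region = "ilium")
  )
  mid <- rbind(
    data.frame(lig = "SP", end = "left",  x = -(xp0 + 2), y = ya1 - 5, z = zp_top - 2, region = "pubis_left"),
    data.frame(lig = "SP", end = "right", x = xp0 + 2,    y = ya1 - 5, z = zp_top - 2, region = "pubis_right"),
    data.frame(lig = "IP", end = "left",  x = -(xp0 + 2), y = ya1 - 7, z = zp_bot + 2, region = "pubis_left"),
    data.frame(lig = "IP", end = "right", x = xp0 + 2,    y = ya1 - 7, z = zp_bot + 2, region = "pubis_right")
  )
  list(bilateral = a, midline = mid)
}

# k nearest nodes (by index order on ties) of a region node set to a point
nearest_region_nodes <- function(mesh, regions, pt, k = 4L) {
  cand <- region_nodes(mesh, regions)
  d <- sqrt(colSums((t(mesh$nodes[cand, , drop = FALSE]) - pt)^2))
  cand[order(d, cand)][seq_len(min(k, length(cand)))]
}

#' Build the parametric pelvis phantom
#'
#' Rasterises the phantom geometry onto a voxel lattice, splits it into
#' tetrahedra, attaches a synthetic Hounsfield-unit field (cortical shell +
#' trabecular interior + optional Gaussian noise, clamped to \[220, 2000\] HU)
#' and registers the surface patches: both acetabula, the S1 endplate and all
#' ligament attachment sites. The mesh is mirror-symmetric about the
#' mid-sagittal plane; with `hu_noise_sd = 0` the HU field is too. The seed
#' governs only HU noise; geometry is deterministic.
#'
#' @param params a [phantom_params] object.
#' @return list with elements `mesh` (a [tet_mesh]) and `hu` (data.frame
#'   `element`, `hu`; `NA` for cartilage/symphysis elements, which are not
#'   HU-mapped).
#' @export
build_phantom <- function(params = phantom_params()) {
  validate_phantom_params(params)
  boxes <- phantom_boxes(params)
  mesh <- tryCatch(lattice_mesh(boxes, params$target_edge_length),
                   error = function(e)
                     stop(sprintf("meshing failure for phantom solids: %s",
                                  conditionMessage(e))))
  vox <- attr(mesh, "voxel")
  present <- unique(mesh$region)
  missing <- setdiff(c(bone_regions(), soft_regions()), present)
  if (length(missing))
    stop(sprintf("meshing failure: empty solids %s (degenerate geometry?)",
                 paste(missing, collapse = ", ")))

  # --- synthetic HU field (per voxel, replicated to its 6 tets) ---
  occ <- array(FALSE, dim = c(max(vox$i), max(vox$j), max(vox$k)))
  occ[cbind(vox$i, vox$j, vox$k)] <- TRUE
  nb <- function(di, dj, dk) {
    ii <- vox$i + di; jj <- vox$j + dj; kk <- vox$k + dk
    ok <- ii >= 1L & ii <= dim(occ)[1L] & jj >= 1L & jj <= dim(occ)[2L] &
      kk >= 1L & kk <= dim(occ)[3L]
    out <- rep(FALSE, nrow(vox))
    out[ok] <- occ[cbind(ii[ok], jj[ok], kk[ok])]
    out
  }
  interior <- nb(1,0,0) & nb(-1,0,0) & nb(0,1,0) & nb(0,-1,0) &
    nb(0,0,1) & nb(0,0,-1)
  hu_vox <- ifelse(interior, params$hu_trabecular, params$hu_cortical)
  if (params$hu_noise_sd > 0) {
    hu_vox <- hu_vox + with_local_seed(params$rng_seed,
      stats::rnorm(length(hu_vox), 0, params$hu_noise_sd))
  }
  hu_vox <- pmin(pmax(hu_vox, 220), 2000)
  hu_elem <- rep(hu_vox, each = 6L)
  hu_elem[!(mesh$region %in% bone_regions())] <- NA_real_

  # --- surface patches ---
  nd <- mesh$nodes
  tol <- 1e-9
  xs <- params$sacrum_width / 2
  xc <- xs + params$cartilage_thickness
  h0 <- params$sacrum_height
  il_l <- region_nodes(mesh, "ilium_left")
  il_r <- region_nodes(mesh, "ilium_right")
  ace_window <- function(side_nodes, sgn) {
    xlo <- xc + 0.2 * params$ilium_width
    xhi <- xc + 0.85 * params$ilium_width
    sel <- side_nodes[abs(nd[side_nodes, 3L]) < tol &
                        sgn * nd[side_nodes, 1L] >= xlo &
                        sgn * nd[side_nodes, 1L] <= xhi &
                        nd[side_nodes, 2L] >= -params$sacrum_depth + 2 &
                        nd[side_nodes, 2L] <= -2]
    sel
  }
  sac <- region_nodes(mesh, c("sacrum_S1_left", "sacrum_S1_right"))
  s1_end <- sac[abs(nd[sac, 3L] - h0) < tol &
                  abs(nd[sac, 1L]) <= params$sacrum_width / 6 + tol]
  patches <- list(
    acetabulum_left = ace_window(il_l, -1),
    acetabulum_right = ace_window(il_r, +1),
    s1_endplate = s1_end)

  anch <- ligament_anchor_table(params)
  for (s in c("left", "right")) {
    sg <- if (s == "left") -1 else 1
    for (r in seq_len(nrow(anch$bilateral))) {
      a <- anch$bilateral[r, ]
      regs <- if (a$region == "sacrum")
        paste0("sacrum_", c("S1", "S2"), "_", s) else paste0("ilium_", s)
      pt <- c(sg * a$x, a$y, a$z)
      nm <- sprintf("lig_%s_%s_%s", a$lig, s, a$end)
      patches[[nm]] <- nearest_region_nodes(mesh, regs, pt)
    }
  }
  for (r in seq_len(nrow(anch$midline))) {
    a <- anch$midline[r, ]
    nm <- sprintf("lig_%s_%s", a$lig, a$end)
    patches[[nm]] <- nearest_region_nodes(mesh, a$region, c(a$x, a$y, a$z))
  }
  mesh$patches <- patches
  validate_mesh(mesh)
  list(mesh = mesh, hu = data.frame(element = seq_len(nrow(mesh$tets)),
                                    hu = hu_elem))
}

# evaluate expr under a seed without clobbering the caller's RNG stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# nearest lattice plane coordinate strictly inside (lo, hi) along axis ax,
# avoiding planes that contain any of the `avoid` coordinates
snap_plane <- function(mesh, ax, target, lo, hi, avoid = numeric()) {
  vals <- sort(unique(round(mesh$nodes[, ax], 9)))
  vals <- vals[vals > lo + 1e-6 & vals < hi - 1e-6]
  if (length(avoid))
    vals <- vals[vapply(vals, function(v) all(abs(v - avoid) > 1e-6),
                        logical(1))]
  if (!length(vals)) stop("no lattice plane available inside target range")
  vals[which.min(abs(vals - target))]
}

# Cut the mesh along lattice plane x = value, restricted to target regions.
# Elements on the `lateral_sign` side get duplicated nodes (free faces).
cut_plane <- function(mesh, value, regions, lateral_sign, site) {
  tol <- 1e-6
  cen <- element_centroids(mesh)
  in_target <- mesh$region %in% regions
  if (!any(in_target))
    stop(sprintf("fracture plane '%s' misses its target region", site))
  tgt_nodes <- region_nodes(mesh, regions)
  on_plane <- tgt_nodes[abs(mesh$nodes[tgt_nodes, 1L] - value) < tol]
  if (!length(on_plane))
    stop(sprintf("fracture plane misses the mesh (%s)", site))
  lat_side <- (cen[, 1L] - value) * lateral_sign > 0
  # incidence of plane nodes
  uses <- mesh$tets %in% on_plane
  dim(uses) <- dim(mesh$tets)
  touch <- rowSums(uses) > 0
  if (any(touch & !in_target)) {
    other <- unique(mesh$region[touch & !in_target])
    stop(sprintf("fracture plane '%s' intersects non-target regions: %s",
                 site, paste(other, collapse = ", ")))
  }
  med_el <- which(touch & in_target & !lat_side)
  lat_el <- which(touch & in_target & lat_side)
  if (!length(med_el) || !length(lat_el))
    stop(sprintf("fracture plane '%s' misses its target region", site))
  shared <- intersect(unique(as.vector(mesh$tets[med_el, , drop = FALSE])),
                      unique(as.vector(mesh$tets[lat_el, , drop = FALSE])))
  shared <- sort(intersect(shared, on_plane))
  bc <- c("acetabulum_left", "acetabulum_right", "s1_endplate")
  for (p in intersect(bc, names(mesh$patches))) {
    if (length(intersect(shared, mesh$patches[[p]])))
      stop(sprintf("cut '%s' would disconnect boundary-condition patch '%s'",
                   site, p))
  }
  n0 <- nrow(mesh$nodes)
  dup <- seq.int(n0 + 1L, n0 + length(shared))
  mesh$nodes <- rbind(mesh$nodes, mesh$nodes[shared, , drop = FALSE])
  map <- integer(n0); map[shared] <- dup
  tt <- mesh$tets[lat_el, , drop = FALSE]
  hit <- tt %in% shared
  tt[hit] <- map[tt[hit]]
  mesh$tets[lat_el, ] <- tt
  axis <- c(lateral_sign, 0, 0)
  mesh$fracture_pairs[[site]] <- list(site = site, node_a = shared,
                                      node_b = dup, axis = axis,
                                      plane_x = value)
  nm <- paste0("fracture_", site)
  mesh$patches[[paste0(nm, "_medial")]] <- shared
  mesh$patches[[paste0(nm, "_lateral")]] <- dup
  mesh
}

#' Cut an FFP IIc fracture pattern into the phantom
#'
#' Introduces the three unilateral fracture planes of a type IIc fragility
#' fracture: a vertical plane through the sacral ala of the injured side
#' (Denis zone II, normal along the lateral-medial axis) and one plane each
#' through the ipsilateral superior and inferior pubic ramus. Interface nodes
#' are duplicated so the paired faces are topologically free (no contact is
#' enforced; faces may separate or interpenetrate). Element count is
#' unchanged; node count grows by the number of duplicated interface nodes.
#'
#' @param mesh intact phantom mesh from [build_phantom()].
#' @param injured_side `"left"` or `"right"`.
#' @param ala_fraction posterior plane position as a fraction of the sacral
#'   half-width from the midline (default 0.6, within zone II).
#' @return the cut [tet_mesh] with three registered fracture face pairs
#'   (`posterior`, `anterior_sup`, `anterior_inf`).
#' @export
cut_ffp2c <- function(mesh, injured_side = c("right", "left"),
                      ala_fraction = 0.6) {
  injured_side <- match.arg(injured_side)
  if (length(mesh$fracture_pairs))
    stop("mesh already carries fracture face pairs")
  sg <- if (injured_side == "right") 1 else -1
  # narrowest sacral half-width over z: the plane must stay inside the
  # sacrum at every level of the tapered ala
  sac_nodes <- region_nodes(mesh, paste0("sacrum_", c("S1", "S2"), "_",
                                         injured_side))
  zl <- round(mesh$nodes[sac_nodes, 3L], 6)
  xs_min <- min(tapply(abs(mesh$nodes[sac_nodes, 1L]), zl, max))
  bc_x <- unique(mesh$nodes[unlist(mesh$patches[c("acetabulum_left",
                                                  "acetabulum_right",
                                                  "s1_endplate")]), 1L])
  x_post <- snap_plane(mesh, 1L, sg * ala_fraction * xs_min,
                       min(0, sg * xs_min), max(0, sg * xs_min),
                       avoid = bc_x)
  sac_regions <- paste0("sacrum_", c("S1", "S2"), "_", injured_side)
  mesh <- cut_plane(mesh, x_post, sac_regions, sg, "posterior")
  ram_sup <- paste0("ramus_sup_", injured_side)
  ram_nodes <- region_nodes(mesh, ram_sup)
  xr <- range(sg * mesh$nodes[ram_nodes, 1L])
  x_ant <- snap_plane(mesh, 1L, sg * mean(xr), min(sg * xr), max(sg * xr))
  mesh <- cut_plane(mesh, x_ant, ram_sup, sg, "anterior_sup")
  mesh <- cut_plane(mesh, x_ant, paste0("ramus_inf_", injured_side), sg,
                    "anterior_inf")
  attr(mesh, "injured_side") <- injured_side
  mesh
}

#' Define a screw fixation construct
#'
#' Describes one of the three fixation variants as parametric cylinders with
#' washers: USI (one screw crossing the injured-side SI joint to
#' mid-sacrum), BSI (two screws, one per side, with slightly convergent,
#' non-parallel axes) or TSI (one transsacral screw spanning the full
#' transverse width). Implant dimensions and material follow typical
#' cannulated SI screws in titanium alloy; all are configurable.
#'
#' @param variant `"USI"`, `"BSI"` or `"TSI"`.
#' @param injured_side `"left"` or `"right"`.
#' @param diameter screw diameter (mm).
#' @param washer_diameter,washer_thickness washer dimensions (mm).
#' @param E,nu implant Young's modulus (MPa) and Poisson ratio.
#' @param bsi_angle_deg transverse-plane convergence half-angle of the two
#'   BSI screws (degrees, > 0 so the axes are non-collinear).
#' @return an object of class `fixation_construct`.
#' @export
fixation_construct <- function(variant = c("USI", "BSI", "TSI"),
                               injured_side = c("right", "left"),
                               diameter = 7.3, washer_diameter = 14,
                               washer_thickness = 2,
                               E = 110000, nu = 0.3, bsi_angle_deg = 4) {
  variant <- match.arg(variant)
  injured_side <- match.arg(injured_side)
  stopifnot(diameter > 0, washer_diameter > 0, E > 0, nu > 0, nu < 0.5)
  structure(list(variant = variant, injured_side = injured_side,
                 diameter = diameter, washer_diameter = washer_diameter,
                 washer_thickness = washer_thickness, E = E, nu = nu,
                 bsi_angle_deg = bsi_angle_deg),
            class = "fixation_construct")
}

# screw axis definitions in mesh coordinates; entry snapped to voxel-centre
# rows so the discrete screw stays contiguous at coarse lattices
construct_screws <- function(mesh, construct) {
  nd <- mesh$nodes
  xi <- max(abs(nd[, 1L]))
  vox <- attr(mesh, "voxel")
  snap <- function(vals, target) vals[which.min(abs(vals - target))]
  sac <- region_nodes(mesh, c("sacrum_S1_left", "sacrum_S1_right"))
  yc <- snap(sort(unique(vox$y)), mean(range(nd[sac, 2L])))
  z1 <- range(nd[sac, 3L])
  zc <- snap(sort(unique(vox$z)), mean(z1))
  sg <- if (construct$injured_side == "right") 1 else -1
  th <- construct$bsi_angle_deg * pi / 180
  mk <- function(name, entry, dir, length) {
    list(name = name, entry = entry, dir = dir / sqrt(sum(dir^2)),
         length = length)
  }
  switch(construct$variant,
    USI = list(mk("usi", c(sg * xi, yc, zc), c(-sg, 0, 0), xi)),
    TSI = list(mk("tsi", c(sg * xi, yc, zc), c(-sg, 0, 0), 2 * xi)),
    BSI = list(
      # injured-side screw identical to the USI screw; the contralateral
      # screw carries the convergence tilt, so the two axes are
      # non-collinear while the injured-side fixation is the same implant
      mk(paste0("bsi_", construct$injured_side),
         c(sg * xi, yc, zc), c(-sg, 0, 0), xi),
      mk(paste0("bsi_", if (sg > 0) "left" else "right"),
         c(-sg * xi, yc, zc), c(sg * cos(th), -sin(th), 0), xi)))
}

#' Place a screw construct into a (fractured) phantom mesh
#'
#' Elements whose centroid lies inside each screw cylinder (with a
#' half-voxel resolution floor on the radius) are re-labeled as
#' `screw_<name>`; the entry-side surface voxel layer inside the washer
#' radius becomes `washer_<name>`. Screws are bonded to the bone by mesh
#' continuity; where a screw crosses a fracture plane the duplicated
#' interface node pairs inside the screw cross-section are re-tied
#' (master-slave), which is what stabilises the fracture. The screw-bone
#' interface node set is recorded as a patch per screw.
#'
#' @param mesh a [tet_mesh], typically from [cut_ffp2c()].
#' @param construct a [fixation_construct].
#' @return the mesh with re-labeled screw/washer regions, tie constraints
#'   across bridged fracture planes and an attribute `implant_material`
#'   (list `E`, `nu`).
#' @export
place_screws <- function(mesh, construct) {
  stopifnot(inherits(construct, "fixation_construct"))
  screws <- construct_screws(mesh, construct)
  cen <- element_centroids(mesh)
  hvox <- mesh$h
  r_eff <- max(construct$diameter / 2, 0.75 * hvox)
  rw_eff <- max(construct$washer_diameter / 2, 1.1 * hvox)
  relabelable <- c(bone_regions(), soft_regions())
  placed_nodes <- integer(0)
  for (s in screws) {
    p0 <- s$entry
    d <- s$dir
    w <- sweep(cen, 2L, p0)
    t_par <- as.vector(w %*% d)
    t_cl <- pmin(pmax(t_par, 0), s$length)
    dist2 <- rowSums((w - outer(t_cl, d))^2)
    inside <- dist2 <= r_eff^2 & mesh$region %in% relabelable
    if (length(placed_nodes)) {
      # separate implants are distinct bodies: never share mesh nodes with
      # a previously placed screw (prevents spurious tip-to-tip welds)
      touch_prev <- matrix(mesh$tets %in% placed_nodes,
                           nrow = nrow(mesh$tets))
      inside <- inside & rowSums(touch_prev) == 0
    }
    if (!any(inside))
      stop(sprintf("screw '%s' captures no elements", s$name))
    wash <- dist2 <= rw_eff^2 & t_par >= -hvox & t_par <= hvox &
      mesh$region %in% relabelable & !inside
    mesh$region[inside] <- paste0("screw_", s$name)
    if (any(wash)) mesh$region[wash] <- paste0("washer_", s$name)
    # protrusion check: tip beyond the mesh bounding box (TSI exits
    # laterally at both entry sites by definition)
    scr_nodes <- region_nodes(mesh, paste0("screw_", s$name))
    tip <- s$entry + s$dir * s$length
    bb_lo <- apply(mesh$nodes, 2L, min); bb_hi <- apply(mesh$nodes, 2L, max)
    if (construct$variant != "TSI" &&
        (any(tip < bb_lo - hvox) || any(tip > bb_hi + hvox)))
      warning(sprintf("screw '%s' protrudes through a non-entry surface",
                      s$name))
    # interface patch: screw nodes shared with non-screw elements
    other <- unique(as.vector(mesh$tets[!(mesh$region %in%
      paste0(c("screw_", "washer_"), s$name)), , drop = FALSE]))
    mesh$patches[[paste0("interface_", s$name)]] <-
      sort(intersect(scr_nodes, other))
    placed_nodes <- c(placed_nodes,
                      region_nodes(mesh, paste0(c("screw_", "washer_"),
                                                s$name)))
  }
  # stabilisation requirement + re-tie across bridged fracture planes
  post <- mesh$fracture_pairs[["posterior"]]
  if (!is.null(post)) {
    need_cross <- switch(construct$variant,
      USI = "usi", TSI = "tsi",
      BSI = paste0("bsi_", construct$injured_side))
    reg <- paste0("screw_", need_cross)
    scr_el <- which(mesh$region == reg)
    if (!length(scr_el))
      stop("construct does not stabilize fracture: required screw missing")
    cx <- element_centroids(mesh)[scr_el, 1L]
    if (!(any(cx < post$plane_x) && any(cx > post$plane_x)))
      stop("construct does not stabilize fracture: screw does not cross the posterior fracture plane")
    new_ties <- list()
    scr_regions <- grep("^(screw|washer)_", unique(mesh$region), value = TRUE)
    scr_nodes_all <- region_nodes(mesh, scr_regions)
    for (fp in mesh$fracture_pairs) {
      sel <- (fp$node_a %in% scr_nodes_all) | (fp$node_b %in% scr_nodes_all)
      if (any(sel))
        new_ties[[fp$site]] <- data.frame(slave = fp$node_b[sel],
                                          master = fp$node_a[sel])
    }
    if (length(new_ties))
      mesh$ties <- unique(rbind(mesh$ties, do.call(rbind, new_ties)))
  }
  attr(mesh, "implant_material") <- list(E = construct$E, nu = construct$nu)
  attr(mesh, "construct") <- construct
  validate_mesh(mesh)
  mesh
}
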