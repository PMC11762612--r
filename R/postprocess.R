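#' Signed fracture-gap distance
#'
#' Mean, over the paired interface nodes, of the relative displacement of
#' the lateral face with respect to the medial face projected on the
#' measurement axis (lateral-medial). Positive values mean the faces
#' separate (opening); negative values mean the fragments translate past
#' one another (the faces are free, so interpenetration is permitted).
#'
#' @param solution a `fem_solution`.
#' @param pair one fracture face pair from `mesh$fracture_pairs` (or its
#'   site name).
#' @param band optional numeric length-2 z-range restricting the probe to a
#'   band (used for the superior/inferior posterior probes).
#' @return signed gap distance in mm.
#' @export
fracture_gap <- function(solution, pair, band = NULL) {
  mesh <- solution$mesh
  if (is.character(pair)) {
    if (is.null(mesh$fracture_pairs[[pair]]))
      stop(sprintf("no fracture face pair '%s' in mesh", pair))
    pair <- mesh$fracture_pairs[[pair]]
  }
  if (length(pair$node_a) != length(pair$node_b))
    stop("unpaired fracture-face nodes")
  sel <- seq_along(pair$node_a)
  if (!is.null(band)) {
    z <- mesh$nodes[pair$node_a, 3L]
    sel <- which(z >= band[1L] & z <= band[2L])
    if (!length(sel)) stop("empty probe band")
  }
  du <- solution$u[pair$node_b[sel], , drop = FALSE] -
    solution$u[pair$node_a[sel], , drop = FALSE]
  mean(as.vector(du %*% pair$axis))
}

#' Regional normal stress
#'
#' Signed extremum (largest magnitude, sign preserved) of the element
#' normal-stress component along a direction over a named region. Elements
#' touching tie constraints, fixed patches or the loaded patch are excluded
#' to keep constraint singularities out of the probe; the extraction rule is
#' recorded in the result's attributes.
#'
#' @param solution a `fem_solution`.
#' @param region region label (e.g. `"sacrum_S1_left"`).
#' @param direction unit direction vector (default lateral-medial, x).
#' @param exclude_patches patch names whose nodes disqualify touching
#'   elements (defaults to the solution's BC/load patches).
#' @return stress in MPa with attribute `rule`.
#' @export
regional_stress <- function(solution, region,
                            direction = c(1, 0, 0),
                            exclude_patches = NULL) {
  mesh <- solution$mesh
  el <- which(mesh$region %in% region)
  if (!length(el)) stop(sprintf("region '%s' is empty", region))
  case <- attr(solution, "load_case")
  if (is.null(exclude_patches)) {
    exclude_patches <- if (!is.null(case))
      c(case$fixed_patches, case$patch) else character(0)
    # bonded implant interfaces count as tie constraints: the screws are
    # bonded to the bone, and elements at the bond carry mesh-resolution
    # stress concentrations that must not masquerade as bone stress
    exclude_patches <- c(exclude_patches,
                         grep("^interface_", names(mesh$patches),
                              value = TRUE))
  }
  bad_nodes <- unique(c(unlist(mesh$patches[exclude_patches]),
                        mesh$ties$slave, mesh$ties$master))
  if (length(bad_nodes)) {
    touch <- matrix(mesh$tets[el, ] %in% bad_nodes, nrow = length(el))
    el <- el[rowSums(touch) == 0]
  }
  if (!length(el)) stop(sprintf("region '%s' empty after exclusions", region))
  d <- direction / sqrt(sum(direction^2))
  s <- solution$stress[el, ]
  sn <- d[1L]^2 * s$sxx + d[2L]^2 * s$syy + d[3L]^2 * s$szz +
    2 * d[1L] * d[2L] * s$sxy + 2 * d[2L] * d[3L] * s$syz +
    2 * d[3L] * d[1L] * s$szx
  out <- sn[which.max(abs(sn))]
  attr(out, "rule") <- paste("signed extremum of the normal stress along",
                             paste(round(d, 3), collapse = ","),
                             "over region elements excluding BC/load/tie",
                             "neighbourhoods")
  out
}

# max principal tension / compression over selected elements
principal_extremes <- function(stress, el = seq_len(nrow(stress))) {
  s <- stress[el, ]
  n <- nrow(s)
  tmax <- -Inf; cmax <- Inf
  for (i in seq_len(n)) {
    S <- matrix(c(s$sxx[i], s$sxy[i], s$szx[i],
                  s$sxy[i], s$syy[i], s$syz[i],
                  s$szx[i], s$syz[i], s$szz[i]), 3L, 3L)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    tmax <- max(tmax, ev[1L])
    cmax <- min(cmax, ev[3L])
  }
  c(tension = tmax, compression = cmax)
}

#' Mesh-convergence study
#'
#' Runs the convergence protocol: the phantom meshed at a descending
#' sequence of edge lengths, uniform linear-elastic bone (default 6000
#' MPa), the ring fixed at the upper level of the sacrum (S1 endplate) and
#' a bipedal stance simulated as upward hip reactions of 1024 N at each
#' acetabulum. For each refinement the maximum principal tension and
#' compression (away from constrained patches) are recorded; the mesh is
#' accepted when the last relative change in both is below 5%.
#'
#' @param params [phantom_params()] for the phantom (its
#'   `target_edge_length` is overridden by `edge_lengths`).
#' @param edge_lengths descending vector of edge lengths (mm), length >= 2.
#' @param E,nu uniform material for this stage.
#' @param threshold acceptance threshold on the relative change (default
#'   0.05).
#' @param exclusion_radius elements with centroids within this distance
#'   (mm) of a constrained or loaded patch are excluded from the stress
#'   extrema. A fixed physical band keeps the probe region identical
#'   across refinements; a one-element band would creep into the
#'   constraint-edge singularity as the mesh is refined.
#' @return object of class `convergence_result`: data.frame with columns
#'   `edge_length`, `n_elements`, `max_tension`, `max_compression`,
#'   `change_tension`, `change_compression`, and attribute `accepted`.
#' @export
convergence_study <- function(params = phantom_params(),
                              edge_lengths = c(5, 2.5),
                              E = 6000, nu = 0.3, threshold = 0.05,
                              exclusion_radius = 8) {
  if (length(edge_lengths) < 2L)
    stop("convergence study needs at least two edge lengths")
  if (is.unsorted(rev(edge_lengths)))
    stop("edge_lengths must be descending")
  rows <- list()
  for (h in edge_lengths) {
    p <- params; p$target_edge_length <- h
    ph <- tryCatch(build_phantom(p), error = function(e) {
      warning(sprintf("meshing failed at h = %g mm, size skipped (%s)",
                      h, conditionMessage(e)))
      NULL
    })
    if (is.null(ph)) next
    mesh <- ph$mesh
    mat <- uniform_material_field(mesh, E, nu)
    fixed <- mesh$patches$s1_endplate
    f <- numeric(3L * nrow(mesh$nodes))
    for (side in c("acetabulum_left", "acetabulum_right")) {
      nd <- mesh$patches[[side]]
      f[3L * (nd - 1L) + 3L] <- 1024 / length(nd)
    }
    sys <- fem_assemble(mesh, mat, fixed_nodes = fixed, load = f)
    sol <- fem_solve(sys)
    excl <- unique(unlist(mesh$patches[c("s1_endplate", "acetabulum_left",
                                         "acetabulum_right")]))
    cen <- element_centroids(mesh)
    d2min <- rep(Inf, nrow(cen))
    for (nd in excl) {
      d2 <- (cen[, 1L] - mesh$nodes[nd, 1L])^2 +
        (cen[, 2L] - mesh$nodes[nd, 2L])^2 +
        (cen[, 3L] - mesh$nodes[nd, 3L])^2
      d2min <- pmin(d2min, d2)
    }
    keep <- which(d2min > exclusion_radius^2)
    pe <- principal_extremes(sol$stress, keep)
    rows[[length(rows) + 1L]] <- data.frame(
      edge_length = h, n_elements = nrow(mesh$tets),
      max_tension = pe[["tension"]],
      max_compression = pe[["compression"]])
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 2L)
    stop("fewer than two refinements meshed; cannot assess convergence")
  tab$change_tension <- c(NA, abs(diff(tab$max_tension)) /
                            abs(tab$max_tension[-nrow(tab)]))
  tab$change_compression <- c(NA, abs(diff(tab$max_compression)) /
                                abs(tab$max_compression[-nrow(tab)]))
  last <- nrow(tab)
  accepted <- tab$change_tension[last] < threshold &&
    tab$change_compression[last] < threshold
  structure(tab, accepted = accepted, threshold = threshold,
            class = c("convergence_result", class(tab)))
}

#' @export
print.convergence_result <- function(x, ...) {
  cat("Mesh convergence (uniform E, S1 endplate fixed, bipedal reactions)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  cat(sprintf("Accepted (last change < %.0f%% in tension and compression): %s\n",
              100 * attr(x, "threshold"), attr(x, "accepted")))
  invisible(x)
}

#' @export
plot.convergence_result <- function(x, ...) {
  graphics::matplot(x$edge_length, cbind(x$max_tension, -x$max_compression),
                    type = "b", pch = c(1, 2), lty = 1,
                    xlim = rev(range(x$edge_length)),
                    xlab = "edge length [mm]",
                    ylab = "extreme principal stress [MPa]", ...)
  graphics::legend("topleft", c("max tension", "max |compression|"),
                   pch = c(1, 2), bty = "n")
  invisible(x)
}

# stance cases in report order, with the paper-style row labels
stance_cases <- function() {
  c(bipedal = "Bipedal stance", right_one_leg = "Right one-legged stance",
    left_one_leg = "Left one-legged stance")
}

#' Compare the three fixation constructs
#'
#' Runs the full comparison: one phantom, cut as an FFP IIc on the injured
#' side, fixed with each construct variant in turn, solved under the three
#' stance load cases. Emits the fracture-gap table (lateral-medial signed
#' gap at the posterior ring and at the superior pubic ramus) and the
#' regional normal-stress table (lateral-medial stress at S1/S2, left and
#' right), one column per construct — the layouts of the fixation
#' comparison.
#'
#' @param params [phantom_params()].
#' @param variants character vector of constructs to compare.
#' @param cases stance case names.
#' @param injured_side `"right"` (default) or `"left"`.
#' @param catalog ligament [stiffness_catalog()].
#' @param constants material [mapping_constants()].
#' @param construct_args extra arguments passed to [fixation_construct()].
#' @param band_fraction fraction of the posterior face height used for the
#'   superior and inferior probe bands (default 0.2: the probes sit at the
#'   cortical margins of the fracture, away from the implant corridor at
#'   the mid-S1 level). The headline posterior value is the superior band;
#'   both bands are kept in `details`.
#' @return object of class `construct_comparison`: list with `gaps` and
#'   `stresses` data.frames, `details` (per-run gap probes), `manifest`.
#' @export
compare_constructs <- function(params = phantom_params(),
                               variants = c("USI", "BSI", "TSI"),
                               cases = names(stance_cases()),
                               injured_side = "right",
                               catalog = stiffness_catalog(),
                               constants = mapping_constants(),
                               construct_args = list(),
                               band_fraction = 0.2) {
  ph <- build_phantom(params)
  cut <- cut_ffp2c(ph$mesh, injured_side)
  zf <- range(cut$nodes[cut$fracture_pairs$posterior$node_a, 3L])
  dz <- diff(zf)
  sup_band <- c(zf[2L] - band_fraction * dz, zf[2L])
  inf_band <- c(zf[1L], zf[1L] + band_fraction * dz)
  gap_rows <- list(); stress_rows <- list(); details <- list()
  regions <- c("S1 right side" = "sacrum_S1_right",
               "S1 left side" = "sacrum_S1_left",
               "S2 right side" = "sacrum_S2_right",
               "S2 left side" = "sacrum_S2_left")
  gaps <- array(NA_real_, dim = c(length(cases), 2L, length(variants)),
                dimnames = list(cases, c("posterior", "anterior"), variants))
  stresses <- array(NA_real_,
                    dim = c(length(cases), length(regions), length(variants)),
                    dimnames = list(cases, names(regions), variants))
  for (v in variants) {
    con <- do.call(fixation_construct,
                   c(list(variant = v, injured_side = injured_side),
                     construct_args))
    mesh_v <- place_screws(cut, con)
    mat <- build_material_field(mesh_v, ph$hu, constants)
    spr <- make_springs(mesh_v, catalog)
    for (cs in cases) {
      sol <- run_load_case(mesh_v, mat, cs, spr)
      g_sup <- fracture_gap(sol, "posterior", band = sup_band)
      g_inf <- fracture_gap(sol, "posterior", band = inf_band)
      g_ant <- fracture_gap(sol, "anterior_sup")
      g_ant_inf <- fracture_gap(sol, "anterior_inf")
      gaps[cs, "posterior", v] <- g_sup
      gaps[cs, "anterior", v] <- g_ant
      for (r in names(regions)) {
        stresses[cs, r, v] <- as.numeric(
          regional_stress(sol, regions[[r]]))
      }
      details[[paste(v, cs, sep = ".")]] <- data.frame(
        variant = v, case = cs,
        posterior_superior = g_sup, posterior_inferior = g_inf,
        anterior_superior_ramus = g_ant, anterior_inferior_ramus = g_ant_inf,
        iterations = sol$iterations)
    }
  }
  lab <- stance_cases()[cases]
  slice <- function(arr, cs) {
    s <- arr[cs, , , drop = FALSE]
    matrix(s, nrow = dim(s)[2L], ncol = dim(s)[3L],
           dimnames = dimnames(s)[2:3])
  }
  gap_df <- do.call(rbind, lapply(cases, function(cs) {
    data.frame(load_case = lab[[cs]],
               site = c("Posterior pelvic ring", "Anterior pelvic ring"),
               slice(gaps, cs),
               check.names = FALSE, row.names = NULL)
  }))
  stress_df <- do.call(rbind, lapply(cases, function(cs) {
    data.frame(load_case = lab[[cs]], region = names(regions),
               slice(stresses, cs),
               check.names = FALSE, row.names = NULL)
  }))
  class(gap_df) <- c("gap_report", class(gap_df))
  class(stress_df) <- c("stress_report", class(stress_df))
  manifest <- list(injured_side = injured_side, variants = variants,
                   cases = cases, seed = params$rng_seed,
                   edge_length = params$target_edge_length,
                   ligament_source = attr(catalog, "source"))
  structure(list(gaps = gap_df, stresses = stress_df,
                 details = do.call(rbind, details), manifest = manifest),
            class = "construct_comparison")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("Fracture-gap distance, lateral-medial direction [mm]\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
print.stress_report <- function(x, ...) {
  cat("Normal stress, lateral-medial direction [MPa]\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
print.construct_comparison <- function(x, ...) {
  cat("Fixation construct comparison (injured side:",
      x$manifest$injured_side, ")\n\n")
  print(x$gaps); cat("\n"); print(x$stresses)
  invisible(x)
}

#' @export
summary.construct_comparison <- function(object, ...) {
  g <- object$gaps
  post_bi <- g[g$load_case == "Bipedal stance" &
                 g$site == "Posterior pelvic ring",
               setdiff(names(g), c("load_case", "site"))]
  ord <- names(sort(unlist(abs(post_bi))))
  cat("Posterior-ring bipedal gap ordering (best first):",
      paste(ord, collapse = " < "), "\n")
  invisible(object)
}
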