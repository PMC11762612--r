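#' Constants of the HU-to-modulus material mapping
#'
#' The mapping follows the Dalstra relations: apparent density is linear in
#' Hounsfield units, rho_app = a*HU + b (capped at `rho_cap`), and Young's
#' modulus follows the power law E = c*rho_app^p, clamped to
#' \[`E_min`, `E_max`\] to represent elderly (osteopenic) bone. The clamped
#' modulus range is discretised into bins of width `bin_width` so that
#' elements share a finite set of materials.
#'
#' Note on `bin_width`: a 5 MPa width over \[200, 6530\] MPa yields 1266
#' distinct materials. A 50 MPa width would yield ~127. Both conventions
#' circulate for this pipeline; the 5 MPa default is the one consistent with
#' a 1266-material discretisation, and the width is fully configurable.
#'
#' @param a slope of the density relation (g/cm^3 per HU).
#' @param b intercept of the density relation (g/cm^3).
#' @param c coefficient of the modulus power law (MPa).
#' @param p exponent of the modulus power law.
#' @param hu_min,hu_max HU segmentation window.
#' @param E_min,E_max modulus clamp range (MPa).
#' @param bin_width material bin width (MPa).
#' @param rho_cap apparent-density cap (g/cm^3).
#' @return object of class `mapping_constants`.
#' @export
mapping_constants <- function(a = 0.00032362, b = 1.0, c = 1958.6, p = 2.33,
                              hu_min = 220, hu_max = 2000,
                              E_min = 200, E_max = 6530,
                              bin_width = 5, rho_cap = 1.8) {
  stopifnot(a > 0, c > 0, p > 0, E_min < E_max, bin_width > 0, rho_cap > 0)
  structure(list(a = a, b = b, c = c, p = p, hu_min = hu_min, hu_max = hu_max,
                 E_min = E_min, E_max = E_max, bin_width = bin_width,
                 rho_cap = rho_cap),
            class = "mapping_constants")
}

#' Hounsfield units to apparent density
#'
#' `rho_app = a*HU + b`, capped at `rho_cap` (the densest bone an HU value
#' is allowed to represent).
#'
#' @param hu numeric vector of Hounsfield units.
#' @param constants a [mapping_constants] object.
#' @return apparent density in g/cm^3.
#' @export
hu_to_density <- function(hu, constants = mapping_constants()) {
  if (any(!is.finite(hu))) stop("non-finite HU value")
  pmin(constants$a * hu + constants$b, constants$rho_cap)
}

#' Apparent density to Young's modulus
#'
#' Power law `E = c*rho_app^p`, clamped to \[`E_min`, `E_max`\] MPa.
#'
#' @param rho_app apparent density (g/cm^3), must be positive.
#' @param constants a [mapping_constants] object.
#' @return Young's modulus in MPa.
#' @export
density_to_modulus <- function(rho_app, constants = mapping_constants()) {
  if (any(!is.finite(rho_app)) || any(rho_app <= 0))
    stop("apparent density must be positive and finite")
  pmin(pmax(constants$c * rho_app^constants$p, constants$E_min),
       constants$E_max)
}

#' Assign binned materials to the bone elements of a mesh
#'
#' Maps per-element HU through [hu_to_density()] and [density_to_modulus()],
#' then snaps each modulus to the centre of its bin of width `bin_width`
#' over \[`E_min`, `E_max`\], so all elements in a bin share one material.
#' Only bone regions are mapped; cartilage, symphysis and implant regions
#' receive their materials separately (see [build_material_field()]).
#'
#' @param mesh a [tet_mesh].
#' @param hu_table data.frame with columns `element`, `hu` covering every
#'   bone element (as returned by [build_phantom()]).
#' @param constants a [mapping_constants] object.
#' @param nu Poisson's ratio assigned to bone (dimensionless, in (0, 0.5)).
#' @return data.frame of class `material_field` with columns `element`,
#'   `hu`, `rho_app`, `E_exact`, `E` (binned), `nu`, `bin_id`; attribute
#'   `n_bins_available` gives the size of the material catalogue.
#' @export
assign_materials <- function(mesh, hu_table, constants = mapping_constants(),
                             nu = 0.3) {
  stopifnot(nu > 0, nu < 0.5)
  bone <- which(mesh$region %in% bone_regions())
  hu <- rep(NA_real_, nrow(mesh$tets))
  hu[hu_table$element] <- hu_table$hu
  miss <- bone[!is.finite(hu[bone])]
  if (length(miss))
    stop(sprintf("missing HU for %d bone elements (first ids: %s)",
                 length(miss),
                 paste(utils::head(miss, 5L), collapse = ", ")))
  rho <- rep(NA_real_, length(hu))
  E_exact <- rep(NA_real_, length(hu))
  rho[bone] <- hu_to_density(hu[bone], constants)
  E_exact[bone] <- density_to_modulus(rho[bone], constants)
  n_bins <- ceiling((constants$E_max - constants$E_min) / constants$bin_width)
  bin_id <- rep(NA_integer_, length(hu))
  bin_id[bone] <- pmin(pmax(ceiling((E_exact[bone] - constants$E_min) /
                                      constants$bin_width), 1L), n_bins)
  E_bin <- rep(NA_real_, length(hu))
  E_bin[bone] <- constants$E_min + (bin_id[bone] - 0.5) * constants$bin_width
  out <- data.frame(element = seq_along(hu), hu = hu, rho_app = rho,
                    E_exact = E_exact, E = E_bin, nu = ifelse(is.na(E_bin),
                                                              NA_real_, nu),
                    bin_id = bin_id)
  attr(out, "n_bins_available") <- n_bins
  attr(out, "n_bins_used") <- length(unique(stats::na.omit(bin_id)))
  class(out) <- c("material_field", class(out))
  out
}

#' Full per-element material field for assembly
#'
#' Combines the binned bone materials from [assign_materials()] with the
#' configured materials for cartilage/symphysis (linear-elastic surrogate,
#' near-incompressible) and implant (screw/washer) regions, giving every
#' element an `E` and `nu`.
#'
#' @param mesh a [tet_mesh].
#' @param hu_table per-element HU table (bone elements).
#' @param constants a [mapping_constants] object.
#' @param bone_nu bone Poisson ratio.
#' @param cartilage list with `E` (MPa) and `nu` for cartilage/symphysis.
#' @param implant list with `E` (MPa) and `nu` for screws and washers; if
#'   the mesh carries an `implant_material` attribute that takes precedence.
#' @return data.frame with per-element `E`, `nu` plus the bone mapping
#'   columns; class `material_field`.
#' @export
build_material_field <- function(mesh, hu_table,
                                 constants = mapping_constants(),
                                 bone_nu = 0.3,
                                 cartilage = list(E = 50, nu = 0.45),
                                 implant = list(E = 110000, nu = 0.3)) {
  mf <- assign_materials(mesh, hu_table, constants, nu = bone_nu)
  soft <- mesh$region %in% soft_regions()
  mf$E[soft] <- cartilage$E
  mf$nu[soft] <- cartilage$nu
  imp <- attr(mesh, "implant_material")
  if (is.null(imp)) imp <- implant
  metal <- grepl("^(screw|washer)_", mesh$region)
  mf$E[metal] <- imp$E
  mf$nu[metal] <- imp$nu
  if (any(!is.finite(mf$E)))
    stop("elements without material after assignment")
  mf
}

#' Uniform material field (convergence-stage model)
#'
#' Assigns one linear-elastic material to every element, as used during the
#' mesh-convergence stage (default 6000 MPa).
#'
#' @param mesh a [tet_mesh].
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @return data.frame with `element`, `E`, `nu`.
#' @export
uniform_material_field <- function(mesh, E = 6000, nu = 0.3) {
  data.frame(element = seq_len(nrow(mesh$tets)), E = E, nu = nu)
}
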