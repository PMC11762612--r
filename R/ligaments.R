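#' Ligament stiffness catalogue
#'
#' Stiffness laws for the eight pelvic ligament groups: anterior sacroiliac
#' (ASL), short and long posterior sacroiliac (SPSL, LPSL), interosseous
#' sacroiliac (ISL), sacrospinous (SS), sacrotuberous (ST), and the superior
#' and inferior pubic ligaments (SP, IP). Three literature sources are
#' available: constant stiffnesses after Shi et al. or Yao et al., and
#' elongation-defined stiffness ranges after Eichenseer et al. (stiffness
#' rising linearly from the low to the high value over 0 to
#' `breakpoint_strain` engineering strain, constant beyond). The default
#' `"eichenseer_shi"` uses the Eichenseer ranges for all ligaments except SP
#' and IP, which take the Shi constants — the configuration of the fixation
#' comparison.
#'
#' @param source `"eichenseer_shi"` (default), `"shi"` or `"yao"`.
#' @param breakpoint_strain strain at which an elongation-defined law
#'   reaches its high stiffness (default 0.10).
#' @return object of class `stiffness_catalog`: data.frame with columns
#'   `name`, `k_low`, `k_high` (N/mm) and attribute `breakpoint_strain`.
#' @export
stiffness_catalog <- function(source = c("eichenseer_shi", "shi", "yao"),
                              breakpoint_strain = 0.10) {
  source <- match.arg(source)
  stopifnot(breakpoint_strain > 0)
  nm <- c("ASL", "SPSL", "LPSL", "ISL", "SS", "ST", "SP", "IP")
  shi <- c(700, 400, 1000, 2800, 1400, 1500, 500, 500)
  yao <- c(18.9, 21.0, 21.0, 22.4, 12.6, 22.5, 12.0, 12.0)
  eich_lo <- c(39, 200, 29, 13, 26, 17, NA, NA)
  eich_hi <- c(103, 525, 75, 34, 68, 45, NA, NA)
  tab <- switch(source,
    shi = data.frame(name = nm, k_low = shi, k_high = shi),
    yao = data.frame(name = nm, k_low = yao, k_high = yao),
    eichenseer_shi = data.frame(
      name = nm,
      k_low = ifelse(is.na(eich_lo), shi, eich_lo),
      k_high = ifelse(is.na(eich_hi), shi, eich_hi)))
  stopifnot(all(tab$k_low > 0), all(tab$k_high >= tab$k_low))
  structure(tab, source = source, breakpoint_strain = breakpoint_strain,
            class = c("stiffness_catalog", class(tab)))
}

#' Build ligament springs on a phantom mesh
#'
#' Creates one tension-only spring (or a parallel bundle with the stiffness
#' split evenly) per ligament per side for the six bilateral groups and a
#' single midline spring each for SP and IP, anchored at the mesh's ligament
#' attachment patches. Rest lengths are the undeformed attachment distances.
#'
#' @param mesh a [tet_mesh] from [build_phantom()] (attachment patches
#'   present).
#' @param catalog a [stiffness_catalog].
#' @param bundle number of parallel springs per ligament (1-4).
#' @return data.frame of class `ligament_springs`, one row per spring:
#'   `name`, `ligament`, `side`, `node_a`, `node_b`, `rest_length`,
#'   `k_low`, `k_high`, `breakpoint_strain`, `tension_only`.
#' @export
make_springs <- function(mesh, catalog = stiffness_catalog(), bundle = 1L) {
  stopifnot(bundle >= 1L, bundle <= 4L)
  eps_b <- attr(catalog, "breakpoint_strain")
  rows <- list()
  add <- function(lig, side, patch_a, patch_b) {
    for (p in c(patch_a, patch_b)) {
      if (is.null(mesh$patches[[p]]) || !length(mesh$patches[[p]]))
        stop(sprintf("attachment patch '%s' for ligament %s missing from mesh",
                     p, lig))
    }
    k <- catalog[catalog$name == lig, ]
    na <- mesh$patches[[patch_a]]
    nb <- mesh$patches[[patch_b]]
    nb_use <- min(bundle, length(na), length(nb))
    for (i in seq_len(nb_use)) {
      a <- na[i]; b <- nb[i]
      L0 <- sqrt(sum((mesh$nodes[a, ] - mesh$nodes[b, ])^2))
      if (L0 <= 0) stop(sprintf("zero rest length for ligament %s", lig))
      rows[[length(rows) + 1L]] <<- data.frame(
        name = sprintf("%s_%s%s", lig, side,
                       if (nb_use > 1L) paste0("_", i) else ""),
        ligament = lig, side = side, node_a = a, node_b = b,
        rest_length = L0,
        k_low = k$k_low / nb_use, k_high = k$k_high / nb_use,
        breakpoint_strain = eps_b, tension_only = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  for (side in c("left", "right")) {
    for (lig in c("ASL", "SPSL", "LPSL", "ISL", "SS", "ST")) {
      add(lig, side,
          sprintf("lig_%s_%s_sacrum", lig, side),
          sprintf("lig_%s_%s_ilium", lig, side))
    }
  }
  add("SP", "mid", "lig_SP_left", "lig_SP_right")
  add("IP", "mid", "lig_IP_left", "lig_IP_right")
  out <- do.call(rbind, rows)
  class(out) <- c("ligament_springs", class(out))
  out
}

#' Axial force of a tension spring
#'
#' Force law of the ligament springs: zero at or below rest length for
#' tension-only springs; above rest length the secant stiffness rises
#' linearly from `k_low` at zero elongation to `k_high` at
#' `breakpoint_strain`, staying at `k_high` beyond (constant-stiffness laws
#' have `k_low == k_high`). Force is `k(eps) * (L - L0)`, tension positive.
#'
#' @param spring one spring: a list or one-row data.frame with fields
#'   `rest_length`, `k_low`, `k_high`, `breakpoint_strain`, `tension_only`.
#' @param current_length current spring length (mm, > 0).
#' @return axial force in N (tension positive).
#' @export
spring_force <- function(spring, current_length) {
  stopifnot(all(current_length > 0))
  L0 <- spring$rest_length
  dl <- current_length - L0
  eps <- dl / L0
  k <- spring_secant_stiffness(spring, eps)
  f <- k * dl
  if (isTRUE(spring$tension_only)) f[dl <= 0] <- 0
  f
}

# secant stiffness at engineering strain eps (vectorised over eps)
spring_secant_stiffness <- function(spring, eps) {
  kl <- spring$k_low; kh <- spring$k_high; eb <- spring$breakpoint_strain
  if (is.null(eb) || !is.finite(eb) || kl == kh) return(rep(kl, length(eps)))
  frac <- pmin(pmax(eps, 0), eb) / eb
  kl + (kh - kl) * frac
}
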