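#' Define a named load case
#'
#' Seven scenarios are available. The four validation cases apply 294 N to
#' the S1 endplate along the anterior, posterior, superior or inferior
#' direction with both acetabula fixed (the sacral-motion validation
#' protocol). The stance cases apply the maximum walking force of 2048 N
#' inferiorly on the S1 endplate: bipedal stance fixes both acetabula (so
#' each side carries 1024 N, half the maximum), a one-legged stance fixes
#' only the stance-side acetabulum.
#'
#' @param name one of `"validation_anterior"`, `"validation_posterior"`,
#'   `"validation_superior"`, `"validation_inferior"`, `"bipedal"`,
#'   `"right_one_leg"`, `"left_one_leg"`.
#' @return object of class `load_case`: applied patch, unit direction,
#'   total magnitude (N), per-side share, fixed patches.
#' @export
make_load_case <- function(name) {
  cases <- list(
    validation_anterior = list(dir = c(0, 1, 0), mag = 294,
                               fixed = c("acetabulum_left", "acetabulum_right")),
    validation_posterior = list(dir = c(0, -1, 0), mag = 294,
                                fixed = c("acetabulum_left", "acetabulum_right")),
    validation_superior = list(dir = c(0, 0, 1), mag = 294,
                               fixed = c("acetabulum_left", "acetabulum_right")),
    validation_inferior = list(dir = c(0, 0, -1), mag = 294,
                               fixed = c("acetabulum_left", "acetabulum_right")),
    bipedal = list(dir = c(0, 0, -1), mag = 2048,
                   fixed = c("acetabulum_left", "acetabulum_right")),
    right_one_leg = list(dir = c(0, 0, -1), mag = 2048,
                         fixed = "acetabulum_right"),
    left_one_leg = list(dir = c(0, 0, -1), mag = 2048,
                        fixed = "acetabulum_left"))
  if (!name %in% names(cases))
    stop(sprintf("unknown load case '%s' (known: %s)", name,
                 paste(names(cases), collapse = ", ")))
  c0 <- cases[[name]]
  structure(list(name = name, patch = "s1_endplate", direction = c0$dir,
                 magnitude = c0$mag,
                 per_side = c0$mag / length(c0$fixed),
                 fixed_patches = c0$fixed),
            class = "load_case")
}

#' Nodal load vector for a load case
#'
#' Distributes the case's total force equally over the nodes of its applied
#' patch along its direction.
#'
#' @param mesh a [tet_mesh] with the case's patches present.
#' @param case a [make_load_case()] object.
#' @return numeric load vector of length `3 * nrow(mesh$nodes)` (N).
#' @export
load_vector <- function(mesh, case) {
  nodes <- mesh$patches[[case$patch]]
  if (is.null(nodes) || !length(nodes))
    stop(sprintf("load patch '%s' missing from mesh", case$patch))
  f <- numeric(3L * nrow(mesh$nodes))
  per <- case$magnitude / length(nodes)
  for (d in 1:3) {
    if (case$direction[d] != 0)
      f[3L * (nodes - 1L) + d] <- per * case$direction[d]
  }
  f
}

#' Run one load case on a mesh
#'
#' Assembles and solves the mesh under the given load case with its fixed
#' patches clamped, using the tension-only active-set iteration when
#' ligament springs are supplied.
#'
#' @param mesh a [tet_mesh].
#' @param materials per-element material table (see
#'   [build_material_field()]).
#' @param case a [make_load_case()] object (or case name).
#' @param springs optional ligament spring table from [make_springs()].
#' @param tol solver tolerance.
#' @return a `fem_solution` with the load case attached as attribute.
#' @export
run_load_case <- function(mesh, materials, case, springs = NULL,
                          tol = 1e-8) {
  if (is.character(case)) case <- make_load_case(case)
  fixed <- unlist(lapply(case$fixed_patches, function(p) {
    nd <- mesh$patches[[p]]
    if (is.null(nd) || !length(nd))
      stop(sprintf("fixed patch '%s' missing from mesh", p))
    nd
  }))
  f <- load_vector(mesh, case)
  sol <- solve_tension_only(mesh, materials, springs,
                            fixed_nodes = fixed, load = f, tol = tol)
  attr(sol, "load_case") <- case
  sol
}

#' Sacral-motion validation protocol
#'
#' Runs the four 294 N validation load cases (anterior, posterior,
#' superior, inferior) on an intact phantom with both acetabula fixed and
#' reports the mean S1-endplate displacement for each.
#'
#' @param mesh intact phantom mesh.
#' @param materials material table.
#' @param springs ligament springs.
#' @return data.frame: case, direction, mean S1 displacement components and
#'   magnitude (mm).
#' @export
validate_loads <- function(mesh, materials, springs = NULL) {
  cases <- paste0("validation_", c("anterior", "posterior", "superior",
                                   "inferior"))
  s1 <- mesh$patches$s1_endplate
  rows <- lapply(cases, function(nm) {
    sol <- run_load_case(mesh, materials, nm, springs)
    um <- colMeans(sol$u[s1, , drop = FALSE])
    data.frame(case = nm, ux = um[1L], uy = um[2L], uz = um[3L],
               magnitude = sqrt(sum(um^2)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
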