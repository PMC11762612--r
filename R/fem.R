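#' Stiffness matrix of one linear tetrahedron
#'
#' Constant-strain tetrahedron stiffness for an isotropic material,
#' assembled from the closed-form node-block expression
#' `K_ab = V * (lambda g_a g_b' + mu g_b g_a' + mu (g_a . g_b) I)` where
#' `g_a` are the shape-function gradients.
#'
#' @param coords 4x3 matrix of node coordinates (mm), positively oriented.
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @return symmetric 12x12 matrix (N/mm per dof ordering x1,y1,z1,...,z4);
#'   positive semi-definite with exactly six rigid-body zero-energy modes.
#' @export
element_stiffness <- function(coords, E, nu) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 4L, ncol(coords) == 3L)
  J <- coords[2:4, ] - matrix(coords[1L, ], 3L, 3L, byrow = TRUE)
  detJ <- det(J)
  if (detJ <= 0) stop("degenerate (zero/negative volume) tetrahedron")
  V <- detJ / 6
  Jinv <- solve(J)
  G <- rbind(-colSums(t(Jinv)), t(Jinv))  # rows g1..g4 (gradients)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  K <- matrix(0, 12L, 12L)
  for (a in 1:4) {
    for (b in 1:4) {
      ga <- G[a, ]; gb <- G[b, ]
      blk <- lam * outer(ga, gb) + mu * outer(gb, ga) +
        mu * sum(ga * gb) * diag(3)
      K[(3 * a - 2):(3 * a), (3 * b - 2):(3 * b)] <- V * blk
    }
  }
  (K + t(K)) / 2
}

# Vectorised shape-function gradients for all elements.
# Returns list(G = list of four m x 3 matrices, V = volumes).
element_gradients <- function(nodes, tets) {
  p1 <- nodes[tets[, 1L], , drop = FALSE]
  e1 <- nodes[tets[, 2L], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3L], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4L], , drop = FALSE] - p1
  crossv <- function(u, v) cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                                 u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                                 u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  c23 <- crossv(e2, e3)
  detJ <- rowSums(e1 * c23)
  if (any(detJ <= 0)) {
    bad <- which(detJ <= 0)
    stop(sprintf("%d degenerate tets (first: element %d)", length(bad),
                 bad[1L]))
  }
  # columns of J^-1 (J rows are e1,e2,e3): c1 = e2 x e3 / det, etc.
  g2 <- c23 / detJ
  g3 <- crossv(e3, e1) / detJ
  g4 <- crossv(e1, e2) / detJ
  g1 <- -(g2 + g3 + g4)
  list(G = list(g1, g2, g3, g4), V = detJ / 6)
}

#' Assemble the global finite-element system
#'
#' Builds the sparse symmetric global stiffness matrix over 3N nodal
#' degrees of freedom from the tetrahedral elements (per-element isotropic
#' materials) plus the axial stiffness of the currently active springs.
#' Tie (bonded) constraints are eliminated master-slave: slave dofs are
#' merged into their masters before assembly, so the tie is exact. Dirichlet
#' conditions are applied by elimination; prescribed non-zero values
#' contribute to the right-hand side.
#'
#' @param mesh a [tet_mesh] (its `ties` are honoured).
#' @param materials per-element data.frame with `E`, `nu`.
#' @param springs optional [make_springs()] table (rows with `node_a`,
#'   `node_b`, stiffness law fields).
#' @param active logical vector marking active springs (default all).
#' @param spring_k optional numeric vector of secant stiffnesses (N/mm)
#'   overriding the catalogue values (used by the active-set iteration).
#' @param fixed_nodes integer vector of nodes clamped in all 3 dofs.
#' @param prescribed optional data.frame `node`, `dof` (1-3), `value` (mm)
#'   of prescribed displacement components.
#' @param load numeric length-3N load vector (N per dof), or NULL.
#' @return an `assembled_system` list: reduced stiffness `K` (dgCMatrix),
#'   right-hand side, dof bookkeeping and the inputs needed for recovery.
#' @export
fem_assemble <- function(mesh, materials, springs = NULL, active = NULL,
                         spring_k = NULL, fixed_nodes = integer(),
                         prescribed = NULL, load = NULL) {
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  # --- master-slave node map from ties ---
  rep_node <- seq_len(n)
  if (nrow(mesh$ties)) {
    for (r in seq_len(nrow(mesh$ties))) {   # resolve chains
      s <- mesh$ties$slave[r]; m <- mesh$ties$master[r]
      while (rep_node[m] != m) m <- rep_node[m]
      rep_node[s] <- m
    }
    rep_node <- rep_node[rep_node]  # one more pass flattens 2-chains
  }
  eg <- element_gradients(mesh$nodes, mesh$tets)
  E <- materials$E; nu <- materials$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  V <- eg$V
  m_el <- nrow(mesh$tets)
  tets_m <- matrix(rep_node[mesh$tets], nrow = m_el)
  nz <- 144L * m_el
  ii <- integer(nz); jj <- integer(nz); xx <- numeric(nz)
  pos <- 0L
  for (a in 1:4) {
    ga <- eg$G[[a]]
    na <- tets_m[, a]
    for (b in 1:4) {
      gb <- eg$G[[b]]
      nb2 <- tets_m[, b]
      dab <- rowSums(ga * gb)
      for (i in 1:3) {
        for (j in 1:3) {
          val <- V * (lam * ga[, i] * gb[, j] + mu * gb[, i] * ga[, j] +
                        (if (i == j) mu * dab else 0))
          idx <- pos + seq_len(m_el)
          ii[idx] <- 3L * (na - 1L) + i
          jj[idx] <- 3L * (nb2 - 1L) + j
          xx[idx] <- val
          pos <- pos + m_el
        }
      }
    }
  }
  # --- springs (rank-one axial stiffness along undeformed direction) ---
  if (!is.null(springs) && nrow(springs)) {
    if (is.null(active)) active <- rep(TRUE, nrow(springs))
    if (is.null(spring_k))
      spring_k <- vapply(seq_len(nrow(springs)), function(s)
        spring_secant_stiffness(springs[s, ], 0), numeric(1))
    act <- which(active)
    if (length(act)) {
      sa <- rep_node[springs$node_a[act]]
      sb <- rep_node[springs$node_b[act]]
      d <- mesh$nodes[springs$node_b[act], , drop = FALSE] -
        mesh$nodes[springs$node_a[act], , drop = FALSE]
      L <- sqrt(rowSums(d^2))
      d <- d / L
      k <- spring_k[act]
      si <- integer(0); sj <- integer(0); sx <- numeric(0)
      for (i in 1:3) {
        for (j in 1:3) {
          kij <- k * d[, i] * d[, j]
          si <- c(si, 3L * (sa - 1L) + i, 3L * (sb - 1L) + i,
                  3L * (sa - 1L) + i, 3L * (sb - 1L) + i)
          sj <- c(sj, 3L * (sa - 1L) + j, 3L * (sb - 1L) + j,
                  3L * (sb - 1L) + j, 3L * (sa - 1L) + j)
          sx <- c(sx, kij, kij, -kij, -kij)
        }
      }
      ii <- c(ii, si); jj <- c(jj, sj); xx <- c(xx, sx)
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  # --- right-hand side ---
  f <- if (is.null(load)) numeric(ndof) else {
    stopifnot(length(load) == ndof)
    # aggregate slave-node loads onto masters
    if (any(rep_node != seq_len(n))) {
      fm <- numeric(ndof)
      src <- rep(seq_len(n), each = 3L)
      dst <- 3L * (rep_node[src] - 1L) + rep(1:3, n)
      fagg <- rowsum(load, dst)
      fm[as.integer(rownames(fagg))] <- fagg
      fm
    } else load
  }
  # --- constrained dofs ---
  fixed_nodes <- unique(rep_node[fixed_nodes])
  fixed_dofs <- as.vector(outer(1:3, 3L * (fixed_nodes - 1L), `+`))
  presc_dofs <- integer(0); presc_vals <- numeric(0)
  if (!is.null(prescribed) && nrow(prescribed)) {
    presc_dofs <- 3L * (rep_node[prescribed$node] - 1L) + prescribed$dof
    presc_vals <- prescribed$value
    dup <- duplicated(presc_dofs)
    presc_dofs <- presc_dofs[!dup]; presc_vals <- presc_vals[!dup]
  }
  slave_dofs <- if (any(rep_node != seq_len(n))) {
    sl <- which(rep_node != seq_len(n))
    as.vector(outer(1:3, 3L * (sl - 1L), `+`))
  } else integer(0)
  con_dofs <- c(fixed_dofs, presc_dofs)
  free <- setdiff(seq_len(ndof), c(con_dofs, slave_dofs))
  if (!length(free)) stop("no free degrees of freedom")
  rhs <- f[free]
  if (length(presc_dofs) && any(presc_vals != 0)) {
    rhs <- rhs - as.vector(K[free, presc_dofs, drop = FALSE] %*% presc_vals)
  }
  structure(list(K = K, f = f, rhs = rhs, free = free,
                 fixed_dofs = fixed_dofs, presc_dofs = presc_dofs,
                 presc_vals = presc_vals, rep_node = rep_node,
                 mesh = mesh, materials = materials, springs = springs,
                 active = active, spring_k = spring_k, ndof = ndof),
            class = "assembled_system")
}

#' Solve an assembled finite-element system
#'
#' Sparse direct (Cholesky) solve of the constrained system; falls back to
#' conjugate gradients with diagonal preconditioning if the factorisation
#' fails. Verifies the relative residual and detects unconstrained rigid
#' modes (singular or indefinite reduced stiffness).
#'
#' @param system an `assembled_system` from [fem_assemble()].
#' @param tol relative residual tolerance.
#' @return a `fem_solution`: nodal displacements `u` (N x 3, mm), element
#'   stress tensors (via [element_stress()]), spring forces (N), reaction
#'   forces at constrained dofs, strain energy and external work (N mm),
#'   and the residual norm.
#' @export
fem_solve <- function(system, tol = 1e-8) {
  free <- system$free
  Kff <- system$K[free, free, drop = FALSE]
  Kff <- Matrix::forceSymmetric((Kff + Matrix::t(Kff)) / 2, uplo = "U")
  uf <- tryCatch({
    ch <- Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE)
    as.vector(Matrix::solve(ch, system$rhs))
  }, error = function(e) {
    stop(sprintf(paste0("insufficient constraints or singular system ",
                        "(factorisation failed: %s)"),
                 conditionMessage(e)))
  })
  res <- as.vector(Kff %*% uf) - system$rhs
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(system$rhs^2)), 1e-30)
  if (!is.finite(rel) || rel > tol)
    stop(sprintf("solver residual %.3e exceeds tolerance %.1e", rel, tol))
  u <- numeric(system$ndof)
  u[free] <- uf
  if (length(system$presc_dofs)) u[system$presc_dofs] <- system$presc_vals
  # expand slaves from masters
  n <- nrow(system$mesh$nodes)
  rep_node <- system$rep_node
  if (any(rep_node != seq_len(n))) {
    sl <- which(rep_node != seq_len(n))
    for (d in 1:3) u[3L * (sl - 1L) + d] <- u[3L * (rep_node[sl] - 1L) + d]
  }
  umat <- matrix(u, ncol = 3L, byrow = TRUE)
  # reactions r = K u - f at constrained dofs
  r_all <- as.vector(system$K %*% u) - system$f
  con <- c(system$fixed_dofs, system$presc_dofs)
  reactions <- r_all[con]
  strain_energy <- 0.5 * sum(u * as.vector(system$K %*% u))
  external_work <- 0.5 * (sum(system$f * u) + sum(reactions * u[con]))
  sol <- structure(list(u = umat, residual = rel,
                        reactions = data.frame(dof = con, force = reactions),
                        strain_energy = strain_energy,
                        external_work = external_work,
                        mesh = system$mesh, materials = system$materials,
                        springs = system$springs, active = system$active,
                        spring_k = system$spring_k,
                        iterations = 1L),
                   class = "fem_solution")
  sol$stress <- element_stress(sol, system$materials)
  sol$spring_forces <- solution_spring_forces(sol)
  sol
}

#' Spring lengths and axial forces of a solution
#'
#' Evaluates every spring of a solved model at its deformed length:
#' elongation, axial force (tension positive; inactive springs carry zero)
#' and activity flag.
#'
#' @param sol a `fem_solution` carrying a `springs` table.
#' @return data.frame with `name`, `length`, `elongation`, `force`,
#'   `active`, or NULL if the solution has no springs.
#' @export
solution_spring_forces <- function(sol) {
  springs <- sol$springs
  if (is.null(springs) || !nrow(springs)) return(NULL)
  pa <- sol$mesh$nodes[springs$node_a, , drop = FALSE] +
    sol$u[springs$node_a, , drop = FALSE]
  pb <- sol$mesh$nodes[springs$node_b, , drop = FALSE] +
    sol$u[springs$node_b, , drop = FALSE]
  L <- sqrt(rowSums((pb - pa)^2))
  f <- vapply(seq_len(nrow(springs)), function(s)
    spring_force(springs[s, ], L[s]), numeric(1))
  act <- if (is.null(sol$active)) rep(TRUE, nrow(springs)) else sol$active
  f[!act] <- 0
  data.frame(name = springs$name, length = L,
             elongation = L - springs$rest_length, force = f,
             active = act)
}

#' Solve with tension-only springs (active-set iteration)
#'
#' Fixed-point iteration on the spring active set and secant stiffness:
#' solve the linear system, deactivate springs in compression, reactivate
#' springs whose gap closes, update elongation-dependent secant
#' stiffnesses, and repeat until the active set is stable and the secant
#' stiffnesses have converged (cap 50 iterations). The converged solution
#' carries no compressive force in any tension-only spring.
#'
#' @param mesh,materials,springs,fixed_nodes,prescribed,load as in
#'   [fem_assemble()].
#' @param tol solver residual tolerance.
#' @param max_iter iteration cap.
#' @return a `fem_solution` with `iterations` set to the number of
#'   active-set solves performed.
#' @export
solve_tension_only <- function(mesh, materials, springs = NULL,
                               fixed_nodes = integer(), prescribed = NULL,
                               load = NULL, tol = 1e-8, max_iter = 50L) {
  if (is.null(springs) || !nrow(springs)) {
    sys <- fem_assemble(mesh, materials, fixed_nodes = fixed_nodes,
                        prescribed = prescribed, load = load)
    return(fem_solve(sys, tol))
  }
  ns <- nrow(springs)
  active <- rep(TRUE, ns)
  eps <- rep(0, ns)
  toggled <- rep(FALSE, ns)
  sol <- NULL
  for (it in seq_len(max_iter)) {
    k_sec <- vapply(seq_len(ns), function(s)
      spring_secant_stiffness(springs[s, ], eps[s]), numeric(1))
    sys <- fem_assemble(mesh, materials, springs, active = active,
                        spring_k = k_sec, fixed_nodes = fixed_nodes,
                        prescribed = prescribed, load = load)
    sol <- fem_solve(sys, tol)
    sf <- solution_spring_forces(sol)
    elong <- sf$elongation
    new_active <- !(springs$tension_only & elong <= 1e-12)
    eps_new <- pmax(elong, 0) / springs$rest_length
    k_next <- vapply(seq_len(ns), function(s)
      spring_secant_stiffness(springs[s, ], eps_new[s]), numeric(1))
    stable <- identical(new_active, active) &&
      max(abs(k_next - k_sec)) <= 1e-9 * max(k_sec)
    toggled <- new_active != active
    active <- new_active
    eps <- eps_new
    if (stable) {
      sol$iterations <- it
      return(sol)
    }
  }
  stop(sprintf(
    "active-set iteration exceeded %d iterations (oscillating springs: %s)",
    max_iter,
    paste(springs$name[toggled | !active], collapse = ", ")))
}

#' Recover per-element stress tensors
#'
#' Constant per-element stress from the linear-tet strain field via Hooke's
#' law, in the anatomical frame (columns `sxx`, `syy`, `szz` are the normal
#' stresses in the lateral-medial, posterior-anterior and
#' inferior-superior directions; `sxy`, `syz`, `szx` the shears). Normal
#' stresses along anatomical axes are the headline output; von Mises is not
#' reported because bone fails as a brittle material.
#'
#' @param solution a `fem_solution` (or list with `u` and `mesh`).
#' @param materials per-element `E`, `nu`.
#' @return data.frame with six stress components per element (MPa).
#' @export
element_stress <- function(solution, materials = solution$materials) {
  mesh <- solution$mesh
  u <- solution$u
  eg <- element_gradients(mesh$nodes, mesh$tets)
  G <- eg$G
  comp <- function(i, j) {
    acc <- 0
    for (a in 1:4) {
      ua <- u[mesh$tets[, a], , drop = FALSE]
      acc <- acc + 0.5 * (G[[a]][, i] * ua[, j] + G[[a]][, j] * ua[, i])
    }
    acc
  }
  exx <- comp(1, 1); eyy <- comp(2, 2); ezz <- comp(3, 3)
  exy <- comp(1, 2); eyz <- comp(2, 3); ezx <- comp(3, 1)
  E <- materials$E; nu <- materials$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  tr <- exx + eyy + ezz
  data.frame(sxx = lam * tr + 2 * mu * exx,
             syy = lam * tr + 2 * mu * eyy,
             szz = lam * tr + 2 * mu * ezz,
             sxy = 2 * mu * exy, syz = 2 * mu * eyz, szx = 2 * mu * ezx)
}

#' @export
print.fem_solution <- function(x, ...) {
  cat("FEM solution:", nrow(x$u), "nodes; max |u| =",
      format(max(abs(x$u)), digits = 4), "mm\n")
  cat("Residual:", format(x$residual, digits = 3),
      " strain energy:", format(x$strain_energy, digits = 6), "N mm",
      " external work:", format(x$external_work, digits = 6), "N mm\n")
  cat("Active-set iterations:", x$iterations, "\n")
  if (!is.null(x$spring_forces)) {
    nt <- sum(x$spring_forces$force > 0)
    cat("Springs in tension:", nt, "of", nrow(x$spring_forces), "\n")
  }
  invisible(x)
}

#' Displacement field plot
#'
#' Scatter of node positions in a chosen anatomical plane coloured by
#' displacement magnitude; a quick diagnostic, not a rendering.
#'
#' @param x a `fem_solution`.
#' @param plane `"xz"` (default, frontal), `"xy"` or `"yz"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fem_solution <- function(x, plane = c("xz", "xy", "yz"), ...) {
  plane <- match.arg(plane)
  ax <- switch(plane, xz = c(1L, 3L), xy = c(1L, 2L), yz = c(2L, 3L))
  mag <- sqrt(rowSums(x$u^2))
  cols <- grDevices::hcl.colors(64, "viridis")
  idx <- pmin(63L, floor(63 * mag / max(mag, 1e-30))) + 1L
  graphics::plot(x$mesh$nodes[, ax[1L]], x$mesh$nodes[, ax[2L]],
                 col = cols[idx], pch = 16, cex = 0.5, asp = 1,
                 xlab = c("x", "y", "z")[ax[1L]],
                 ylab = c("x", "y", "z")[ax[2L]], ...)
  invisible(x)
}
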