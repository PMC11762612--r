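# Shared, lazily built fixtures.  Everything is generated in code; the
# expensive runs (full construct comparison, convergence) are built once per
# test session and reused.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

default_phantom <- function() {
  fixture("phantom", function() build_phantom(phantom_params()))
}

noiseless_phantom <- function() {
  fixture("phantom0", function()
    build_phantom(phantom_params(hu_noise_sd = 0)))
}

default_comparison <- function() {
  fixture("comparison", function() compare_constructs())
}

# independent oracle: constant-strain-tet stiffness via explicit B-matrix
# assembly (Ke = V * B' D B), a different formulation from the package's
# closed-form gradient blocks
bmatrix_tet_stiffness <- function(coords, E, nu) {
  J <- coords[2:4, ] - matrix(coords[1, ], 3, 3, byrow = TRUE)
  V <- det(J) / 6
  Jinv <- solve(J)
  G <- rbind(-colSums(t(Jinv)), t(Jinv))  # 4 x 3 gradient rows
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- G[a, 1]
    B[2, c0 + 2] <- G[a, 2]
    B[3, c0 + 3] <- G[a, 3]
    B[4, c0 + 1] <- G[a, 2]; B[4, c0 + 2] <- G[a, 1]
    B[5, c0 + 2] <- G[a, 3]; B[5, c0 + 3] <- G[a, 2]
    B[6, c0 + 1] <- G[a, 3]; B[6, c0 + 3] <- G[a, 1]
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  V * t(B) %*% D %*% B
}

# uniform-material table for an arbitrary mesh
unimat <- function(mesh, E = 1000, nu = 0.3) {
  data.frame(element = seq_len(nrow(mesh$tets)), E = E, nu = nu)
}

# sum of reaction forces per component over all constrained dofs
reaction_sums <- function(sol) {
  comp <- (sol$reactions$dof - 1L) %% 3L + 1L
  vapply(1:3, function(d) sum(sol$reactions$force[comp == d]), numeric(1))
}

# seesaw rig: a beam block clamped along its bottom mid column plus two
# fully fixed anchor blocks above the beam ends; one tension spring from
# each beam end up to its anchor.  Loading one beam end downward stretches
# that end's spring and slackens the other.
seesaw_rig <- function() {
  boxes <- data.frame(
    region = c("beam", "anchor_l", "anchor_r"),
    x0 = c(0, 0, 9), x1 = c(10, 1, 10),
    y0 = c(0, 0, 0), y1 = c(1, 1, 1),
    z0 = c(0, 3, 3), z1 = c(1, 4, 4))
  mesh <- lattice_mesh(boxes, 1)
  nd <- mesh$nodes
  near <- function(pt, regions) {
    cand <- region_nodes(mesh, regions)
    cand[which.min(colSums((t(nd[cand, , drop = FALSE]) - pt)^2))]
  }
  ends <- c(near(c(0.0, 0.5, 1), "beam"), near(c(10, 0.5, 1), "beam"))
  anchors <- c(near(c(0.0, 0.5, 3), "anchor_l"), near(c(10, 0.5, 3), "anchor_r"))
  springs <- data.frame(
    name = c("left", "right"),
    node_a = ends, node_b = anchors,
    rest_length = sqrt(rowSums((nd[anchors, ] - nd[ends, ])^2)),
    k_low = 50, k_high = 50, breakpoint_strain = NA_real_,
    tension_only = TRUE)
  mid <- which(abs(nd[, 1] - 5) < 1e-9 & abs(nd[, 3]) < 1e-9)
  fixed <- c(mid, region_nodes(mesh, c("anchor_l", "anchor_r")))
  tip <- near(c(10, 0.5, 0), "beam")
  f <- numeric(3 * nrow(nd))
  f[3 * (tip - 1) + 3] <- -40      # push the right end down
  list(mesh = mesh, springs = springs, fixed = fixed, load = f)
}

# brute-force oracle: enumerate all activation subsets, keep those whose
# solution is self-consistent (active springs elongated, inactive slack)
seesaw_consistent_sets <- function(rig) {
  mat <- unimat(rig$mesh, E = 1e6, nu = 0.3)
  ns <- nrow(rig$springs)
  ok <- list()
  for (mask in 0:(2^ns - 1)) {
    act <- as.logical(bitwAnd(mask, 2^(seq_len(ns) - 1)) > 0)
    sys <- fem_assemble(rig$mesh, mat, rig$springs, active = act,
                        fixed_nodes = rig$fixed, load = rig$load)
    # a pattern whose system is floppy (rigid mode not held by any active
    # spring) cannot be an equilibrium state
    sol <- tryCatch(suppressWarnings(fem_solve(sys)),
                    error = function(e) NULL)
    if (is.null(sol)) next
    sol$active <- act
    sf <- solution_spring_forces(sol)
    elong <- sf$elongation
    consistent <- all(elong[act] >= -1e-9) && all(elong[!act] <= 1e-9)
    if (consistent) ok[[length(ok) + 1]] <- act
  }
  ok
}
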