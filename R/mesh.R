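#' Labeled tetrahedral mesh
#'
#' Container for a linear tetrahedral mesh in the anatomical frame used
#' throughout the package: x runs left to right (lateral-medial), y posterior
#' to anterior, z inferior to superior, all coordinates in millimetres.
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z (mm).
#' @param tets integer matrix, one row per element, four node indices.
#' @param region character or factor of length `nrow(tets)`; exactly one
#'   region label per element (e.g. `"sacrum_S1_left"`, `"cartilage_si_right"`,
#'   `"screw_tsi"`).
#' @param patches named list of integer node-index vectors (surface patches:
#'   acetabula, S1 endplate, ligament attachment sites, fracture faces).
#' @param fracture_pairs list of fracture face pairs, each a list with
#'   integer vectors `node_a` (medial face) and `node_b` (lateral face) in
#'   bijection, a unit `axis` (medial-to-lateral measurement direction) and a
#'   `site` name.
#' @param ties data.frame with columns `slave`, `master`: bonded node pairs
#'   eliminated during assembly.
#' @param h nominal lattice edge length (mm), kept for provenance.
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, region, patches = list(),
                     fracture_pairs = list(), ties = NULL, h = NA_real_) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  stopifnot(ncol(nodes) == 3L, ncol(tets) == 4L)
  region <- as.character(region)
  if (length(region) != nrow(tets))
    stop("one region label per element required")
  if (is.null(ties)) ties <- data.frame(slave = integer(), master = integer())
  m <- structure(list(nodes = nodes, tets = tets, region = region,
                      patches = patches, fracture_pairs = fracture_pairs,
                      ties = ties, h = h),
                 class = "tet_mesh")
  validate_mesh(m)
  m
}

#' Validate a tetrahedral mesh
#'
#' Checks connectivity bounds, positive element volumes (consistent
#' orientation), patch index validity and fracture-pair bijections.
#'
#' @param mesh a [tet_mesh].
#' @return `mesh`, invisibly; errors describe the first violation found.
#' @export
validate_mesh <- function(mesh) {
  n <- nrow(mesh$nodes)
  if (any(mesh$tets < 1L) || any(mesh$tets > n))
    stop("tet connectivity references invalid nodes")
  v <- tet_volumes(mesh$nodes, mesh$tets)
  if (any(v <= 0)) {
    bad <- which(v <= 0)
    stop(sprintf("%d non-positive-volume tets (first: element %d)",
                 length(bad), bad[1L]))
  }
  for (nm in names(mesh$patches)) {
    p <- mesh$patches[[nm]]
    if (length(p) && (any(p < 1L) || any(p > n)))
      stop(sprintf("patch '%s' references invalid nodes", nm))
  }
  for (fp in mesh$fracture_pairs) {
    if (length(fp$node_a) != length(fp$node_b))
      stop(sprintf("fracture pair '%s' has unequal node counts", fp$site))
  }
  invisible(mesh)
}

#' Signed tetrahedron volumes
#'
#' @param nodes node coordinate matrix (mm).
#' @param tets element connectivity matrix.
#' @return numeric vector of signed volumes (mm^3); positive for
#'   consistently oriented elements.
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 3L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
  c3 <- nodes[tets[, 4L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
  # triple product a . (b x c) / 6
  (a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) +
   a[, 2L] * (b[, 3L] * c3[, 1L] - b[, 1L] * c3[, 3L]) +
   a[, 3L] * (b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])) / 6
}

#' Element centroids
#' @param mesh a [tet_mesh].
#' @return matrix of element centroid coordinates (mm).
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 2L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 3L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 4L], , drop = FALSE]) / 4
}

# Kuhn subdivision of a hexahedral cell into 6 tets, corners indexed
# 1 + dx + 2*dy + 4*dz.  Each row is one tet; orientation fixed at build.
.kuhn_tets <- rbind(
  c(1L, 2L, 4L, 8L),
  c(1L, 2L, 6L, 8L),
  c(1L, 3L, 4L, 8L),
  c(1L, 3L, 7L, 8L),
  c(1L, 5L, 6L, 8L),
  c(1L, 5L, 7L, 8L)
)

# mirror image of the Kuhn pattern about the x axis (corner dx bit
# flipped): used for voxels left of the mid-sagittal plane so the
# tetrahedralisation — not only the node set — is mirror-symmetric
.kuhn_mirror <- matrix(c(2L, 1L, 4L, 3L, 6L, 5L, 8L, 7L)[.kuhn_tets],
                       nrow = nrow(.kuhn_tets))

#' Mesh a union of axis-aligned boxes on a voxel lattice
#'
#' Builds a linear tetrahedral mesh by rasterising a prioritised list of
#' labeled boxes onto a uniform voxel lattice and splitting every occupied
#' voxel into six positively oriented tetrahedra. Voxels take the label of
#' the first box containing their centre, so earlier boxes win overlaps.
#' Shared lattice nodes weld adjacent boxes into one connected solid.
#'
#' @param boxes data.frame with columns `region`, `x0,x1,y0,y1,z0,z1` (mm).
#' @param h target edge length (mm); the realised spacing per axis is the
#'   bounding extent divided by `round(extent / h)`.
#' @return a [tet_mesh] with per-element `region` labels and an attribute
#'   `voxel` (data.frame of voxel centres and indices, one row per voxel,
#'   used to attach voxel-wise fields such as HU).
#' @export
lattice_mesh <- function(boxes, h) {
  stopifnot(is.data.frame(boxes), h > 0)
  bb <- c(min(boxes$x0), max(boxes$x1), min(boxes$y0), max(boxes$y1),
          min(boxes$z0), max(boxes$z1))
  ext <- c(bb[2L] - bb[1L], bb[4L] - bb[3L], bb[6L] - bb[5L])
  nvox <- pmax(1L, as.integer(round(ext / h)))
  hx <- ext / nvox
  cx <- bb[1L] + (seq_len(nvox[1L]) - 0.5) * hx[1L]
  cy <- bb[3L] + (seq_len(nvox[2L]) - 0.5) * hx[2L]
  cz <- bb[5L] + (seq_len(nvox[3L]) - 0.5) * hx[3L]
  cen <- expand.grid(x = cx, y = cy, z = cz, KEEP.OUT.ATTRS = FALSE)
  lab <- rep(NA_character_, nrow(cen))
  eps <- 1e-9
  for (r in seq_len(nrow(boxes))) {
    b <- boxes[r, ]
    # x-membership mirrored for boxes left of the mid-sagittal plane so a
    # box and its reflection capture mirror-image voxel sets exactly
    in_x <- if (b$x1 <= eps) {
      cen$x > b$x0 + eps & cen$x <= b$x1 + eps
    } else {
      cen$x >= b$x0 - eps & cen$x < b$x1 - eps
    }
    inside <- is.na(lab) & in_x &
      cen$y >= b$y0 - eps & cen$y < b$y1 - eps &
      cen$z >= b$z0 - eps & cen$z < b$z1 - eps
    lab[inside] <- b$region
  }
  keep <- which(!is.na(lab))
  if (!length(keep)) stop("no voxels inside any box; degenerate geometry")
  # voxel integer indices
  ii <- arrayInd(keep, nvox)
  # node lattice ids for the 8 corners of each voxel
  nnx <- nvox + 1L
  nid <- function(i, j, k) (k - 1L) * nnx[1L] * nnx[2L] + (j - 1L) * nnx[1L] + i
  corn <- matrix(0L, nrow = length(keep), ncol = 8L)
  c_off <- cbind(dx = c(0L,1L,0L,1L,0L,1L,0L,1L),
                 dy = c(0L,0L,1L,1L,0L,0L,1L,1L),
                 dz = c(0L,0L,0L,0L,1L,1L,1L,1L))
  for (c8 in 1:8) {
    corn[, c8] <- nid(ii[, 1L] + c_off[c8, 1L],
                      ii[, 2L] + c_off[c8, 2L],
                      ii[, 3L] + c_off[c8, 3L])
  }
  used <- sort(unique(as.vector(corn)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  # node coordinates from lattice ids
  k <- (used - 1L) %/% (nnx[1L] * nnx[2L])
  rem <- (used - 1L) %% (nnx[1L] * nnx[2L])
  j <- rem %/% nnx[1L]
  i <- rem %% nnx[1L]
  nodes <- cbind(bb[1L] + i * hx[1L], bb[3L] + j * hx[2L], bb[5L] + k * hx[3L])
  corn <- matrix(remap[corn], nrow = nrow(corn))
  nv <- nrow(corn)
  left <- cen$x[keep] < 0
  tets <- matrix(0L, nrow = 6L * nv, ncol = 4L)
  for (t6 in 1:6) {
    rows <- seq.int(t6, by = 6L, length.out = nv)
    tets[rows[!left], ] <- corn[!left, .kuhn_tets[t6, ], drop = FALSE]
    tets[rows[left], ] <- corn[left, .kuhn_mirror[t6, ], drop = FALSE]
  }
  region <- rep(lab[keep], each = 6L)
  # enforce positive orientation generically
  v <- tet_volumes(nodes, tets)
  neg <- v < 0
  if (any(neg)) tets[neg, c(3L, 4L)] <- tets[neg, c(4L, 3L)]
  vox <- data.frame(x = cen$x[keep], y = cen$y[keep], z = cen$z[keep],
                    i = ii[, 1L], j = ii[, 2L], k = ii[, 3L],
                    region = lab[keep], stringsAsFactors = FALSE)
  m <- tet_mesh(nodes, tets, region, h = max(hx))
  attr(m, "voxel") <- vox
  attr(m, "spacing") <- hx
  m
}

#' Rectangular block benchmark mesh
#'
#' Convenience mesher for verification problems (patch tests, cantilever
#' benchmark): a single box of given extents, with face patches named
#' `xmin`, `xmax`, `ymin`, `ymax`, `zmin`, `zmax`.
#'
#' @param lx,ly,lz box extents (mm).
#' @param h target edge length (mm).
#' @return a [tet_mesh] with the six face patches.
#' @export
box_mesh <- function(lx, ly, lz, h) {
  boxes <- data.frame(region = "block", x0 = 0, x1 = lx, y0 = 0, y1 = ly,
                      z0 = 0, z1 = lz, stringsAsFactors = FALSE)
  m <- lattice_mesh(boxes, h)
  tol <- 1e-9
  nd <- m$nodes
  m$patches <- list(
    xmin = which(abs(nd[, 1L]) < tol),
    xmax = which(abs(nd[, 1L] - lx) < tol),
    ymin = which(abs(nd[, 2L]) < tol),
    ymax = which(abs(nd[, 2L] - ly) < tol),
    zmin = which(abs(nd[, 3L]) < tol),
    zmax = which(abs(nd[, 3L] - lz) < tol))
  m
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("Tetrahedral mesh:", nrow(x$nodes), "nodes,", nrow(x$tets),
      "elements, lattice h =", format(x$h), "mm\n")
  tb <- sort(table(x$region), decreasing = TRUE)
  cat("Regions:", paste0(names(tb), " (", as.integer(tb), ")",
                         collapse = ", "), "\n")
  if (length(x$patches))
    cat("Patches:", paste(names(x$patches), collapse = ", "), "\n")
  if (length(x$fracture_pairs))
    cat("Fracture face pairs:",
        paste(vapply(x$fracture_pairs, `[[`, "", "site"), collapse = ", "),
        "\n")
  if (nrow(x$ties)) cat("Tie constraints:", nrow(x$ties), "node pairs\n")
  invisible(x)
}

#' @export
summary.tet_mesh <- function(object, ...) {
  v <- tet_volumes(object$nodes, object$tets)
  out <- list(n_nodes = nrow(object$nodes), n_elements = nrow(object$tets),
              total_volume = sum(v),
              volume_by_region = tapply(v, object$region, sum),
              bbox = apply(object$nodes, 2L, range))
  class(out) <- "summary.tet_mesh"
  out
}

#' @export
print.summary.tet_mesh <- function(x, ...) {
  cat("Nodes:", x$n_nodes, " Elements:", x$n_elements, "\n")
  cat("Total volume:", format(x$total_volume), "mm^3\n")
  print(round(x$volume_by_region, 1))
  invisible(x)
}

#' Nodes used by elements of given regions
#' @param mesh a [tet_mesh].
#' @param regions character vector of region labels.
#' @return sorted integer vector of node indices.
#' @export
region_nodes <- function(mesh, regions) {
  sort(unique(as.vector(mesh$tets[mesh$region %in% regions, , drop = FALSE])))
}
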