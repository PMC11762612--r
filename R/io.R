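#' Write a mesh in Gmsh MSH 2.2 ascii format
#'
#' Region labels are written as physical tags via `$PhysicalNames`;
#' connectivity and coordinates round-trip exactly at 12 significant
#' digits. Patches and fracture pairs are not representable in MSH; use VTU
#' to preserve them.
#'
#' @param mesh a [tet_mesh].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_mesh_msh <- function(mesh, file) {
  lev <- sort(unique(mesh$region))
  rid <- match(mesh$region, lev)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$PhysicalNames", as.character(length(lev))), con)
  writeLines(sprintf("3 %d \"%s\"", seq_along(lev), lev), con)
  writeLines(c("$EndPhysicalNames", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.12g %.12g %.12g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]),
             con)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(mesh$tets))), con)
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", seq_len(nrow(mesh$tets)),
                     rid, rid, mesh$tets[, 1L], mesh$tets[, 2L],
                     mesh$tets[, 3L], mesh$tets[, 4L]), con)
  writeLines("$EndElements", con)
  invisible(file)
}

#' Read a Gmsh MSH 2.2 ascii mesh
#'
#' @param file path to an MSH 2.2 file with tetrahedral (type 4) elements.
#' @return a [tet_mesh].
#' @export
read_mesh_msh <- function(file) {
  ln <- readLines(file)
  sec <- function(name) {
    a <- which(ln == paste0("$", name)) + 1L
    b <- which(ln == paste0("$End", name)) - 1L
    if (!length(a) || !length(b)) stop(sprintf("MSH section %s missing", name))
    ln[a:b]
  }
  fmt <- strsplit(sec("MeshFormat")[1L], " ")[[1L]]
  if (fmt[1L] != "2.2") stop("only MSH format 2.2 ascii is supported")
  phys <- sec("PhysicalNames")
  nph <- as.integer(phys[1L])
  names_map <- character(nph)
  for (i in seq_len(nph)) {
    parts <- strsplit(phys[1L + i], " ")[[1L]]
    id <- as.integer(parts[2L])
    names_map[id] <- gsub('"', "", paste(parts[-(1:2)], collapse = " "))
  }
  nl <- sec("Nodes")
  nn <- as.integer(nl[1L])
  nm <- matrix(as.numeric(unlist(strsplit(nl[1L + seq_len(nn)], " "))),
               ncol = 4L, byrow = TRUE)
  el <- sec("Elements")
  ne <- as.integer(el[1L])
  em <- strsplit(el[1L + seq_len(ne)], " ")
  keep <- vapply(em, function(x) x[2L] == "4", logical(1))
  em <- em[keep]
  tets <- t(vapply(em, function(x) {
    ntags <- as.integer(x[3L])
    as.integer(x[(4L + ntags):(3L + ntags + 4L)])
  }, integer(4)))
  rid <- vapply(em, function(x) as.integer(x[4L]), integer(1))
  tet_mesh(nm[order(nm[, 1L]), 2:4, drop = FALSE], tets, names_map[rid])
}

# ascii float formatting used in VTU files
.fmt <- function(x) format(x, digits = 15, scientific = TRUE, trim = TRUE)

#' Write a mesh (optionally with a solution) as VTK VTU XML
#'
#' Ascii `UnstructuredGrid` file: region labels as integer cell data (with
#' the label dictionary in a `FieldData`-style comment), patches as 0/1
#' point-data arrays, per-element HU / material / stress fields as cell
#' data, nodal displacements as point data. Readable by ParaView and by
#' [read_mesh_vtu()].
#'
#' @param mesh a [tet_mesh].
#' @param file output path.
#' @param point_data named list of per-node vectors or 3-column matrices.
#' @param cell_data named list of per-element vectors.
#' @return `file`, invisibly.
#' @export
write_mesh_vtu <- function(mesh, file, point_data = list(),
                           cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  lev <- sort(unique(mesh$region))
  rid <- match(mesh$region, lev) - 1L
  out <- c('<?xml version="1.0"?>',
           sprintf('<!-- region_levels: %s -->', paste(lev, collapse = ";")),
           '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
           '  <UnstructuredGrid>',
           sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  da <- function(name, type, ncomp, values) {
    c(sprintf('        <DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">',
              type, name, ncomp),
      paste0("          ", paste(values, collapse = " ")),
      '        </DataArray>')
  }
  out <- c(out, '      <Points>',
           da("Points", "Float64", 3L, .fmt(as.vector(t(mesh$nodes)))),
           '      </Points>', '      <Cells>',
           da("connectivity", "Int64", 1L, as.vector(t(mesh$tets)) - 1L),
           da("offsets", "Int64", 1L, seq_len(m) * 4L),
           da("types", "UInt8", 1L, rep(10L, m)),
           '      </Cells>')
  pd <- c('      <PointData>')
  for (p in names(mesh$patches)) {
    # rank encoding (0 = not in patch) so patch node ordering survives
    v <- integer(n); v[mesh$patches[[p]]] <- seq_along(mesh$patches[[p]])
    pd <- c(pd, da(paste0("patch_", p), "Int32", 1L, v))
  }
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    if (is.matrix(v)) pd <- c(pd, da(nm, "Float64", ncol(v),
                                     .fmt(as.vector(t(v)))))
    else pd <- c(pd, da(nm, "Float64", 1L, .fmt(v)))
  }
  pd <- c(pd, '      </PointData>')
  cd <- c('      <CellData>', da("region_id", "Int32", 1L, rid))
  for (nm in names(cell_data)) {
    cd <- c(cd, da(nm, "Float64", 1L, .fmt(cell_data[[nm]])))
  }
  cd <- c(cd, '      </CellData>')
  out <- c(out, pd, cd, '    </Piece>', '  </UnstructuredGrid>',
           '</VTKFile>')
  writeLines(out, file)
  invisible(file)
}

#' Read a VTU file written by [write_mesh_vtu()]
#'
#' @param file path to an ascii VTU UnstructuredGrid file with tet cells.
#' @return list with `mesh` (a [tet_mesh], patches restored), `point_data`
#'   and `cell_data` (named lists).
#' @export
read_mesh_vtu <- function(file) {
  txt <- readLines(file)
  lev <- NULL
  cm <- grep("region_levels:", txt, value = TRUE)
  if (length(cm))
    lev <- strsplit(sub(".*region_levels: *", "",
                        sub(" *-->.*", "", cm[1L])), ";")[[1L]]
  doc <- xml2::read_xml(file)
  arrays <- xml2::xml_find_all(doc, ".//*[local-name()='DataArray']")
  get_arr <- function(name) {
    for (a in arrays) {
      if (identical(xml2::xml_attr(a, "Name"), name))
        return(as.numeric(strsplit(trimws(xml2::xml_text(a)),
                                   "[ \n\t]+")[[1L]]))
    }
    NULL
  }
  pts <- matrix(get_arr("Points"), ncol = 3L, byrow = TRUE)
  conn <- matrix(as.integer(get_arr("connectivity")), ncol = 4L,
                 byrow = TRUE) + 1L
  types <- as.integer(get_arr("types"))
  if (any(types != 10L)) stop("VTU contains non-tetrahedral cells")
  rid <- as.integer(get_arr("region_id"))
  region <- if (!is.null(lev)) lev[rid + 1L] else as.character(rid)
  patches <- list(); point_data <- list(); cell_data <- list()
  for (a in arrays) {
    nm <- xml2::xml_attr(a, "Name")
    if (is.na(nm) ||
        nm %in% c("Points", "connectivity", "offsets", "types", "region_id"))
      next
    vals <- as.numeric(strsplit(trimws(xml2::xml_text(a)), "[ \n\t]+")[[1L]])
    ncomp <- as.integer(xml2::xml_attr(a, "NumberOfComponents"))
    if (startsWith(nm, "patch_")) {
      idx <- which(vals > 0)
      patches[[sub("^patch_", "", nm)]] <- idx[order(vals[idx])]
    } else if (length(vals) == nrow(conn)) {
      cell_data[[nm]] <- vals
    } else if (ncomp > 1L) {
      point_data[[nm]] <- matrix(vals, ncol = ncomp, byrow = TRUE)
    } else {
      point_data[[nm]] <- vals
    }
  }
  mesh <- tet_mesh(pts, conn, region, patches = patches)
  list(mesh = mesh, point_data = point_data, cell_data = cell_data)
}

#' Write a solved load case as VTU
#'
#' @param solution a `fem_solution`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_solution_vtu <- function(solution, file) {
  s <- solution$stress
  write_mesh_vtu(solution$mesh, file,
                 point_data = list(displacement = solution$u),
                 cell_data = as.list(s))
}

#' Read an ascii STL surface
#'
#' Parses facets, welds coincident vertices and rejects files containing
#' degenerate (zero-area) triangles, reporting how many offend.
#'
#' @param file path to an ascii STL file.
#' @param tol vertex welding / degeneracy tolerance.
#' @return list with `vertices` (V x 3) and `faces` (F x 3 indices).
#' @export
read_stl <- function(file, tol = 1e-9) {
  ln <- trimws(readLines(file))
  vx <- ln[startsWith(ln, "vertex")]
  if (!length(vx) || length(vx) %% 3L != 0L)
    stop("not a valid ascii STL (vertex count not a multiple of 3)")
  v <- matrix(as.numeric(unlist(strsplit(sub("^vertex +", "", vx),
                                         " +"))), ncol = 3L, byrow = TRUE)
  key <- apply(round(v / max(tol, 1e-12)) * tol, 1L, paste, collapse = "_")
  uid <- !duplicated(key)
  verts <- v[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  e1 <- verts[faces[, 2L], , drop = FALSE] - verts[faces[, 1L], , drop = FALSE]
  e2 <- verts[faces[, 3L], , drop = FALSE] - verts[faces[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  area2 <- sqrt(rowSums(cr^2))
  ndeg <- sum(area2 <= tol)
  if (ndeg > 0)
    stop(sprintf("STL rejected: %d degenerate triangles", ndeg))
  list(vertices = verts, faces = faces)
}

#' Write / read the per-element HU table as CSV
#' @param hu_table data.frame `element`, `hu`.
#' @param file path.
#' @return `file` (write) or the table (read).
#' @export
write_hu_csv <- function(hu_table, file) {
  utils::write.csv(hu_table, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_hu_csv
#' @export
read_hu_csv <- function(file) {
  utils::read.csv(file)
}

#' Round-trip an object through a mesh format
#'
#' Writes the object to a temporary file in the requested format, reads it
#' back and verifies that coordinates, connectivity and labels are
#' reproduced (within 1e-12 for coordinates). Supported: `"msh"`, `"vtu"`
#' for meshes; `"vtu"` for solutions.
#'
#' @param obj a [tet_mesh] or `fem_solution`.
#' @param format `"msh"` or `"vtu"`.
#' @return the re-read object.
#' @export
io_roundtrip <- function(obj, format = c("vtu", "msh")) {
  supported <- c("vtu", "msh")
  if (!format[1L] %in% supported)
    stop(sprintf("unsupported format '%s' (supported: %s)", format[1L],
                 paste(supported, collapse = ", ")))
  format <- match.arg(format)
  tf <- tempfile(fileext = paste0(".", format))
  on.exit(unlink(tf))
  if (inherits(obj, "fem_solution")) {
    if (format != "vtu") stop("solutions round-trip through VTU only")
    write_solution_vtu(obj, tf)
    back <- read_mesh_vtu(tf)
    if (max(abs(back$point_data$displacement - obj$u)) > 1e-12)
      stop("displacement field did not round-trip")
    return(back)
  }
  if (format == "msh") {
    write_mesh_msh(obj, tf)
    back <- read_mesh_msh(tf)
  } else {
    write_mesh_vtu(obj, tf)
    back <- read_mesh_vtu(tf)$mesh
  }
  if (max(abs(back$nodes - obj$nodes)) > 1e-12)
    stop("node coordinates did not round-trip")
  if (!identical(unname(back$tets), unname(obj$tets)))
    stop("connectivity did not round-trip")
  if (!identical(back$region, obj$region))
    stop("region labels did not round-trip")
  back
}
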