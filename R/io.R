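# Plain-text file plumbing: ASCII VTU (XML unstructured grid) writing and
# reading, Gmsh MSH 2.2 import with physical-group -> region-tag mapping,
# and JSON round-tripping of frame sets. Full 17-significant-digit decimal
# is used everywhere so doubles survive write/read bit-identically.

.fmt <- function(x) sprintf("%.17g", x)

#' Write an ASCII VTU file
#'
#' @param path output file.
#' @param vertices n x 3 coordinates (m).
#' @param cells m x 4 tets or m x 3 triangles (1-based).
#' @param point_data named list of per-vertex vectors/matrices.
#' @param cell_data named list of per-cell vectors.
#' @return the path, invisibly.
#' @export
write_vtu <- function(path, vertices, cells, point_data = list(),
                      cell_data = list()) {
  nc <- ncol(cells)
  stopifnot(nc %in% c(3L, 4L))
  vtk_type <- if (nc == 4L) 10L else 5L
  n <- nrow(vertices)
  m <- nrow(cells)
  da <- function(name, x, comps = 1L) {
    sprintf(
      '    <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n    </DataArray>',
      name, comps, paste(.fmt(t(x)), collapse = " ")
    )
  }
  pd <- if (length(point_data)) {
    paste0("   <PointData>\n", paste(vapply(names(point_data), function(nm) {
      x <- point_data[[nm]]
      comps <- if (is.matrix(x)) ncol(x) else 1L
      da(nm, if (is.matrix(x)) x else matrix(x, ncol = 1), comps)
    }, character(1)), collapse = "\n"), "\n   </PointData>\n")
  } else ""
  cd <- if (length(cell_data)) {
    paste0("   <CellData>\n", paste(vapply(names(cell_data), function(nm) {
      da(nm, matrix(cell_data[[nm]], ncol = 1), 1L)
    }, character(1)), collapse = "\n"), "\n   </CellData>\n")
  } else ""
  txt <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
    " <UnstructuredGrid>\n",
    sprintf('  <Piece NumberOfPoints="%d" NumberOfCells="%d">\n', n, m),
    "   <Points>\n",
    sprintf('    <DataArray type="Float64" NumberOfComponents="3" format="ascii">\n%s\n    </DataArray>\n',
            paste(.fmt(t(vertices)), collapse = " ")),
    "   </Points>\n",
    "   <Cells>\n",
    sprintf('    <DataArray type="Int64" Name="connectivity" format="ascii">\n%s\n    </DataArray>\n',
            paste(t(cells) - 1L, collapse = " ")),
    sprintf('    <DataArray type="Int64" Name="offsets" format="ascii">\n%s\n    </DataArray>\n',
            paste(seq_len(m) * nc, collapse = " ")),
    sprintf('    <DataArray type="UInt8" Name="types" format="ascii">\n%s\n    </DataArray>\n',
            paste(rep(vtk_type, m), collapse = " ")),
    "   </Cells>\n",
    pd, cd,
    "  </Piece>\n </UnstructuredGrid>\n</VTKFile>\n"
  )
  writeLines(txt, path)
  invisible(path)
}

#' Read an ASCII VTU file written by [write_vtu()] (or compatible)
#'
#' @param path input file.
#' @return list with `vertices`, `cells` (1-based), `point_data`,
#'   `cell_data`.
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) {
    stop(sprintf("format error in '%s': no <Piece>", path))
  }
  nums <- function(node) {
    as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
  }
  pts <- xml2::xml_find_first(piece, ".//Points/DataArray")
  vertices <- matrix(nums(pts), ncol = 3, byrow = TRUE)
  conn <- nums(xml2::xml_find_first(
    piece, ".//Cells/DataArray[@Name='connectivity']"
  ))
  offs <- nums(xml2::xml_find_first(
    piece, ".//Cells/DataArray[@Name='offsets']"
  ))
  nc <- offs[1]
  if (any(diff(offs) != nc)) {
    stop(sprintf("format error in '%s': mixed cell types", path))
  }
  cells <- matrix(as.integer(conn) + 1L, ncol = nc, byrow = TRUE)
  grab <- function(xpath) {
    out <- list()
    for (nodeset in xml2::xml_find_all(piece, xpath)) {
      nm <- xml2::xml_attr(nodeset, "Name")
      comps <- as.integer(xml2::xml_attr(nodeset, "NumberOfComponents"))
      if (is.na(comps)) comps <- 1L
      x <- nums(nodeset)
      out[[nm]] <- if (comps > 1L) {
        matrix(x, ncol = comps, byrow = TRUE)
      } else x
    }
    out
  }
  list(
    vertices = vertices, cells = cells,
    point_data = grab(".//PointData/DataArray"),
    cell_data = grab(".//CellData/DataArray")
  )
}

#' Write / read a frame set as JSON (bit-identical round trip)
#'
#' @param frames a `frame_set`.
#' @param path file path.
#' @return the path (write) or a `frame_set` (read).
#' @export
write_frame_set <- function(frames, path) {
  obj <- list(
    period = .fmt(frames$period),
    frame_times = .fmt(frames$frame_times),
    wall_vertex_ids = frames$wall_vertex_ids,
    n_wall = length(frames$wall_vertex_ids),
    displacements = lapply(frames$displacements, function(d) {
      .fmt(as.vector(d)) # column-major flat vector of decimal strings
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_frame_set
#' @export
read_frame_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  disp <- lapply(obj$displacements, function(d) {
    matrix(as.numeric(unlist(d)), ncol = 3)
  })
  structure(list(
    frame_times = as.numeric(unlist(obj$frame_times)),
    period = as.numeric(obj$period),
    wall_vertex_ids = as.integer(unlist(obj$wall_vertex_ids)),
    displacements = disp
  ), class = "frame_set")
}

#' Write a tagged mesh as Gmsh MSH 2.2 ASCII
#'
#' Tets are written with physical group 100; boundary triangles carry
#' their region tag as the physical group.
#'
#' @param path output file.
#' @param geom a `chamber_geometry`.
#' @return the path, invisibly.
#' @export
write_msh <- function(path, geom) {
  v <- geom$vertices
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(v))), con)
  writeLines(sprintf("%d %s %s %s", seq_len(nrow(v)),
                     .fmt(v[, 1]), .fmt(v[, 2]), .fmt(v[, 3])), con)
  writeLines(c("$EndNodes", "$Elements"), con)
  nt <- nrow(geom$tets)
  nf <- nrow(geom$boundary_facets)
  writeLines(as.character(nt + nf), con)
  writeLines(sprintf(
    "%d 2 2 %d %d %d %d %d", seq_len(nf), geom$boundary_tag,
    geom$boundary_tag, geom$boundary_facets[, 1],
    geom$boundary_facets[, 2], geom$boundary_facets[, 3]
  ), con)
  writeLines(sprintf(
    "%d 4 2 100 100 %d %d %d %d", nf + seq_len(nt),
    geom$tets[, 1], geom$tets[, 2], geom$tets[, 3], geom$tets[, 4]
  ), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Import a tagged tetrahedral mesh from Gmsh MSH 2.2 ASCII
#'
#' Physical groups of surface triangles are mapped onto region tags; by
#' default group ids are taken directly as region codes (1 = WALL, ...,
#' 6 = MV), or supply `tag_map` (named integer vector: group id -> region
#' name).
#'
#' @param path input file.
#' @param tag_map optional named mapping, e.g. `c("11" = "WALL")`.
#' @return a `chamber_geometry` (without appendage metadata).
#' @export
read_msh <- function(path, tag_map = NULL) {
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) {
      stop(sprintf("format error in '%s': missing $%s", path, name))
    }
    lines[(i0 + 1L):(i1 - 1L)]
  }
  nd <- sect("Nodes")
  n <- as.integer(nd[1])
  node_rows <- do.call(rbind, strsplit(nd[1 + seq_len(n)], "\\s+"))
  ids <- as.integer(node_rows[, 1])
  verts <- matrix(as.numeric(node_rows[, 2:4]), ncol = 3)
  remap <- integer(max(ids))
  remap[ids] <- seq_len(n)

  el <- sect("Elements")
  m <- as.integer(el[1])
  tets <- list(); tris <- list(); tri_tag <- integer(0)
  for (ln in el[1 + seq_len(m)]) {
    f <- as.integer(strsplit(ln, "\\s+")[[1]])
    type <- f[2]
    ntags <- f[3]
    phys <- if (ntags >= 1) f[4] else NA_integer_
    nodes <- f[(4 + ntags):length(f)]
    if (type == 4L) {
      tets[[length(tets) + 1L]] <- remap[nodes]
    } else if (type == 2L) {
      tris[[length(tris) + 1L]] <- remap[nodes]
      tri_tag <- c(tri_tag, phys)
    }
  }
  if (!length(tets)) stop(sprintf("format error in '%s': no tets", path))
  tets <- do.call(rbind, tets)
  tets <- orient_tets(verts, tets)
  bf <- boundary_facets(verts, tets)
  tag <- rep(NA_integer_, nrow(bf))
  if (length(tris)) {
    tris <- do.call(rbind, tris)
    if (!is.null(tag_map)) {
      mapped <- REGION_TAGS[tag_map[as.character(tri_tag)]]
      tri_tag <- as.integer(mapped)
    }
    if (any(is.na(tri_tag)) || !all(tri_tag %in% REGION_TAGS)) {
      stop(sprintf(
        "format error in '%s': surface physical groups do not map to region tags",
        path
      ))
    }
    key <- function(f) {
      apply(f, 1L, function(r) paste(sort.int(r), collapse = "_"))
    }
    idx <- match(key(bf), key(tris))
    if (any(is.na(idx))) {
      stop(sprintf("format error in '%s': untagged boundary facets", path))
    }
    tag <- tri_tag[idx]
  } else {
    stop(sprintf("format error in '%s': no tagged surface triangles", path))
  }
  structure(list(
    vertices = verts, tets = tets, boundary_facets = bf,
    boundary_tag = as.integer(tag), tag_legend = REGION_TAGS,
    laa_wall_vertices = integer(0), laa_cells = integer(0),
    ostium_ring = integer(0), params = list(kind = "msh", path = path),
    laa_axis = c(0, 0, 1)
  ), class = "chamber_geometry")
}
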