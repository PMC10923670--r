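## Mesh and solution I/O: Gmsh MSH v2.2 (ASCII, read + write) and VTK
## unstructured-grid XML (.vtu, write).  Both are plain-text formats; the
## MSH writer/reader round-trips coordinates bit-exactly via %.17g.

.msh_phys <- c(inlet = 1L, outlet = 2L, wall = 3L)

#' Write a mesh to disk
#'
#' @param mesh a [mesh_channel()] mesh.
#' @param path output path; the format is chosen from the extension
#'   (`.msh` for Gmsh v2.2, `.vtu` for VTK XML).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "msh") write_msh22(mesh, path)
  else if (ext == "vtu") write_vtu(mesh, path)
  else stop("unsupported mesh format: ", ext)
  invisible(path)
}

write_msh22 <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               sprintf("%d", mesh$n_nodes)), con)
  writeLines(sprintf("%d %.17g %.17g 0", seq_len(mesh$n_nodes),
                     mesh$coords[, 1], mesh$coords[, 2]), con)
  writeLines("$EndNodes", con)
  nb <- nrow(mesh$boundary)
  writeLines(c("$Elements", sprintf("%d", nb + mesh$n_elem)), con)
  ## type 8 = 3-node second-order line; tags: physical, geometric
  phys <- .msh_phys[mesh$boundary$tag]
  writeLines(sprintf("%d 8 2 %d %d %d %d %d", seq_len(nb), phys, phys,
                     mesh$boundary$n1, mesh$boundary$n2, mesh$boundary$mid),
             con)
  ## type 9 = 6-node second-order triangle
  writeLines(sprintf("%d 9 2 0 0 %d %d %d %d %d %d", nb + seq_len(mesh$n_elem),
                     mesh$tri[, 1], mesh$tri[, 2], mesh$tri[, 3],
                     mesh$tri[, 4], mesh$tri[, 5], mesh$tri[, 6]), con)
  writeLines("$EndElements", con)
}

#' Read a Gmsh MSH v2.2 mesh written by [write_mesh()]
#'
#' @param path path to a `.msh` file.
#' @return a `tri_mesh` object (structured-grid metadata is not recoverable
#'   from the file and is absent; such meshes support validation and I/O but
#'   not the structured point-location fast path).
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  grab <- function(tag) {
    i <- which(lines == paste0("$", tag)) + 1L
    j <- which(lines == paste0("$End", tag)) - 1L
    lines[i:j]
  }
  nd <- grab("Nodes")
  n_nodes <- as.integer(nd[1])
  nm <- matrix(as.numeric(unlist(strsplit(nd[-1], " ", fixed = TRUE))),
               ncol = 4, byrow = TRUE)
  coords <- nm[order(nm[, 1]), 2:3, drop = FALSE]
  el <- grab("Elements")[-1]
  tok <- strsplit(el, " ", fixed = TRUE)
  types <- vapply(tok, function(t) as.integer(t[2]), 0L)
  lines3 <- tok[types == 8L]
  tris <- tok[types == 9L]
  tri <- t(vapply(tris, function(t) as.integer(t[(length(t) - 5):length(t)]),
                  integer(6)))
  inv_phys <- stats::setNames(names(.msh_phys), .msh_phys)
  boundary <- do.call(rbind, lapply(lines3, function(t) {
    n <- as.integer(t)
    data.frame(n1 = n[length(n) - 2], n2 = n[length(n) - 1],
               tag = inv_phys[[as.character(n[4])]], elem = NA_integer_,
               mid = n[length(n)])
  }))
  n_corner <- max(tri[, 1:3])
  structure(list(coords = coords, tri = tri, n_corner = n_corner,
                 n_nodes = n_nodes, n_elem = nrow(tri), boundary = boundary,
                 grid = NULL, h_far = NA_real_, h_lesion = NA_real_),
            class = "tri_mesh")
}

#' Write a mesh or flow solution as VTK XML unstructured grid (.vtu)
#'
#' @param mesh a `tri_mesh`.
#' @param path output path.
#' @param point_data optional named list of nodal vectors (length `n_nodes`)
#'   written as point data arrays (e.g. velocity components, pressure
#'   prolonged to all nodes, stresses, viscosity).
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  n <- mesh$n_nodes; ne <- mesh$n_elem
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  co <- as.vector(t(cbind(mesh$coords, 0)))
  ## VTK quadratic triangle (type 22) uses the same corner+midside order
  conn <- as.vector(t(mesh$tri - 1L))
  pd <- ""
  if (!is.null(point_data) && length(point_data)) {
    arrays <- vapply(names(point_data), function(nm) {
      paste0('        <DataArray type="Float64" Name="', nm,
             '" format="ascii">\n          ', num(point_data[[nm]]),
             "\n        </DataArray>")
    }, "")
    pd <- paste0("      <PointData>\n", paste(arrays, collapse = "\n"),
                 "\n      </PointData>\n")
  }
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
    "  <UnstructuredGrid>\n",
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">\n', n, ne),
    pd,
    "      <Points>\n",
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">\n',
    "          ", num(co), "\n        </DataArray>\n      </Points>\n",
    "      <Cells>\n",
    '        <DataArray type="Int32" Name="connectivity" format="ascii">\n',
    "          ", paste(conn, collapse = " "), "\n        </DataArray>\n",
    '        <DataArray type="Int32" Name="offsets" format="ascii">\n',
    "          ", paste(seq_len(ne) * 6L, collapse = " "),
    "\n        </DataArray>\n",
    '        <DataArray type="UInt8" Name="types" format="ascii">\n',
    "          ", paste(rep(22L, ne), collapse = " "), "\n        </DataArray>\n",
    "      </Cells>\n    </Piece>\n  </UnstructuredGrid>\n</VTKFile>\n")
  cat(xml, file = path)
  invisible(path)
}

#' Export a flow state as VTU point data
#'
#' Writes velocity components, velocity magnitude, pressure (prolonged from
#' corner values to midside nodes by edge averaging), extra-stress components
#' and, for shear-thinning cases, the local viscosity.
#'
#' @param state a `flow_state` from [newton_solve()] / [solve_case()].
#' @param mesh the mesh the state lives on.
#' @param path output `.vtu` path.
#' @return `path`, invisibly.
#' @export
write_state_vtu <- function(state, mesh, path) {
  p_full <- prolong_pressure(state$p, mesh)
  pd <- list(u = state$u, v = state$v,
             speed = sqrt(state$u^2 + state$v^2), p = p_full)
  if (!is.null(state$s11)) {
    pd$s11 <- state$s11; pd$s12 <- state$s12; pd$s22 <- state$s22
  }
  write_vtu(mesh, path, point_data = pd)
}

## corner pressure -> all P2 nodes (midsides get edge-endpoint average)
prolong_pressure <- function(p_corner, mesh) {
  out <- numeric(mesh$n_nodes)
  out[seq_len(mesh$n_corner)] <- p_corner
  for (k in 1:3) {
    c1 <- mesh$tri[, k]; c2 <- mesh$tri[, k %% 3 + 1]; m <- mesh$tri[, 3 + k]
    out[m] <- (p_corner[c1] + p_corner[c2]) / 2
  }
  out
}
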