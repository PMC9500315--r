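# Model and result file I/O: VTU (XML unstructured grid) with a metadata
# payload for lossless model round trips, legacy-VTK mesh export, and an
# Abaqus-INP-subset writer for cross-checking in external solvers.

fmt_num <- function(x) sprintf("%.17g", x)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  gsub("<", "&lt;", s, fixed = TRUE)
}

# flattened cells over all blocks
flatten_cells <- function(mesh) {
  conn <- integer(0); offs <- integer(0); types <- integer(0)
  for (b in mesh$blocks) {
    k <- KIND_NNODE[[b$kind]]
    if (nrow(b$conn) == 0) next
    conn <- c(conn, as.vector(t(b$conn)) - 1L)
    offs <- c(offs, (if (length(offs)) offs[length(offs)] else 0L) +
                k * seq_len(nrow(b$conn)))
    types <- c(types, rep(VTK_CELL_TYPE[[b$kind]], nrow(b$conn)))
  }
  list(conn = conn, offsets = offs, types = types)
}

#' Write a model or mesh to file
#'
#' Dispatches on the file extension: `.vtu` (XML, lossless model round
#' trip), `.vtk` (legacy ASCII, mesh only) or `.inp` (Abaqus subset export:
#' `*NODE`, `*ELEMENT`, `*NSET`, `*ELSET`, `*SURFACE`).
#'
#' @param x a `spine_model` or `fe_mesh`.
#' @param path output file path.
#' @param point_data optional named list of per-node vectors/matrices.
#' @param cell_data optional named list of per-element vectors.
#' @return the path, invisibly.
#' @export
write_model <- function(x, path, point_data = list(), cell_data = list()) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vtu = write_model_vtu(x, path, point_data, cell_data),
         vtk = write_mesh_vtk(if (inherits(x, "spine_model")) x$mesh else x,
                              path),
         inp = write_model_inp(x, path),
         cf_format_error("unsupported model file extension '.%s'", ext))
  invisible(path)
}

#' Read a model or mesh from file
#'
#' `.vtu` files written by [write_model()] restore the full `spine_model`
#' (or `fe_mesh` if no metadata payload is present); `.vtk` files restore
#' the mesh only.
#'
#' @param path input file path.
#' @return a `spine_model` or `fe_mesh`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) cf_format_error("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vtu = read_model_vtu(path),
         vtk = read_mesh_vtk(path),
         cf_format_error("unsupported model file extension '.%s'", ext))
}

write_model_vtu <- function(x, path, point_data = list(),
                            cell_data = list()) {
  is_model <- inherits(x, "spine_model")
  mesh <- if (is_model) x$mesh else x
  fc <- flatten_cells(mesh)
  n <- nrow(mesh$nodes); m <- length(fc$types)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  # metadata payload: everything except the node/cell arrays
  meta <- if (is_model) {
    x2 <- x
    x2$mesh <- list(blocks_kind = vapply(mesh$blocks, `[[`, character(1), "kind"),
                    nsets = mesh$nsets, elsets = mesh$elsets,
                    surfaces = mesh$surfaces)
    # hex-float encoding keeps the material vectors bit-exact through JSON
    x2$E <- sprintf("%a", x$E)
    x2$nu <- sprintf("%a", x$nu)
    x2$area <- sprintf("%a", x$area)
    as.character(jsonlite::serializeJSON(x2, digits = NA))
  } else {
    as.character(jsonlite::serializeJSON(
      list(nsets = mesh$nsets, elsets = mesh$elsets,
           surfaces = mesh$surfaces), digits = NA))
  }
  w('<FieldData>')
  w('<DataArray type="String" Name="cervifem_meta" NumberOfTuples="1" format="ascii">')
  writeLines(xml_escape(meta), con)
  w('</DataArray>')
  w('</FieldData>')
  w('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('<Points>')
  w('<DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
                   fmt_num(mesh$nodes[, 3])), con)
  w('</DataArray>')
  w('</Points>')
  w('<Cells>')
  w('<DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(paste(fc$conn, collapse = " "), con)
  w('</DataArray>')
  w('<DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(paste(fc$offsets, collapse = " "), con)
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(fc$types, collapse = " "), con)
  w('</DataArray>')
  w('</Cells>')
  if (is_model) {
    cell_data <- c(list(youngs_modulus = x$E, poisson_ratio = x$nu),
                   cell_data)
  }
  if (length(cell_data)) {
    w('<CellData>')
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      v[!is.finite(v)] <- -1
      w('<DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(paste(fmt_num(v), collapse = " "), con)
      w('</DataArray>')
    }
    w('</CellData>')
  }
  if (length(point_data)) {
    w('<PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      nc <- if (is.matrix(v)) ncol(v) else 1L
      w('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
        nm, nc)
      if (is.matrix(v)) {
        writeLines(apply(v, 1, function(r) paste(fmt_num(r), collapse = " ")),
                   con)
      } else writeLines(paste(fmt_num(v), collapse = " "), con)
      w('</DataArray>')
    }
    w('</PointData>')
  }
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

read_model_vtu <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    cf_format_error("malformed VTU file %s: %s", path, conditionMessage(e)))
  ns <- xml2::xml_ns_strip(doc)
  get_arr <- function(xpath, what) {
    node <- xml2::xml_find_first(doc, xpath)
    if (is.na(node) || inherits(node, "xml_missing"))
      cf_format_error("VTU file lacks %s", what)
    scan(text = xml2::xml_text(node), what = numeric(), quiet = TRUE)
  }
  pts <- get_arr(".//Points/DataArray", "point coordinates")
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  conn <- as.integer(get_arr(".//Cells/DataArray[@Name='connectivity']",
                             "connectivity"))
  offs <- as.integer(get_arr(".//Cells/DataArray[@Name='offsets']", "offsets"))
  types <- as.integer(get_arr(".//Cells/DataArray[@Name='types']", "cell types"))
  kind_of <- setNames(names(VTK_CELL_TYPE), VTK_CELL_TYPE)
  blocks <- list()
  # rebuild contiguous blocks of equal type
  starts <- c(1L, which(diff(types) != 0) + 1L)
  ends <- c(starts[-1] - 1L, length(types))
  for (g in seq_along(starts)) {
    tp <- types[starts[g]]
    kind <- kind_of[[as.character(tp)]]
    if (is.null(kind)) cf_format_error("unsupported VTK cell type %d", tp)
    k <- KIND_NNODE[[kind]]
    o0 <- if (starts[g] == 1L) 0L else offs[starts[g] - 1L]
    idx <- (o0 + 1L):offs[ends[g]]
    cm <- matrix(conn[idx] + 1L, ncol = k, byrow = TRUE)
    storage.mode(cm) <- "integer"
    blocks[[g]] <- list(kind = kind, conn = cm)
  }
  meta_node <- xml2::xml_find_first(
    doc, ".//FieldData/DataArray[@Name='cervifem_meta']")
  if (is.na(meta_node) || inherits(meta_node, "xml_missing"))
    return(fe_mesh(nodes, blocks))
  meta <- jsonlite::unserializeJSON(xml2::xml_text(meta_node))
  if (!is.null(meta$E)) { # full model payload
    model <- meta
    mesh <- fe_mesh(nodes, blocks, nsets = meta$mesh$nsets,
                    elsets = meta$mesh$elsets, surfaces = meta$mesh$surfaces)
    model$mesh <- mesh
    model$E <- suppressWarnings(as.numeric(meta$E))
    model$nu <- suppressWarnings(as.numeric(meta$nu))
    model$area <- suppressWarnings(as.numeric(meta$area))
    class(model) <- "spine_model"
    return(model)
  }
  fe_mesh(nodes, blocks, nsets = meta$nsets, elsets = meta$elsets,
          surfaces = meta$surfaces)
}

#' Write a solved result alongside its model to VTU
#'
#' Stores the displacement field as point data and the principal strains,
#' damage index and truss status as cell data.
#'
#' @param result a `solve_result`.
#' @param model the model.
#' @param path output `.vtu` path.
#' @param th damage thresholds used for the Di field.
#' @return the path, invisibly.
#' @export
write_result_vtu <- function(result, model, path, th = damage_thresholds()) {
  ps <- principal_strains(result$strain)
  di <- damage_index(ps, th)
  truss_active <- rep(NA_real_, mesh_nelem(model$mesh))
  if (!is.null(result$truss))
    truss_active[result$truss$elem] <- as.numeric(result$truss$active)
  write_model_vtu(model, path,
                  point_data = list(displacement = result$displacements),
                  cell_data = list(e1 = ps[, 1], e3 = ps[, 3], Di = di,
                                   truss_active = truss_active))
}

# legacy ASCII VTK (mesh only)
write_mesh_vtk <- function(mesh, path) {
  fc <- flatten_cells(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cervifem mesh", "ASCII", "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", nrow(mesh$nodes)), con)
  writeLines(paste(fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
                   fmt_num(mesh$nodes[, 3])), con)
  sizes <- diff(c(0L, fc$offsets))
  writeLines(sprintf("CELLS %d %d", length(fc$types),
                     length(fc$conn) + length(fc$types)), con)
  pos <- 0L
  lines <- character(length(fc$types))
  for (i in seq_along(fc$types)) {
    k <- sizes[i]
    lines[i] <- paste(c(k, fc$conn[(pos + 1):(pos + k)]), collapse = " ")
    pos <- pos + k
  }
  writeLines(lines, con)
  writeLines(sprintf("CELL_TYPES %d", length(fc$types)), con)
  writeLines(as.character(fc$types), con)
  invisible(path)
}

read_mesh_vtk <- function(path) {
  txt <- readLines(path)
  ip <- grep("^POINTS", txt)
  if (!length(ip)) cf_format_error("not a legacy VTK unstructured grid: %s", path)
  npts <- as.integer(strsplit(txt[ip], "\\s+")[[1]][2])
  body <- paste(txt[(ip + 1):length(txt)], collapse = "\n")
  nums <- scan(text = body, what = numeric(), n = 3 * npts, quiet = TRUE)
  nodes <- matrix(nums, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", txt)[1]
  hdr <- as.integer(strsplit(txt[ic], "\\s+")[[1]][2:3])
  cell_nums <- scan(text = paste(txt[(ic + 1):length(txt)], collapse = "\n"),
                    what = integer(), n = hdr[2], quiet = TRUE)
  it <- grep("^CELL_TYPES", txt)[1]
  types <- scan(text = paste(txt[(it + 1):length(txt)], collapse = "\n"),
                what = integer(), n = hdr[1], quiet = TRUE)
  kind_of <- setNames(names(VTK_CELL_TYPE), VTK_CELL_TYPE)
  conn_list <- list(); kinds <- character(hdr[1])
  pos <- 0L
  cells <- vector("list", hdr[1])
  for (i in seq_len(hdr[1])) {
    k <- cell_nums[pos + 1L]
    cells[[i]] <- cell_nums[(pos + 2L):(pos + 1L + k)] + 1L
    kinds[i] <- kind_of[[as.character(types[i])]]
    pos <- pos + 1L + k
  }
  blocks <- list()
  starts <- c(1L, which(diff(types) != 0) + 1L)
  ends <- c(starts[-1] - 1L, length(types))
  for (g in seq_along(starts)) {
    cm <- do.call(rbind, cells[starts[g]:ends[g]])
    storage.mode(cm) <- "integer"
    blocks[[g]] <- list(kind = kinds[starts[g]], conn = cm)
  }
  fe_mesh(nodes, blocks)
}
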