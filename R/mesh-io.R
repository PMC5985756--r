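#' Read and write meshes in legacy VTK unstructured-grid format
#'
#' ASCII legacy VTK (\code{DATASET UNSTRUCTURED_GRID}) with the region label
#' stored as a \code{CELL_DATA} integer scalar named \code{region}. Boundary
#' facets and their surface tags do not fit the volumetric VTK cell list and
#' are written to a companion file \code{<path>.facets.csv}; \code{read_mesh}
#' picks it up automatically when present. Per-vertex or per-element fields
#' can be attached on write.
#'
#' @param mesh an \code{emf_mesh}.
#' @param path output file (conventionally \code{.vtk}).
#' @param point_data named list of per-vertex vectors/matrices to append.
#' @param cell_data named list of per-element vectors to append.
#' @return invisibly, the path.
#' @export
write_mesh <- function(mesh, path, point_data = NULL, cell_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); ne <- nrow(mesh$elements)
  d <- mesh$dim
  verts <- mesh$vertices
  if (d == 2L) verts <- cbind(verts, 0)
  writeLines(c("# vtk DataFile Version 3.0",
               "cardioemf labeled mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nv)), con)
  utils::write.table(format(verts, digits = 17, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  npe <- d + 1L
  writeLines(sprintf("CELLS %d %d", ne, ne * (npe + 1L)), con)
  utils::write.table(cbind(npe, mesh$elements - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  ctype <- if (d == 3L) 10L else 5L
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(ctype, ne)), con)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  labs <- region_codes(mesh$element_labels)
  writeLines(as.character(labs$codes), con)
  if (!is.null(cell_data)) {
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(as.numeric(cell_data[[nm]]), digits = 17), con)
    }
  }
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    for (nm in names(point_data)) {
      val <- point_data[[nm]]
      if (is.matrix(val) && ncol(val) > 1L) {
        v3 <- if (ncol(val) == 2L) cbind(val, 0) else val
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(format(v3, digits = 17, trim = TRUE), con,
                           row.names = FALSE, col.names = FALSE, quote = FALSE)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(format(as.numeric(val), digits = 17), con)
      }
    }
  }
  if (!is.null(mesh$boundary_facets) && nrow(mesh$boundary_facets) > 0) {
    fc <- as.data.frame(mesh$boundary_facets)
    names(fc) <- paste0("v", seq_len(ncol(fc)))
    fc$tag <- mesh$facet_tags
    utils::write.csv(fc, paste0(path, ".facets.csv"), row.names = FALSE)
  }
  invisible(path)
}

region_codes <- function(labels) {
  universe <- c("lv", "ao", "cushion", "av", "mv", "lvbp", "aobp")
  extra <- setdiff(unique(labels), universe)
  universe <- c(universe, extra)
  list(codes = match(labels, universe) - 1L, universe = universe)
}

#' @rdname write_mesh
#' @param validate validate the mesh after reading.
#' @return \code{read_mesh}: an \code{emf_mesh}; extra fields present in the
#'   file are attached as attribute \code{fields}.
#' @export
read_mesh <- function(path, validate = TRUE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !grepl("UNSTRUCTURED_GRID", lines[4]))
    stop_emf("malformed file: expected 'DATASET UNSTRUCTURED_GRID' on line 4 of ", path)
  i <- grep("^POINTS", lines)[1]
  if (is.na(i)) stop_emf("malformed file: no POINTS record in ", path)
  nv <- as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]][2])
  pts <- scan_block(lines, i + 1L, nv * 3L, "POINTS")
  verts <- matrix(pts, nv, 3, byrow = TRUE)
  j <- grep("^CELLS", lines)[1]
  if (is.na(j)) stop_emf("malformed file: no CELLS record in ", path)
  hd <- as.integer(strsplit(trimws(lines[j]), "\\s+")[[1]][2:3])
  ne <- hd[1]
  cells <- as.integer(scan_block(lines, j + 1L, hd[2], "CELLS"))
  k <- grep("^CELL_TYPES", lines)[1]
  ctypes <- as.integer(scan_block(lines, k + 1L, ne, "CELL_TYPES"))
  ct <- unique(ctypes)
  if (length(ct) != 1L || !ct %in% c(5L, 10L))
    stop_emf("unknown cell types in ", path, ": ",
             paste(setdiff(ct, c(5L, 10L)), collapse = ", "),
             " (only triangles [5] and tetrahedra [10] are supported)")
  npe <- if (ct == 10L) 4L else 3L
  cm <- matrix(cells, ne, npe + 1L, byrow = TRUE)
  if (any(cm[, 1] != npe)) stop_emf("malformed file: CELLS counts disagree with CELL_TYPES")
  elements <- cm[, -1, drop = FALSE] + 1L
  d <- if (ct == 10L) 3L else 2L
  if (d == 2L) verts <- verts[, 1:2, drop = FALSE]
  labels <- NULL
  fields <- list()
  cd <- grep("^CELL_DATA", lines)[1]
  if (!is.na(cd)) {
    sc <- grep("^SCALARS", lines)
    sc <- sc[sc > cd]
    for (s in sc) {
      nm <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
      n_here <- ne
      pd <- grep("^POINT_DATA", lines)[1]
      if (!is.na(pd) && s > pd) n_here <- nv
      vals <- scan_block(lines, s + 2L, n_here, nm)
      if (nm == "region" && n_here == ne) labels <- vals else fields[[nm]] <- vals
    }
  }
  if (is.null(labels)) {
    warning("mesh file has no region label array; defaulting to a single 'lv' region")
    label_chr <- rep("lv", ne)
  } else {
    universe <- region_codes("lv")$universe
    label_chr <- universe[as.integer(labels) + 1L]
    label_chr[is.na(label_chr)] <- "lv"
  }
  facfile <- paste0(path, ".facets.csv")
  bf <- NULL; tags <- NULL
  if (file.exists(facfile)) {
    fc <- utils::read.csv(facfile)
    bf <- as.matrix(fc[, grep("^v", names(fc)), drop = FALSE])
    tags <- as.character(fc$tag)
  }
  mesh <- labeled_mesh(verts, elements, label_chr, boundary_facets = bf,
                       facet_tags = tags, validate = validate)
  if (length(fields) > 0) attr(mesh, "fields") <- fields
  mesh
}

scan_block <- function(lines, from, n_values, what) {
  vals <- numeric(0)
  i <- from
  while (length(vals) < n_values && i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) > 0 && suppressWarnings(anyNA(as.numeric(tok))))
      stop_emf("malformed file: non-numeric data in ", what, " record near line ", i)
    vals <- c(vals, as.numeric(tok))
    i <- i + 1L
  }
  if (length(vals) < n_values)
    stop_emf("malformed file: ", what, " record truncated (expected ",
             n_values, " values)")
  vals[seq_len(n_values)]
}
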