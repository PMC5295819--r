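# Mesh snapshots are written as Wavefront OBJ or ASCII PLY; per-vertex
# factor levels travel in a sidecar CSV keyed by vertex index, and clone
# membership in a per-triangle CSV.  ASCII formats are used throughout so
# snapshots stay diffable and portable.

#' Write a canvas mesh as OBJ
#' @param canvas a canvas.
#' @param path output file path.
#' @export
write_obj <- function(canvas, path) {
  v <- canvas$vertices; t <- canvas$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# tissuecanvas mesh v1", con)
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", t[, 1], t[, 2], t[, 3]), con)
  invisible(path)
}

#' Read an OBJ mesh into a canvas
#' @param path OBJ file path.
#' @param thickness thickness assigned to the loaded canvas.
#' @return a canvas object (rest metrics set to the loaded geometry).
#' @export
read_obj <- function(path, thickness = 10) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    as.integer(sub("/.*$", "", x[2:4]))
  }))
  new_canvas(v, f, thickness)
}

#' Write a canvas mesh as ASCII PLY
#' @param canvas a canvas.
#' @param path output file path.
#' @export
write_ply <- function(canvas, path) {
  v <- canvas$vertices; t <- canvas$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment tissuecanvas mesh v1",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(t)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", t[, 1] - 1L, t[, 2] - 1L, t[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY mesh into a canvas
#' @param path PLY file path.
#' @param thickness thickness assigned to the loaded canvas.
#' @return a canvas object.
#' @export
read_ply <- function(path, thickness = 10) {
  ln <- readLines(path)
  if (ln[1] != "ply") abort("%s is not a PLY file", path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", ln, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", ln, value = TRUE)[1]))
  body <- which(ln == "end_header") + 1L
  v <- do.call(rbind, lapply(strsplit(ln[body:(body + nv - 1L)], "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(ln[(body + nv):(body + nv + nf - 1L)], "\\s+"),
                             function(x) as.integer(x[2:4]) + 1L))
  new_canvas(v, f, thickness)
}

#' Write per-vertex factor levels as a sidecar CSV
#' @param canvas a canvas.
#' @param path output CSV path (columns: vertex, one column per factor).
#' @export
write_factor_csv <- function(canvas, path) {
  df <- data.frame(vertex = seq_len(nrow(canvas$vertices)))
  for (nm in names(canvas$factors)) df[[nm]] <- canvas$factors[[nm]]
  if (!is.null(canvas$pol)) df$POL <- canvas$pol
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a sidecar factor CSV onto a canvas
#' @param canvas a canvas.
#' @param path CSV path written by [write_factor_csv()].
#' @return the canvas with factors attached.
#' @export
read_factor_csv <- function(canvas, path) {
  df <- utils::read.csv(path)
  for (nm in setdiff(names(df), "vertex")) {
    if (nm == "POL") canvas$pol <- df[[nm]][order(df$vertex)]
    else canvas <- set_factor(canvas, nm, df[[nm]][order(df$vertex)])
  }
  canvas
}

#' Write clone membership as CSV
#' @param canvas a canvas with clones.
#' @param path output CSV path (columns: triangle, clone_id).
#' @export
write_clone_csv <- function(canvas, path) {
  utils::write.csv(data.frame(triangle = seq_along(canvas$clone_id),
                              clone_id = canvas$clone_id),
                   path, row.names = FALSE)
  invisible(path)
}
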