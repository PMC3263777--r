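#' Read a mesh in OFF format
#'
#' Plain-text Object File Format: header line `OFF`, then vertex/face/edge
#' counts, vertex coordinates and polygonal faces (triangles required here).
#'
#' @param path file path.
#' @return a [triangle_mesh()].
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  body <- scan(text = paste(lines[-(1:2)], collapse = "\n"), quiet = TRUE)
  verts <- matrix(body[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  rest <- body[-seq_len(3 * nv)]
  faces <- matrix(NA_integer_, nf, 3)
  pos <- 1
  for (i in seq_len(nf)) {
    k <- rest[pos]
    if (k != 3) stop("non-triangular face in OFF file")
    faces[i, ] <- rest[pos + 1:3] + 1L  # OFF is 0-based
    pos <- pos + k + 1
  }
  triangle_mesh(verts, faces)
}

#' Write a mesh in OFF format
#' @param mesh a [triangle_mesh()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    sprintf("%.17g %.17g %.17g", r[1], r[2], r[3])), con)
  tr <- mesh$triangles - 1L
  writeLines(sprintf("3 %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  invisible(path)
}

#' Read or write per-vertex region labels as delimited text
#'
#' Two tab-separated columns: `vertex_index` (1-based) and `region_id`.
#'
#' @param path file path.
#' @param n_vertices expected number of vertices.
#' @return integer vector of labels.
#' @export
read_labels <- function(path, n_vertices) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  lab <- integer(n_vertices)
  lab[d$vertex_index] <- d$region_id
  lab
}

#' @rdname read_labels
#' @param labels integer vector of per-vertex labels.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(vertex_index = seq_along(labels), region_id = labels),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a graded region-to-region connectivity matrix
#'
#' Square delimited-text matrix with a header of region names; entries are
#' integer grades 0 (absent) to 3 (strong), zero diagonal.
#'
#' @param path file path.
#' @return integer matrix with region names as dimnames.
#' @export
read_region_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  storage.mode(m) <- "integer"
  if (nrow(m) != ncol(m)) stop("region matrix must be square")
  m
}

#' @rdname read_region_matrix
#' @param m integer matrix of grades with dimnames.
#' @export
write_region_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read or write electrode positions as delimited text
#'
#' Tab-separated columns: `label`, `x`, `y`, `z` (mm).
#'
#' @param path file path.
#' @return data.frame with columns label, x, y, z.
#' @export
read_electrodes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_electrodes
#' @param electrodes data.frame with columns label, x, y, z.
#' @export
write_electrodes <- function(electrodes, path) {
  utils::write.table(electrodes, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
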