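# ASCII PLY and STL surface I/O. PLY is the map carrier because a single
# standard file holds positions, per-vertex scalars and colors.

#' Write a triangulated mesh (with optional per-vertex properties) as ASCII PLY
#'
#' @param mesh a \code{template_mesh} or list with \code{vertices}, \code{faces}.
#' @param path output path.
#' @param vertex_props optional data.frame of extra per-vertex properties;
#'   integer columns are written as \code{int} (columns named red/green/blue
#'   as \code{uchar}), doubles as \code{float}.
#' @param comments character vector of header comment lines.
#' @return \code{path}, invisibly.
#' @export
write_ply <- function(mesh, path, vertex_props = NULL, comments = character()) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  header <- c("ply", "format ascii 1.0",
              paste("comment", comments),
              sprintf("element vertex %d", nv),
              "property float x", "property float y", "property float z")
  cols <- sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3])
  if (!is.null(vertex_props)) {
    if (nrow(vertex_props) != nv) stop("vertex_props rows must match vertex count")
    for (nm in names(vertex_props)) {
      col <- vertex_props[[nm]]
      if (is.integer(col) || all(col == round(col))) {
        type <- if (nm %in% c("red", "green", "blue", "alpha")) "uchar" else "int"
        cols <- paste(cols, sprintf("%d", as.integer(col)))
      } else {
        type <- "float"
        cols <- paste(cols, sprintf("%.6f", col))
      }
      header <- c(header, sprintf("property %s %s", type, nm))
    }
  }
  header <- c(header,
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  con <- file(path, "wb")  # binary connection: LF line endings on all platforms
  on.exit(close(con))
  writeLines(c(header, cols, sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
             con, sep = "\n")
  invisible(path)
}

#' Read a surface mesh from ASCII PLY or STL
#'
#' @param path input file; format chosen by content (PLY magic) then extension.
#' @param ... passed to \code{\link{template_mesh}} (joint-line plane, axes, side).
#' @return A \code{template_mesh}; any extra PLY vertex properties are
#'   attached as attribute \code{"vertex_props"}.
#' @export
read_mesh <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (identical(trimws(first), "ply")) read_ply(path, ...) else read_stl(path, ...)
}

read_ply <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  if (trimws(lines[1]) != "ply") stop("not a PLY file")
  if (!grepl("^format ascii", lines[2]))
    stop("only ASCII PLY is supported (got: ", lines[2], ")")
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY header not terminated")
  header <- lines[seq_len(end)]
  elems <- list(); cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(n = as.integer(tok[3]), props = character())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        elems[[cur]]$list <- TRUE
      } else {
        elems[[cur]]$props <- c(elems[[cur]]$props, tok[length(tok)])
      }
    }
  }
  if (is.null(elems$vertex)) stop("PLY has no vertex element")
  nv <- elems$vertex$n
  npr <- length(elems$vertex$props)
  body <- lines[(end + 1L):length(lines)]
  vals <- scan(text = body[seq_len(nv)], quiet = TRUE)
  if (length(vals) != nv * npr) stop("malformed PLY vertex block")
  vm <- matrix(vals, nrow = nv, ncol = npr, byrow = TRUE)
  colnames(vm) <- elems$vertex$props
  verts <- vm[, c("x", "y", "z"), drop = FALSE]
  dimnames(verts) <- NULL
  faces <- matrix(integer(), 0, 3)
  if (!is.null(elems$face) && elems$face$n > 0) {
    fvals <- scan(text = body[nv + seq_len(elems$face$n)], quiet = TRUE)
    fm <- matrix(fvals, nrow = elems$face$n, byrow = TRUE)
    if (any(fm[, 1] != 3)) stop("only triangulated PLY faces are supported")
    faces <- matrix(as.integer(fm[, 2:4] + 1L), ncol = 3)
  }
  mesh <- template_mesh(verts, faces, ...)
  extra <- setdiff(colnames(vm), c("x", "y", "z"))
  if (length(extra))
    attr(mesh, "vertex_props") <- as.data.frame(vm[, extra, drop = FALSE])
  mesh
}

read_stl <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^\\s*solid", lines[1]))
    stop("only ASCII STL is supported")
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) %% 3L != 0L) stop("malformed STL: vertex count not a multiple of 3")
  vals <- scan(text = sub("^\\s*vertex\\s+", "", vlines), quiet = TRUE)
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  key <- apply(pts, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  verts <- pts[uniq, , drop = FALSE]
  idx <- match(key, key[uniq])
  faces <- matrix(as.integer(idx), ncol = 3, byrow = TRUE)
  template_mesh(verts, faces, ...)
}
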