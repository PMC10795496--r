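#' Point cloud objects
#'
#' A point cloud is the universal currency of the reconstruction pipeline:
#' an N x 3 matrix of coordinates in millimetres, optionally paired row-for-row
#' with RGB colors in `[0, 255]`, as produced by RGB-D capture.
#'
#' @param points numeric matrix (or coercible) with 3 columns, one row per
#'   point, coordinates in mm. At least one point; all coordinates finite.
#' @param colors optional numeric matrix with 3 columns (RGB in `[0, 255]`)
#'   and the same number of rows as `points`.
#' @return An object of class `"point_cloud"`: a list with elements `points`
#'   and `colors` (`NULL` when absent).
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), ncol = 3))
#' npoints(pc)
#' @export
point_cloud <- function(points, colors = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns")
  if (nrow(points) < 1L) stop("point cloud must contain at least one point")
  if (!all(is.finite(points))) stop("point coordinates must be finite")
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (ncol(colors) != 3L) stop("colors must have 3 columns (RGB)")
    if (nrow(colors) != nrow(points))
      stop("color count (", nrow(colors), ") must equal point count (",
           nrow(points), ")")
    if (any(!is.finite(colors)) || any(colors < 0) || any(colors > 255))
      stop("colors must lie in [0, 255]")
    storage.mode(colors) <- "double"
    dimnames(colors) <- NULL
  }
  structure(list(points = points, colors = colors), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("point_cloud:", nrow(x$points), "points,",
      if (is.null(x$colors)) "no colors" else "with RGB colors", "\n")
  rng <- apply(x$points, 2, range)
  cat(sprintf("  extent (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`
#' @return integer point count
#' @export
npoints <- function(cloud) nrow(as_points(cloud))

#' Coerce to a bare coordinate matrix
#' @param cloud a `point_cloud` or numeric matrix
#' @return N x 3 numeric matrix
#' @export
as_points <- function(cloud) {
  if (inherits(cloud, "point_cloud")) return(cloud$points)
  if (is.matrix(cloud) && ncol(cloud) == 3L) return(cloud)
  stop("expected a point_cloud or an N x 3 matrix")
}

# Subset a cloud by point index, keeping colors paired with their points.
#' Subset a point cloud
#' @param cloud a `point_cloud`
#' @param idx integer indices of points to keep
#' @return a `point_cloud`
#' @export
pc_subset <- function(cloud, idx) {
  stopifnot(inherits(cloud, "point_cloud"))
  point_cloud(cloud$points[idx, , drop = FALSE],
              if (!is.null(cloud$colors)) cloud$colors[idx, , drop = FALSE])
}

.pc_format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "pcd", "xyz")) return(ext)
  if (ext %in% c("txt", "asc")) return("xyz")
  stop("cannot infer point-cloud format from extension '", ext, "'")
}

#' Read a point cloud from disk
#'
#' Supports ASCII and binary-little-endian PLY, ASCII PCD, and plain-text
#' XYZ / XYZRGB (whitespace separated, 3 or 6 columns, `#` comments).
#'
#' @param path file path
#' @param format one of `"auto"`, `"ply"`, `"pcd"`, `"xyz"`; `"auto"` infers
#'   from the file extension.
#' @return a [point_cloud()] carrying colors iff the file stores them, point
#'   order preserved as stored.
#' @export
read_cloud <- function(path, format = c("auto", "ply", "pcd", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .pc_format_from_path(path)
  switch(format,
         ply = .read_ply(path),
         pcd = .read_pcd(path),
         xyz = .read_xyz(path))
}

#' Write a point cloud to disk
#'
#' @param cloud a [point_cloud()]
#' @param path destination path (parent directory must exist)
#' @param format `"auto"` (from extension), `"ply"`, `"pcd"` or `"xyz"`
#' @param binary write binary-little-endian PLY instead of ASCII (PLY only);
#'   coordinates are stored as doubles, so round trips are exact.
#' @return `invisible(path)`
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "pcd", "xyz"),
                        binary = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  if (format == "auto") format <- .pc_format_from_path(path)
  switch(format,
         ply = .write_ply(cloud, path, binary),
         pcd = .write_pcd(cloud, path),
         xyz = .write_xyz(cloud, path))
  invisible(path)
}

# --- XYZ text dialect: whitespace separated, 3 or 6 columns, '#' comments ---

.read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("no points in XYZ file: ", path)
  toks <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  ncols <- lengths(toks)
  if (!all(ncols %in% c(3L, 6L)) || length(unique(ncols)) != 1L) {
    bad <- keep[which(!(ncols %in% c(3L, 6L)) | ncols != ncols[1])[1]]
    stop("malformed XYZ record at line ", bad, " of ", path,
         " (expected 3 or 6 columns)")
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad <- keep[ceiling(which(is.na(vals))[1] / ncols[1])]
    stop("non-numeric value at line ", bad, " of ", path)
  }
  m <- matrix(vals, ncol = ncols[1], byrow = TRUE)
  point_cloud(m[, 1:3, drop = FALSE],
              if (ncols[1] == 6L) m[, 4:6, drop = FALSE])
}

.write_xyz <- function(cloud, path) {
  m <- cloud$points
  if (!is.null(cloud$colors)) m <- cbind(m, cloud$colors)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = " ")),
             path)
}

# --- PLY ---------------------------------------------------------------------

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(raw, off, type) {
  sz <- .ply_type_size[[type]]
  bytes <- raw[(off + 1L):(off + sz)]
  val <- switch(type,
    char = , int8 = readBin(bytes, "integer", size = 1, signed = TRUE),
    uchar = , uint8 = readBin(bytes, "integer", size = 1, signed = FALSE),
    short = , int16 = readBin(bytes, "integer", size = 2, endian = "little"),
    ushort = , uint16 = readBin(bytes, "integer", size = 2, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(bytes, "integer", size = 4, endian = "little"),
    float = , float32 = readBin(bytes, "double", size = 4, endian = "little"),
    double = , float64 = readBin(bytes, "double", size = 8, endian = "little"))
  list(value = as.double(val), off = off + sz)
}

.read_ply <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  # header is ASCII up to "end_header\n"
  marker <- charToRaw("end_header")
  hdr_end <- NA_integer_
  limit <- min(length(raw), 65536L)
  for (i in seq_len(limit - length(marker))) {
    if (raw[i] == marker[1] &&
        identical(raw[i:(i + length(marker) - 1L)], marker)) {
      j <- i + length(marker)
      while (j <= length(raw) && raw[j] != as.raw(10L)) j <- j + 1L
      hdr_end <- j
      break
    }
  }
  if (is.na(hdr_end)) stop("not a PLY file (no end_header): ", path)
  header <- strsplit(rawToChar(raw[1:hdr_end]), "\r?\n")[[1]]
  if (!grepl("^ply", header[1])) stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) stop("PLY missing format line: ", path)
  fmt <- strsplit(trimws(fmt_line), "[[:space:]]+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format '", fmt, "' in ", path)

  elements <- list()
  cur <- NULL
  for (ln in header) {
    toks <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(toks) == 0L) next
    if (toks[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = toks[2], count = as.integer(toks[3]), props = list())
    } else if (toks[1] == "property" && !is.null(cur)) {
      if (toks[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = toks[5], type = toks[4], list = TRUE, count_type = toks[3])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = toks[3], type = toks[2], list = FALSE)
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || elements$vertex$count < 1L)
    stop("PLY has no vertices: ", path)

  parse_vertex <- function(rows) {
    pnames <- vapply(elements$vertex$props, `[[`, "", "name")
    need <- match(c("x", "y", "z"), pnames)
    if (anyNA(need)) stop("PLY vertex element lacks x/y/z properties: ", path)
    pts <- rows[, need, drop = FALSE]
    cid <- match(c("red", "green", "blue"), pnames)
    cols <- if (!anyNA(cid)) rows[, cid, drop = FALSE]
    point_cloud(pts, cols)
  }

  if (fmt == "ascii") {
    body <- strsplit(trimws(rawToChar(raw[(hdr_end + 1L):length(raw)])),
                     "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    pos <- 1L
    out <- NULL
    for (el in elements) {
      if (any(vapply(el$props, `[[`, TRUE, "list"))) {
        pos <- pos + el$count  # one line per list row
        next
      }
      n <- el$count
      if (pos + n - 1L > length(body))
        stop("PLY truncated in element '", el$name, "': ", path)
      if (el$name == "vertex") {
        toks <- strsplit(trimws(body[pos:(pos + n - 1L)]), "[[:space:]]+")
        np <- length(el$props)
        if (any(lengths(toks) != np))
          stop("malformed PLY vertex record near line ",
               pos + which(lengths(toks) != np)[1], " of body: ", path)
        rows <- matrix(as.numeric(unlist(toks)), ncol = np, byrow = TRUE)
        out <- parse_vertex(rows)
      }
      pos <- pos + n
    }
    if (is.null(out)) stop("PLY vertex element not found in body: ", path)
    return(out)
  }

  # binary little endian: walk elements sequentially
  off <- hdr_end  # 0-based offset of first body byte is hdr_end (1-based raw)
  out <- NULL
  for (el in elements) {
    if (el$name == "vertex") {
      np <- length(el$props)
      rows <- matrix(0, el$count, np)
      # fast path: all scalar properties
      if (!any(vapply(el$props, `[[`, TRUE, "list"))) {
        for (r in seq_len(el$count)) {
          for (pi in seq_len(np)) {
            sc <- .ply_read_scalar(raw, off, el$props[[pi]]$type)
            rows[r, pi] <- sc$value
            off <- sc$off
          }
        }
        out <- parse_vertex(rows)
      } else stop("list properties on vertex element unsupported: ", path)
    } else {
      for (r in seq_len(el$count)) {
        for (pr in el$props) {
          if (pr$list) {
            cnt <- .ply_read_scalar(raw, off, pr$count_type)
            off <- cnt$off + .ply_type_size[[pr$type]] * as.integer(cnt$value)
          } else {
            off <- off + .ply_type_size[[pr$type]]
          }
        }
      }
    }
  }
  if (is.null(out)) stop("PLY vertex element not found: ", path)
  out
}

.write_ply <- function(cloud, path, binary = FALSE) {
  n <- nrow(cloud$points)
  has_col <- !is.null(cloud$colors)
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
           paste("element vertex", n),
           "property double x", "property double y", "property double z")
  if (has_col)
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  hdr <- c(hdr, "end_header")
  if (!binary) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    m <- cloud$points
    lines <- sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3])
    if (has_col) {
      cc <- round(cloud$colors)
      lines <- paste(lines, sprintf("%d %d %d", cc[, 1], cc[, 2], cc[, 3]))
    }
    writeLines(lines, con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    if (has_col) {
      cc <- round(cloud$colors)
      for (i in seq_len(n)) {
        writeBin(as.double(cloud$points[i, ]), con, size = 8, endian = "little")
        writeBin(as.integer(cc[i, ]), con, size = 1)
      }
    } else {
      writeBin(as.double(t(cloud$points)), con, size = 8, endian = "little")
    }
  }
}

# --- PCD (ascii) -------------------------------------------------------------

.read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), lines, value = TRUE)
    if (length(ln) == 0L) return(NULL)
    strsplit(trimws(ln[1]), "[[:space:]]+")[[1]][-1]
  }
  fields <- get_field("FIELDS")
  if (is.null(fields)) stop("PCD missing FIELDS header: ", path)
  types <- get_field("TYPE")
  npts <- as.integer(get_field("POINTS")[1])
  data_mode <- tolower(get_field("DATA")[1])
  if (!identical(data_mode, "ascii"))
    stop("only ascii PCD supported (DATA ", data_mode, "): ", path)
  start <- grep("^DATA\\b", lines)[1] + 1L
  body <- lines[start:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < npts) stop("PCD truncated: ", path)
  toks <- strsplit(trimws(body[seq_len(npts)]), "[[:space:]]+")
  if (any(lengths(toks) != length(fields)))
    stop("malformed PCD record at data line ",
         which(lengths(toks) != length(fields))[1], " of ", path)
  m <- matrix(as.numeric(unlist(toks)), ncol = length(fields), byrow = TRUE)
  xi <- match(c("x", "y", "z"), fields)
  if (anyNA(xi)) stop("PCD lacks x/y/z fields: ", path)
  pts <- m[, xi, drop = FALSE]
  cols <- NULL
  ri <- match("rgb", fields)
  if (!is.na(ri)) {
    if (!is.null(types) && types[ri] == "F")
      stop("float-packed rgb PCD field unsupported; use TYPE U: ", path)
    packed <- as.integer(m[, ri])
    cols <- cbind(bitwAnd(bitwShiftR(packed, 16L), 255L),
                  bitwAnd(bitwShiftR(packed, 8L), 255L),
                  bitwAnd(packed, 255L))
  }
  point_cloud(pts, cols)
}

.write_pcd <- function(cloud, path) {
  n <- nrow(cloud$points)
  has_col <- !is.null(cloud$colors)
  fields <- if (has_col) "x y z rgb" else "x y z"
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7",
           paste("FIELDS", fields),
           paste("SIZE", if (has_col) "8 8 8 4" else "8 8 8"),
           paste("TYPE", if (has_col) "F F F U" else "F F F"),
           paste("COUNT", if (has_col) "1 1 1 1" else "1 1 1"),
           paste("WIDTH", n), "HEIGHT 1",
           "VIEWPOINT 0 0 0 1 0 0 0",
           paste("POINTS", n), "DATA ascii")
  m <- cloud$points
  lines <- sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3])
  if (has_col) {
    cc <- round(cloud$colors)
    packed <- cc[, 1] * 65536 + cc[, 2] * 256 + cc[, 3]
    lines <- paste(lines, format(packed, scientific = FALSE, trim = TRUE))
  }
  writeLines(c(hdr, lines), path)
}
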