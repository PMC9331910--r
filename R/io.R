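#' Read a point cloud from PLY, PCD or XYZ
#'
#' Supported dialects: ASCII and binary-little-endian PLY 1.0 with float or
#' double x,y,z (and optionally nx,ny,nz) vertex properties; ASCII PCD v0.7
#' with FIELDS x y z [normal_x normal_y normal_z]; whitespace-separated XYZ
#' text with 3 or 6 columns. Point order is preserved. Coordinates are
#' multiplied by \code{unit} to convert into the package's internal
#' centimetres.
#'
#' @param path file path.
#' @param format "ply", "pcd" or "xyz"; default guesses from the extension.
#' @param unit scale factor to cm (1 = file already in cm, 100 = file in m).
#' @return A \linkS4class{PointCloud}.
#' @export
readCloud <- function(path, format = c("auto", "ply", "pcd", "xyz"), unit = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.info(path)$size == 0) stop("empty cloud: file has no content: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     ply = "ply", pcd = "pcd", xyz = "xyz", txt = "xyz",
                     stop("cannot guess format from extension of ", path))
  }
  cl <- switch(format,
               ply = .readPLY(path),
               pcd = .readPCD(path),
               xyz = .readXYZ(path))
  if (nrow(cl@points) == 0) stop("empty cloud: no points in ", path)
  if (unit != 1) cl <- pointCloud(cl@points * unit, normals = cl@normals)
  cl
}

.readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ASCII lines
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("malformed PLY header (no end_header): ", path)
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 1000) stop("malformed PLY header (runaway) in ", path)
  }
  if (!grepl("^ply", header[1])) stop("malformed PLY header at line 1: not a PLY file")
  fmtLine <- grep("^format ", header, value = TRUE)
  if (length(fmtLine) != 1) stop("malformed PLY header: missing format line")
  binary <- grepl("binary_little_endian", fmtLine)
  if (!binary && !grepl("ascii", fmtLine))
    stop("unsupported PLY format: ", fmtLine)

  # vertex element and its properties (only the vertex element is read)
  elLines <- grep("^element ", header)
  vLine <- grep("^element vertex ", header)
  if (length(vLine) != 1) stop("malformed PLY header: need exactly one vertex element")
  nVert <- as.integer(sub("^element vertex +", "", header[vLine]))
  nxtEl <- elLines[elLines > vLine]
  endIdx <- if (length(nxtEl)) min(nxtEl) else length(header)
  propLines <- header[(vLine + 1):(endIdx - 1)]
  propLines <- grep("^property ", propLines, value = TRUE)
  if (any(grepl("^property list", propLines)))
    stop("malformed PLY header: list property inside vertex element")
  toks <- strsplit(trimws(propLines), "\\s+")
  types <- vapply(toks, `[`, "", 2)
  names_ <- vapply(toks, `[`, "", 3)
  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L, float = 4L,
             float32 = 4L, double = 8L, float64 = 8L)
  if (!all(types %in% names(sizes)))
    stop("malformed PLY header: unknown property type ",
         paste(setdiff(types, names(sizes)), collapse = ", "))
  need <- c("x", "y", "z")
  if (!all(need %in% names_)) stop("malformed PLY header: vertex needs x, y, z")
  hasN <- all(c("nx", "ny", "nz") %in% names_)
  if (vLine != elLines[1] && length(elLines) > 1)
    stop("unsupported PLY layout: vertex element must come first")

  if (binary) {
    vals <- matrix(NA_real_, nVert, length(names_))
    rdrs <- lapply(seq_along(types), function(i) {
      tp <- types[i]
      if (tp %in% c("float", "float32")) function(c) readBin(c, "double", 1, size = 4, endian = "little")
      else if (tp %in% c("double", "float64")) function(c) readBin(c, "double", 1, size = 8, endian = "little")
      else if (tp %in% c("uchar", "uint8", "char", "int8")) function(c) as.numeric(readBin(c, "integer", 1, size = 1, endian = "little"))
      else if (tp %in% c("short", "int16", "ushort", "uint16")) function(c) as.numeric(readBin(c, "integer", 1, size = 2, endian = "little"))
      else function(c) as.numeric(readBin(c, "integer", 1, size = 4, endian = "little"))
    })
    for (r in seq_len(nVert)) {
      for (ci in seq_along(rdrs)) {
        v <- rdrs[[ci]](con)
        if (length(v) == 0) stop("malformed PLY: unexpected end of binary data at vertex ", r)
        vals[r, ci] <- v
      }
    }
  } else {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    if (length(body) < nVert) stop("malformed PLY: expected ", nVert,
                                   " vertex records, found ", length(body))
    body <- body[seq_len(nVert)]
    vals <- matrix(NA_real_, nVert, length(names_))
    sp <- strsplit(trimws(body), "\\s+")
    for (r in seq_len(nVert)) {
      row <- suppressWarnings(as.numeric(sp[[r]]))
      if (length(row) < length(names_) || anyNA(row[seq_along(names_)]))
        stop("malformed PLY record at data line ", r)
      vals[r, ] <- row[seq_along(names_)]
    }
  }
  colnames(vals) <- names_
  normals <- if (hasN) vals[, c("nx", "ny", "nz"), drop = FALSE] else NULL
  pointCloud(vals[, c("x", "y", "z"), drop = FALSE], normals = normals)
}

.readPCD <- function(path) {
  lines <- readLines(path)
  hEnd <- grep("^DATA ", lines)
  if (length(hEnd) != 1) stop("malformed PCD header: missing DATA line")
  if (!grepl("^DATA\\s+ascii", lines[hEnd]))
    stop("unsupported PCD: only ASCII data is supported")
  fieldsLine <- grep("^FIELDS ", lines, value = TRUE)
  if (length(fieldsLine) != 1) stop("malformed PCD header: missing FIELDS")
  fields <- strsplit(trimws(sub("^FIELDS ", "", fieldsLine)), "\\s+")[[1]]
  if (!all(c("x", "y", "z") %in% fields)) stop("malformed PCD: need x y z fields")
  hasN <- all(c("normal_x", "normal_y", "normal_z") %in% fields)
  ptsLine <- grep("^POINTS ", lines, value = TRUE)
  nPts <- if (length(ptsLine)) as.integer(sub("^POINTS +", "", ptsLine[1])) else NA
  body <- lines[(hEnd + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (!is.na(nPts) && length(body) < nPts)
    stop("malformed PCD: expected ", nPts, " points, found ", length(body))
  if (!is.na(nPts)) body <- body[seq_len(nPts)]
  sp <- strsplit(trimws(body), "\\s+")
  vals <- matrix(NA_real_, length(body), length(fields))
  for (r in seq_along(sp)) {
    row <- suppressWarnings(as.numeric(sp[[r]]))
    if (length(row) < length(fields) || anyNA(row[seq_along(fields)]))
      stop("malformed PCD record at data line ", r)
    vals[r, ] <- row[seq_along(fields)]
  }
  colnames(vals) <- fields
  normals <- if (hasN) vals[, c("normal_x", "normal_y", "normal_z"), drop = FALSE] else NULL
  pointCloud(vals[, c("x", "y", "z"), drop = FALSE], normals = normals)
}

.readXYZ <- function(path) {
  vals <- tryCatch(as.matrix(utils::read.table(path, comment.char = "#")),
                   error = function(e) stop("malformed XYZ file ", path, ": ",
                                            conditionMessage(e)))
  storage.mode(vals) <- "double"
  if (anyNA(vals)) stop("malformed XYZ record (non-numeric field) in ", path)
  if (ncol(vals) == 3) pointCloud(vals)
  else if (ncol(vals) >= 6) pointCloud(vals[, 1:3, drop = FALSE],
                                       normals = vals[, 4:6, drop = FALSE])
  else stop("malformed XYZ file: need 3 or 6 columns, found ", ncol(vals))
}

#' Write a point cloud to PLY, PCD or XYZ
#'
#' Normals are emitted iff present. Written files carry a comment recording
#' the unit (cm). ASCII PLY/PCD/XYZ use full double precision so a
#' write/read round trip preserves coordinates to printed precision; binary
#' PLY is bit-exact (float64 properties).
#'
#' @param cloud a non-empty \linkS4class{PointCloud}.
#' @param path output path.
#' @param format "ply", "pcd" or "xyz"; default guesses from the extension.
#' @param binary write binary-little-endian PLY instead of ASCII.
#' @return \code{path}, invisibly.
#' @export
writeCloud <- function(cloud, path, format = c("auto", "ply", "pcd", "xyz"),
                       binary = FALSE) {
  stopifnot(is(cloud, "PointCloud"))
  if (nrow(cloud@points) == 0) stop("refusing to write an empty cloud")
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     ply = "ply", pcd = "pcd", xyz = "xyz",
                     stop("cannot guess format from extension of ", path))
  }
  switch(format,
         ply = .writePLY(cloud, path, binary),
         pcd = .writePCD(cloud, path),
         xyz = .writeXYZ(cloud, path))
  invisible(path)
}

.writePLY <- function(cloud, path, binary) {
  p <- cloud@points
  nm <- cloud@normals
  hasN <- !is.null(nm)
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
              "comment unit cm",
              paste("element vertex", nrow(p)),
              "property float64 x", "property float64 y", "property float64 z",
              if (hasN) c("property float64 nx", "property float64 ny",
                          "property float64 nz"),
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  dat <- if (hasN) cbind(p, nm) else p
  if (binary) {
    writeBin(as.numeric(t(dat)), con, size = 8, endian = "little")
  } else {
    writeLines(apply(dat, 1, function(r)
      paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = " ")), con)
  }
}

.writePCD <- function(cloud, path) {
  p <- cloud@points
  nm <- cloud@normals
  hasN <- !is.null(nm)
  fields <- if (hasN) "x y z normal_x normal_y normal_z" else "x y z"
  nf <- if (hasN) 6 else 3
  header <- c("# .PCD v0.7 - Point Cloud Data file format",
              "# unit cm",
              "VERSION 0.7",
              paste("FIELDS", fields),
              paste("SIZE", paste(rep(8, nf), collapse = " ")),
              paste("TYPE", paste(rep("F", nf), collapse = " ")),
              paste("COUNT", paste(rep(1, nf), collapse = " ")),
              paste("WIDTH", nrow(p)),
              "HEIGHT 1",
              "VIEWPOINT 0 0 0 1 0 0 0",
              paste("POINTS", nrow(p)),
              "DATA ascii")
  dat <- if (hasN) cbind(p, nm) else p
  body <- apply(dat, 1, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = " "))
  writeLines(c(header, body), path)
}

.writeXYZ <- function(cloud, path) {
  p <- cloud@points
  nm <- cloud@normals
  dat <- if (!is.null(nm)) cbind(p, nm) else p
  body <- apply(dat, 1, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = " "))
  writeLines(c("# unit cm", body), path)
}
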