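#' Read a point cloud from disk
#'
#' Supports LAS (1.2-1.4, point record formats 0-3), PLY (ascii and
#' binary-little-endian) and delimited ASCII XYZ (whitespace or comma
#' separated, `#` comment lines ignored). Coordinates are returned in
#' meters; for LAS the per-file scale and offset are applied so values are
#' real-world. When coordinates are UTM-scale (beyond 1e4 m) a local frame
#' origin is split off and stored on the cloud (see [point_cloud()]).
#'
#' @param path file to read.
#' @param format one of `"auto"`, `"las"`, `"ply"`, `"xyz"`. `"auto"`
#'   dispatches on the file extension.
#' @return a `point_cloud`; LAS classification codes and PLY extra
#'   properties are preserved as attributes.
#' @export
read_point_cloud <- function(path, format = c("auto", "las", "ply", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      las = "las", laz = "las", ply = "ply",
      xyz = "xyz", txt = "xyz", csv = "xyz",
      stop(sprintf("unknown point-cloud format for '%s'", path)))
  }
  cloud <- switch(format,
    las = read_las(path),
    ply = read_ply(path),
    xyz = read_xyz(path))
  localize_origin(cloud)
}

#' Write a point cloud to disk
#'
#' The written file round-trips through [read_point_cloud()] with
#' coordinate error at most 1e-6 m (XYZ, PLY) or the LAS scale quantum
#' (default 1 mm). Attributes travel where the format allows: `class` into
#' the LAS classification field, any numeric attribute into extra PLY
#' properties.
#'
#' @param cloud a `point_cloud`.
#' @param path destination file.
#' @param format one of `"las"`, `"ply"`, `"xyz"`; default from extension.
#' @param las_scale coordinate quantum for LAS output, meters.
#' @param las_offset optional 3-vector of LAS coordinate offsets.
#' @param binary write binary-little-endian PLY instead of ascii.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path,
                              format = c("auto", "las", "ply", "xyz"),
                              las_scale = 0.001, las_offset = NULL,
                              binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, las = "las", ply = "ply", xyz = "xyz",
                     stop(sprintf("unknown point-cloud format for '%s'", path)))
  }
  switch(format,
    las = write_las(cloud, path, scale = las_scale, offset = las_offset),
    ply = write_ply(cloud, path, binary = binary),
    xyz = write_xyz(cloud, path))
  invisible(path)
}

# move very large coordinates into the stored origin to keep the working
# frame numerically small
localize_origin <- function(cloud) {
  if (n_points(cloud) == 0 || any(cloud$origin != 0)) return(cloud)
  mins <- apply(cloud$coords, 2, min)
  if (all(abs(range(cloud$coords)) < 1e4)) return(cloud)
  origin <- floor(mins)
  point_cloud(sweep(cloud$coords, 2, origin, "-"), cloud$attrs, origin)
}

## ---- ASCII XYZ ----------------------------------------------------------

read_xyz <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop(sprintf("cannot read '%s': %s",
                                                    path, conditionMessage(e))))
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) return(point_cloud(NULL))
  parts <- strsplit(trimws(gsub(",", " ", lines[keep])), "\\s+")
  short <- which(lengths(parts) < 3)
  if (length(short))
    stop(sprintf("parse error in '%s' at line %d: fewer than 3 columns",
                 path, keep[short[1]]))
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[1:3]), numeric(3)))
  bad <- which(colSums(is.na(vals)) > 0)
  if (length(bad))
    stop(sprintf("parse error in '%s' at line %d: non-numeric value",
                 path, keep[bad[1]]))
  point_cloud(t(vals))
}

write_xyz <- function(cloud, path) {
  m <- pc_coords(cloud, absolute = TRUE)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e))))
  on.exit(close(con))
  if (nrow(m) > 0)
    writeLines(sprintf("%.9f %.9f %.9f", m[, 1], m[, 2], m[, 3]), con)
  invisible(path)
}

## ---- PLY ----------------------------------------------------------------

.ply_types <- data.frame(
  name = c("char", "int8", "uchar", "uint8", "short", "int16", "ushort",
           "uint16", "int", "int32", "uint", "uint32", "float", "float32",
           "double", "float64"),
  size = c(1, 1, 1, 1, 2, 2, 2, 2, 4, 4, 4, 4, 4, 4, 8, 8),
  what = c("integer", "integer", "integer", "integer", "integer", "integer",
           "integer", "integer", "integer", "integer", "integer", "integer",
           "double", "double", "double", "double"),
  signed = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
             FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop(sprintf("'%s': truncated PLY header", path))
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 1000) stop(sprintf("'%s': runaway PLY header", path))
  }
  if (trimws(header[1]) != "ply") stop(sprintf("'%s' is not a PLY file", path))
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("'%s': unsupported PLY format '%s'", path, fmt))
  # parse elements and their properties
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = character(), types = character())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props <- c(cur$props, tok[5]); cur$types <- c(cur$types, "list")
      } else {
        cur$props <- c(cur$props, tok[3]); cur$types <- c(cur$types, tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) stop(sprintf("'%s': no vertex element", path))

  for (el in elements) {
    if (el$name == "vertex") {
      vert <- read_ply_element(con, el, fmt, path)
      break
    }
    skip_ply_element(con, el, fmt, path)
  }
  need <- c("x", "y", "z")
  if (!all(need %in% colnames(vert)))
    stop(sprintf("'%s': vertex element lacks x/y/z", path))
  extra <- setdiff(colnames(vert), need)
  attrs <- NULL
  if (length(extra)) {
    attrs <- lapply(extra, function(nm) {
      v <- vert[, nm]
      if (nm %in% c("class", "classification", "row_id")) as.integer(v) else v
    })
    names(attrs) <- sub("^classification$", "class", extra)
  }
  point_cloud(vert[, need, drop = FALSE], attrs)
}

read_ply_element <- function(con, el, fmt, path) {
  if (any(el$types == "list"))
    stop(sprintf("'%s': list properties on vertex element are unsupported",
                 path))
  n <- el$count
  p <- length(el$props)
  if (fmt == "ascii") {
    if (n == 0) {
      m <- matrix(numeric(0), ncol = p)
    } else {
      lines <- readLines(con, n = n)
      vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines),
                                                          "\\s+"))))
      if (length(vals) != n * p || anyNA(vals))
        stop(sprintf("'%s': malformed ascii vertex data", path))
      m <- matrix(vals, ncol = p, byrow = TRUE)
    }
  } else {
    ti <- match(el$types, .ply_types$name)
    if (anyNA(ti)) stop(sprintf("'%s': unknown PLY property type", path))
    sizes <- .ply_types$size[ti]
    rowsize <- sum(sizes)
    raw <- readBin(con, "raw", n * rowsize)
    if (length(raw) < n * rowsize)
      stop(sprintf("'%s': truncated PLY vertex data", path))
    rawm <- matrix(raw, nrow = rowsize)
    offs <- cumsum(c(0, sizes))
    m <- matrix(0, nrow = n, ncol = p)
    for (j in seq_len(p)) {
      bytes <- as.vector(rawm[(offs[j] + 1):offs[j + 1], , drop = FALSE])
      v <- readBin(bytes, .ply_types$what[ti[j]], n = n, size = sizes[j],
                   signed = if (sizes[j] < 4) .ply_types$signed[ti[j]] else TRUE,
                   endian = "little")
      if (!.ply_types$signed[ti[j]] && sizes[j] == 4)
        v <- ifelse(v < 0, as.numeric(v) + 2^32, as.numeric(v))
      m[, j] <- v
    }
  }
  colnames(m) <- el$props
  m
}

skip_ply_element <- function(con, el, fmt, path) {
  if (fmt == "ascii") {
    readLines(con, n = el$count)
  } else {
    if (any(el$types == "list"))
      stop(sprintf("'%s': cannot skip binary list element before vertices",
                   path))
    sizes <- .ply_types$size[match(el$types, .ply_types$name)]
    readBin(con, "raw", el$count * sum(sizes))
  }
  invisible(NULL)
}

write_ply <- function(cloud, path, binary = FALSE) {
  m <- pc_coords(cloud, absolute = TRUE)
  attrs <- cloud$attrs
  extra <- names(attrs)
  extra_type <- vapply(extra, function(nm)
    if (is.integer(attrs[[nm]])) "int" else "double", character(1))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e))))
  on.exit(close(con))
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    sprintf("element vertex %d", nrow(m)),
    "property double x", "property double y", "property double z",
    if (length(extra)) sprintf("property %s %s", extra_type, extra),
    "end_header")
  writeLines(header, con)
  if (nrow(m) == 0) return(invisible(path))
  cols <- c(list(m[, 1], m[, 2], m[, 3]), unname(attrs[extra]))
  if (binary) {
    for (i in seq_len(nrow(m))) {
      for (j in seq_along(cols)) {
        v <- cols[[j]][i]
        if (j > 3 && extra_type[j - 3] == "int")
          writeBin(as.integer(v), con, size = 4, endian = "little")
        else writeBin(as.double(v), con, size = 8, endian = "little")
      }
    }
  } else {
    fmt <- paste(c("%.9f", "%.9f", "%.9f",
                   if (length(extra))
                     ifelse(extra_type == "int", "%d", "%.9f")),
                 collapse = " ")
    writeLines(do.call(sprintf, c(list(fmt), cols)), con)
  }
  invisible(path)
}

## ---- LAS ----------------------------------------------------------------

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop(sprintf("'%s' is not a LAS file", path))
  hdr <- readBin(con, "raw", 371)  # rest of the largest (1.4) header
  u8  <- function(off) as.integer(hdr[off - 4 + 1])
  u16 <- function(off) readBin(hdr[(off - 4 + 1):(off - 4 + 2)], "integer",
                               size = 2, signed = FALSE, endian = "little")
  u32 <- function(off) {
    v <- readBin(hdr[(off - 4 + 1):(off - 4 + 4)], "integer", size = 4,
                 endian = "little")
    if (v < 0) v + 2^32 else as.numeric(v)
  }
  dbl <- function(off) readBin(hdr[(off - 4 + 1):(off - 4 + 8)], "double",
                               size = 8, endian = "little")
  ver <- c(u8(24), u8(25))
  if (ver[1] != 1 || !ver[2] %in% 1:4)
    stop(sprintf("'%s': unsupported LAS version %d.%d", path, ver[1], ver[2]))
  data_offset <- u32(96)
  pdrf <- u8(104)
  if (bitwAnd(pdrf, 0x80) != 0)
    stop(sprintf("'%s': LAZ compression is not supported", path))
  if (pdrf > 5)
    stop(sprintf("'%s': unsupported LAS point format %d", path, pdrf))
  reclen <- u16(105)
  n <- u32(107)
  scale <- c(dbl(131), dbl(139), dbl(147))
  offset <- c(dbl(155), dbl(163), dbl(171))
  if (n == 0 && ver[2] == 4) {  # LAS 1.4 64-bit count (low word suffices)
    n <- u32(247)
  }
  seek(con, data_offset)
  raw <- readBin(con, "raw", n * reclen)
  if (length(raw) < n * reclen)
    stop(sprintf("'%s': truncated LAS point data", path))
  rawm <- matrix(raw, nrow = reclen)
  geti32 <- function(off) readBin(as.vector(rawm[(off + 1):(off + 4), ,
                                                 drop = FALSE]),
                                  "integer", n = n, size = 4,
                                  endian = "little")
  x <- geti32(0) * scale[1] + offset[1]
  y <- geti32(4) * scale[2] + offset[2]
  z <- geti32(8) * scale[3] + offset[3]
  cls <- as.integer(rawm[16, ])  # classification byte, formats 0-5
  point_cloud(cbind(x, y, z), attrs = list(class = cls))
}

write_las <- function(cloud, path, scale = 0.001, offset = NULL) {
  m <- pc_coords(cloud, absolute = TRUE)
  n <- nrow(m)
  if (is.null(offset))
    offset <- if (n > 0) floor(apply(m, 2, min)) else c(0, 0, 0)
  scale <- rep_len(as.double(scale), 3)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e))))
  on.exit(close(con))
  w8  <- function(v) writeBin(as.integer(v), con, size = 1)
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wd  <- function(v) writeBin(as.double(v), con, size = 8, endian = "little")
  writeChar("LASF", con, 4, eos = NULL)
  w16(0); w16(0)                       # file source id, global encoding
  writeBin(raw(16), con)               # GUID
  w8(1); w8(2)                         # version 1.2
  writeBin(raw(64), con)               # system id + generating software
  w16(1); w16(2026)                    # day / year
  w16(227)                             # header size
  w32(227)                             # offset to point data
  w32(0)                               # number of VLRs
  w8(0)                                # point data record format 0
  w16(20)                              # record length
  w32(n)
  for (i in 1:5) w32(0)                # points by return
  wd(scale)
  wd(offset)
  rng <- if (n > 0) apply(m, 2, range) else matrix(0, 2, 3)
  wd(c(rng[2, 1], rng[1, 1], rng[2, 2], rng[1, 2], rng[2, 3], rng[1, 3]))
  if (n > 0) {
    xi <- as.integer(round((m[, 1] - offset[1]) / scale[1]))
    yi <- as.integer(round((m[, 2] - offset[2]) / scale[2]))
    zi <- as.integer(round((m[, 3] - offset[3]) / scale[3]))
    cls <- pc_attr(cloud, "class")
    if (is.null(cls)) cls <- integer(n)
    rec <- matrix(as.raw(0), nrow = 20, ncol = n)
    rec[1:4, ]   <- matrix(writeBin(xi, raw(), size = 4, endian = "little"), 4)
    rec[5:8, ]   <- matrix(writeBin(yi, raw(), size = 4, endian = "little"), 4)
    rec[9:12, ]  <- matrix(writeBin(zi, raw(), size = 4, endian = "little"), 4)
    rec[15, ]    <- as.raw(0x09)       # single return, first of one
    rec[16, ]    <- as.raw(cls %% 256)
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}
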