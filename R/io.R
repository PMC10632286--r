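#' Mesh file input/output
#'
#' Binary and ASCII STL, and binary (little-endian) or ASCII PLY. Units are
#' assumed to be millimetres. STL files store independent triangles;
#' reading welds identical vertices back together.
#'
#' @param path file path; format chosen from the extension (.stl/.ply).
#' @param mesh a `surface_mesh`.
#' @name mesh-io
NULL

#' @rdname mesh-io
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl_binary(mesh, path),
         ply = write_ply_binary(mesh, path),
         stop("unsupported mesh format '", ext, "' (use .stl or .ply)",
              call. = FALSE))
  invisible(path)
}

#' @rdname mesh-io
#' @export
read_mesh <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("mesh file missing or empty: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         stop("unsupported mesh format '", ext, "'", call. = FALSE))
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 80)), con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  fc <- face_corners(mesh)
  nrm <- cross3(fc$b - fc$a, fc$c - fc$a)
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, 1e-300)
  block <- matrix(0, nf, 12)
  block[, 1:3] <- nrm
  block[, 4:6] <- fc$a
  block[, 7:9] <- fc$b
  block[, 10:12] <- fc$c
  attr_bytes <- as.raw(c(0, 0))
  for (i in seq_len(nf)) {
    writeBin(as.numeric(block[i, ]), con, size = 4, endian = "little")
    writeBin(attr_bytes, con)
  }
}

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  if (grepl("^solid", rawToChar(head[1:5])) && is_ascii_stl(path))
    return(read_stl_ascii(path))
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  tris <- matrix(NA_real_, nf, 9)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "raw", 2)
    tris[i, ] <- rec[4:12]
  }
  soup_to_mesh(tris, basename(path))
}

is_ascii_stl <- function(path) {
  txt <- readLines(path, n = 5, warn = FALSE)
  any(grepl("facet|endsolid", txt))
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  if (is.null(nums) || nrow(nums) %% 3 != 0)
    stop("malformed ASCII STL: ", path, call. = FALSE)
  tris <- matrix(t(matrix(t(nums), nrow = 3 * 3)), ncol = 9, byrow = TRUE)
  soup_to_mesh(tris, basename(path))
}

# independent-triangle soup (rows = 9 coords) -> welded surface_mesh
soup_to_mesh <- function(tris, name) {
  nf <- nrow(tris)
  v <- rbind(tris[, 1:3, drop = FALSE], tris[, 4:6, drop = FALSE],
             tris[, 7:9, drop = FALSE])
  f <- cbind(seq_len(nf), nf + seq_len(nf), 2 * nf + seq_len(nf))
  weld_vertices(surface_mesh(v, f, name = name), digits = 6)
}

write_ply_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           paste("element vertex", nrow(mesh$vertices)),
           "property double x", "property double y", "property double z",
           paste("element face", nrow(mesh$faces)),
           "property list uchar int vertex_indices", "end_header")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.numeric(t(mesh$vertices)), con, size = 8, endian = "little")
  for (i in seq_len(nrow(mesh$faces))) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4, endian = "little")
  }
}

read_ply <- function(path) {
  # read the whole file, split header from body at "end_header\n"
  raw <- readBin(path, "raw", file.size(path))
  hdr_end <- grepRaw("end_header\n", raw, fixed = TRUE)
  if (length(hdr_end) == 0) stop("malformed PLY header: ", path, call. = FALSE)
  hdr <- strsplit(rawToChar(raw[seq_len(hdr_end - 1)]), "\n")[[1]]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  body_at <- hdr_end + nchar("end_header\n")
  if (any(grepl("format ascii", hdr))) {
    txt <- strsplit(rawToChar(raw), "\n")[[1]]
    start <- grep("^end_header", txt)[1]
    vl <- txt[start + seq_len(nv)]
    v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[1:3])))
    fl <- txt[start + nv + seq_len(nf)]
    f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x)
      as.integer(x[2:4]) + 1L))
    return(surface_mesh(v, f, name = basename(path)))
  }
  sz <- if (any(grepl("property double x", hdr))) 8L else 4L
  off <- body_at
  vbytes <- raw[off:(off + 3 * sz * nv - 1)]
  v <- matrix(readBin(vbytes, "numeric", 3 * nv, size = sz, endian = "little"),
              ncol = 3, byrow = TRUE)
  off <- off + 3 * sz * nv
  f <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    cnt <- as.integer(raw[off])
    if (cnt != 3) stop("only triangle PLY faces are supported", call. = FALSE)
    f[i, ] <- readBin(raw[(off + 1):(off + 12)], "integer", 3, size = 4,
                      endian = "little") + 1L
    off <- off + 13
  }
  surface_mesh(v, f, name = basename(path))
}
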