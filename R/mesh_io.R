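# Mesh file input/output: PLY (binary little-endian and ascii), STL (binary
# and ascii) and OBJ (vertices/faces only). Binary PLY stores coordinates as
# doubles, so a write/read round trip is bit-exact. STL duplicates vertices
# per facet; they are merged on read and the winding made consistent.

#' Read a surface mesh
#'
#' Dialect is selected by file extension (`.ply`, `.stl`, `.obj`). Duplicate
#' vertices are merged (STL) and face winding repaired so the enclosed volume
#' is positive for closed surfaces.
#'
#' @param path file path.
#' @return a [trimesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path) || file.info(path)$size == 0)
    stop_md("format-error", "missing or empty mesh file: %s", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    ply = read_ply(path),
    stl = read_stl(path),
    obj = read_obj(path),
    stop_md("format-error", "unsupported mesh format: .%s", ext)
  )
  repair_orientation(mesh)
}

#' Write a surface mesh
#'
#' @param mesh a [trimesh()].
#' @param path output path; `.ply` (binary little-endian, double precision,
#'   with per-vertex normals), `.stl` (binary) or `.obj`.
#' @param ascii write the ascii dialect instead of binary (PLY/STL only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(mesh, path, ascii = ascii),
    stl = write_stl(mesh, path, ascii = ascii),
    obj = write_obj(mesh, path),
    stop_md("format-error", "unsupported mesh format: .%s", ext)
  )
  invisible(path)
}

# ---- orientation ----

#' Make face winding consistent and outward
#'
#' Breadth-first propagation of winding across shared edges, then a global
#' flip if the signed volume of a closed result is negative. Open meshes are
#' returned with consistent (but possibly inward) winding.
#'
#' @param mesh a [trimesh()].
#' @export
repair_orientation <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  if (nf == 0) return(mesh)
  nv <- nrow(mesh$vertices)
  he <- mesh_halfedges(mesh)
  ek <- edge_keys(he, nv)
  fid <- rep(seq_len(nf), times = 3L)
  ord <- order(ek)
  ek_s <- ek[ord]
  fid_s <- fid[ord]
  # adjacency: faces sharing an edge (runs of equal keys)
  runs <- rle(ek_s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  adj <- vector("list", nf)
  for (i in seq_along(starts)) {
    if (runs$lengths[i] < 2L) next
    fs <- fid_s[starts[i]:ends[i]]
    for (a in fs) adj[[a]] <- c(adj[[a]], setdiff(fs, a))
  }
  flipped <- rep(FALSE, nf)
  visited <- rep(FALSE, nf)
  dir_keys <- function(face, flip) {
    tri <- f[face, ]
    if (flip) tri <- tri[c(1, 3, 2)]
    (c(tri[1], tri[2], tri[3]) - 1) * as.double(nv) + c(tri[2], tri[3], tri[1])
  }
  for (root in seq_len(nf)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      dk_cur <- dir_keys(cur, flipped[cur])
      for (nb in adj[[cur]]) {
        if (visited[nb]) next
        # consistent winding traverses a shared edge in opposite directions;
        # a shared directed edge means the neighbour must be flipped
        flipped[nb] <- any(dir_keys(nb, FALSE) %in% dk_cur)
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  if (any(flipped)) f[flipped, ] <- f[flipped, c(1, 3, 2), drop = FALSE]
  out <- trimesh(mesh$vertices, f, mesh$normals)
  vol <- tryCatch(if (is_watertight(out)) mesh_volume(out) else NA_real_,
                  error = function(e) NA_real_)
  if (!is.na(vol) && vol < 0)
    out <- trimesh(out$vertices, out$faces[, c(1, 3, 2), drop = FALSE], out$normals)
  out
}

# ---- PLY ----

write_ply <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices
  nrm <- mesh$normals
  if (is.null(nrm)) nrm <- vertex_normals(mesh)
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ply",
    if (ascii) "format ascii 1.0" else "format binary_little_endian 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    "property double nx", "property double ny", "property double nz",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  writeLines(hdr, con, sep = "\n")
  if (ascii) {
    dat <- cbind(v, nrm)
    writeLines(apply(dat, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                               collapse = " ")), con, sep = "\n")
    writeLines(apply(f, 1, function(r) paste(c(3L, r - 1L), collapse = " ")),
               con, sep = "\n")
  } else {
    writeBin(as.vector(t(cbind(v, nrm))), con, size = 8, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ascii lines
  read_line <- function() {
    chars <- raw(0)
    repeat {
      ch <- readBin(con, "raw", 1)
      if (length(ch) == 0 || ch == as.raw(10)) break
      chars <- c(chars, ch)
    }
    sub("\r$", "", rawToChar(chars))
  }
  magic <- read_line()
  if (!identical(magic, "ply")) stop_md("format-error", "not a PLY file: %s", path)
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    ln <- read_line()
    if (ln == "end_header") break
    if (ln == "" && length(elements) == 0 && is.null(fmt))
      stop_md("format-error", "truncated PLY header")
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
      elements[[tok[2]]] <- cur
    } else if (tok[1] == "property") {
      p <- if (tok[2] == "list") list(list = TRUE, ctype = tok[3], itype = tok[4], name = tok[5])
           else list(list = FALSE, type = tok[2], name = tok[3])
      elements[[cur$name]]$props <- c(elements[[cur$name]]$props, list(p))
      cur <- elements[[cur$name]]
    }
  }
  if (is.null(fmt) || !"vertex" %in% names(elements) || !"face" %in% names(elements))
    stop_md("format-error", "PLY missing vertex/face elements")
  nv <- elements$vertex$count
  nf <- elements$face$count
  vprops <- elements$vertex$props
  typesize <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
                int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
                float = 4, float32 = 4, double = 8, float64 = 8)
  read_scalar <- function(type, n = 1) {
    sz <- typesize[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", n, size = sz, endian = "little")
    else
      readBin(con, "integer", n, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }
  if (identical(fmt, "ascii")) {
    vlines <- vapply(seq_len(nv), function(i) read_line(), character(1))
    vdat <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), as.numeric))
    flines <- vapply(seq_len(nf), function(i) read_line(), character(1))
    fdat <- lapply(strsplit(trimws(flines), "\\s+"), as.integer)
  } else if (identical(fmt, "binary_little_endian")) {
    vdat <- matrix(NA_real_, nv, length(vprops))
    fixed <- all(!vapply(vprops, `[[`, TRUE, "list"))
    if (!fixed) stop_md("format-error", "list properties on vertices unsupported")
    types <- vapply(vprops, `[[`, "", "type")
    if (length(unique(types)) == 1L) {
      raw_all <- read_scalar(types[1], nv * length(vprops))
      vdat <- matrix(raw_all, nv, length(vprops), byrow = TRUE)
    } else {
      for (i in seq_len(nv))
        for (j in seq_along(vprops)) vdat[i, j] <- read_scalar(types[j])
    }
    fdat <- vector("list", nf)
    fp <- elements$face$props[[1]]
    for (i in seq_len(nf)) {
      cnt <- read_scalar(fp$ctype)
      fdat[[i]] <- c(cnt, read_scalar(fp$itype, cnt))
    }
  } else stop_md("format-error", "unsupported PLY format: %s", fmt)
  pnames <- vapply(vprops, `[[`, "", "name")
  xyz <- match(c("x", "y", "z"), pnames)
  if (anyNA(xyz)) stop_md("format-error", "PLY vertex element lacks x/y/z")
  v <- vdat[, xyz, drop = FALSE]
  nrm <- NULL
  nidx <- match(c("nx", "ny", "nz"), pnames)
  if (!anyNA(nidx)) nrm <- vdat[, nidx, drop = FALSE]
  faces <- do.call(rbind, lapply(fdat, function(r) {
    if (r[1] != 3L) stop_md("format-error", "non-triangular PLY face")
    r[2:4] + 1L
  }))
  trimesh(v, faces, nrm)
}

# ---- STL ----

write_stl <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- face_normals(mesh)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid morphodetail", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3) {
        p <- v[f[i, k], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid morphodetail", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(fn[i, ]), con, size = 4, endian = "little")
      for (k in 1:3)
        writeBin(as.numeric(v[f[i, k], ]), con, size = 4, endian = "little")
      writeBin(as.integer(0L), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", min(80, sz))
  is_ascii <- grepl("^solid", rawToChar(head80[seq_len(min(5, length(head80)))]))
  # binary STL also often starts with "solid"; check size consistency
  if (!is_ascii || sz >= 84) {
    close(con)
    con <- file(path, "rb")
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!is.na(ntri) && sz == 84 + 50 * ntri) {
      tris <- matrix(NA_real_, ntri * 3, 3)
      for (i in seq_len(ntri)) {
        invisible(readBin(con, "double", 3, size = 4, endian = "little"))
        for (k in 1:3)
          tris[(i - 1) * 3 + k, ] <- readBin(con, "double", 3, size = 4, endian = "little")
        invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      }
      close(con)
      return(stl_weld(tris))
    }
  }
  close(con)
  # ascii
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop_md("format-error", "malformed ascii STL: %s", path)
  tris <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                function(t) as.numeric(t[2:4])))
  stl_weld(tris)
}

# merge exactly coincident vertices of an unindexed triangle soup
stl_weld <- function(tris) {
  key <- paste(tris[, 1], tris[, 2], tris[, 3], sep = "_")
  uid <- match(key, unique(key))
  v <- tris[!duplicated(key), , drop = FALSE]
  f <- matrix(uid, ncol = 3, byrow = TRUE)
  trimesh(v, f)
}

# ---- OBJ ----

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0 || length(fl) == 0)
    stop_md("format-error", "OBJ without vertices or faces: %s", path)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(t) as.numeric(t[2:4])))
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(t) {
    idx <- vapply(t[-1], function(s) as.integer(strsplit(s, "/")[[1]][1]), 1L)
    if (length(idx) != 3L) stop_md("format-error", "non-triangular OBJ face")
    idx
  }))
  trimesh(v, f)
}
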