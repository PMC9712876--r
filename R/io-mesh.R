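#' Read or write a triangle mesh (PLY or OBJ)
#'
#' `read_mesh`/`write_mesh` dispatch on the file extension. PLY supports both
#' `ascii` and `binary_little_endian` encodings (vertices as float64 on write);
#' OBJ is the plain `v`/`f` subset. Faces with more than three sides are
#' fan-triangulated on read.
#'
#' @param path File path ending in `.ply` or `.obj`.
#' @param mesh A [surface_mesh].
#' @param format For PLY writing: `"binary"` (little-endian, default) or
#'   `"ascii"`.
#' @return `read_mesh` returns a [surface_mesh]; `write_mesh` returns `path`
#'   invisibly.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_mesh: no such file: %s", path))
  switch(tolower(tools::file_ext(path)),
         ply = read_ply(path),
         obj = read_obj(path),
         stop(sprintf("read_mesh: unsupported mesh format: %s", path)))
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path, format = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "surface_mesh"))
  switch(tolower(tools::file_ext(path)),
         ply = write_ply(mesh, path, format = match.arg(format)),
         obj = write_obj(mesh, path),
         stop(sprintf("write_mesh: unsupported mesh format: %s", path)))
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply")) stop("read_ply: not a PLY file (missing magic)")
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = data.frame(type, name, list_count_type))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("read_ply: unexpected end of header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok) || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(list = TRUE, count_type = tok[3], type = tok[4], name = tok[5])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(list = FALSE, type = tok[2], name = tok[3])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else {
      stop(sprintf("read_ply: unsupported header line: %s", line))
    }
  }
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop(sprintf("read_ply: unsupported PLY format '%s'", fmt))
  }
  if (is.null(elements$vertex) || is.null(elements$face)) {
    stop("read_ply: PLY file must contain vertex and face elements")
  }
  if (fmt == "ascii") {
    body <- readLines(con)
    parsed <- parse_ply_ascii(body, elements)
  } else {
    parsed <- parse_ply_binary(con, elements)
  }
  surface_mesh(parsed$vertices, parsed$faces)
}

ply_type_size <- function(type) {
  switch(type,
         char = , uchar = , int8 = , uint8 = 1L,
         short = , ushort = , int16 = , uint16 = 2L,
         int = , uint = , int32 = , uint32 = , float = , float32 = 4L,
         double = , float64 = 8L,
         stop(sprintf("read_ply: unknown property type '%s'", type)))
}

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size(type)
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "double", n = 1L, size = sz, endian = "little")
  } else {
    readBin(con, "integer", n = 1L, size = sz,
            signed = !(sz < 4L && grepl("^u", type)), endian = "little")
  }
}

parse_ply_binary <- function(con, elements) {
  out <- list()
  for (el in elements) {
    if (el$name == "vertex") {
      nprop <- length(el$props)
      pnames <- vapply(el$props, `[[`, "", "name")
      vals <- matrix(0, el$count, nprop)
      for (i in seq_len(el$count)) {
        for (j in seq_len(nprop)) vals[i, j] <- ply_read_scalar(con, el$props[[j]]$type)
      }
      out$vertices <- vals[, match(c("x", "y", "z"), pnames), drop = FALSE]
    } else if (el$name == "face") {
      prop <- el$props[[1]]
      faces <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        k <- ply_read_scalar(con, prop$count_type)
        idx <- integer(k)
        for (j in seq_len(k)) idx[j] <- ply_read_scalar(con, prop$type)
        faces[[i]] <- idx + 1L
      }
      out$faces <- triangulate_fans(faces)
    }
  }
  out
}

parse_ply_ascii <- function(body, elements) {
  out <- list()
  pos <- 1L
  for (el in elements) {
    lines <- body[pos:(pos + el$count - 1L)]
    pos <- pos + el$count
    if (el$name == "vertex") {
      pnames <- vapply(el$props, `[[`, "", "name")
      vals <- do.call(rbind, lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
      out$vertices <- vals[, match(c("x", "y", "z"), pnames), drop = FALSE]
    } else if (el$name == "face") {
      faces <- lapply(lines, function(l) {
        v <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
        v[-1][seq_len(v[1])] + 1L
      })
      out$faces <- triangulate_fans(faces)
    }
  }
  out
}

triangulate_fans <- function(faces) {
  tris <- lapply(faces, function(idx) {
    if (length(idx) < 3L) stop("read_ply: face with fewer than 3 vertices")
    cbind(idx[1], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
  })
  do.call(rbind, tris)
}

write_ply <- function(mesh, path, format = "binary") {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  hdr <- c(
    "ply",
    sprintf("format %s 1.0",
            if (format == "binary") "binary_little_endian" else "ascii"),
    sprintf("element vertex %d", nv),
    "property float64 x", "property float64 y", "property float64 z",
    sprintf("element face %d", nf),
    "property list uchar int32 vertex_indices",
    "end_header")
  if (format == "ascii") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(mesh$vertices, 1, function(v) {
      paste(format(v, digits = 17, scientific = FALSE, trim = TRUE), collapse = " ")
    }), con)
    writeLines(apply(mesh$faces, 1, function(f) {
      paste(c(3L, f - 1L), collapse = " ")
    }), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(t(mesh$vertices)), con, size = 8L, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (!length(vlines) || !length(flines)) {
    stop("read_obj: file contains no vertices or no faces")
  }
  vertices <- do.call(rbind, lapply(vlines, function(l) {
    as.numeric(strsplit(trimws(sub("^v", "", l)), "\\s+")[[1]][1:3])
  }))
  faces <- lapply(flines, function(l) {
    toks <- strsplit(trimws(sub("^f", "", l)), "\\s+")[[1]]
    as.integer(vapply(strsplit(toks, "/"), `[[`, "", 1L))
  })
  surface_mesh(vertices, triangulate_fans(faces))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1, function(v) {
    paste("v", paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
                     collapse = " "))
  }), con)
  writeLines(apply(mesh$faces, 1, function(f) {
    paste("f", paste(f, collapse = " "))
  }), con)
  invisible(path)
}
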