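#' Read a labeled surface mesh from OFF or PLY
#'
#' OFF files carry geometry only; face labels then come from a sidecar CSV
#' with columns \code{face_index} (1-based) and \code{label}. PLY files
#' (ascii or binary little-endian) may carry an integer per-face property
#' named \code{label} (0 = basolateral, 1 = apical) or use the same sidecar.
#'
#' @param path mesh file (.off or .ply, by extension or content).
#' @param label_path optional sidecar CSV path (face_index,label).
#' @return a \code{\link{labeled_mesh}}.
#' @export
read_labeled_mesh <- function(path, label_path = NULL) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "off") read_off(path) else read_ply(path)
  lab <- m$label
  if (!is.null(label_path)) {
    d <- read.csv(label_path)
    if (!all(c("face_index", "label") %in% names(d)))
      stop("sidecar label CSV needs columns face_index, label")
    lab <- rep(NA_character_, nrow(m$faces))
    lab[d$face_index] <- as.character(d$label)
    if (anyNA(lab)) stop("sidecar labels missing for ", sum(is.na(lab)), " faces")
  }
  if (is.null(lab)) stop("no face labels: supply a PLY 'label' property or a sidecar CSV")
  labeled_mesh(m$vertices, m$faces, lab)
}

read_off <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (!grepl("OFF", ln[1])) stop("not an OFF file: ", path)
  counts <- scan(text = ln[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  body <- scan(text = paste(ln[-(1:2)], collapse = "\n"), quiet = TRUE)
  v <- matrix(body[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  rest <- body[-seq_len(3 * nv)]
  f <- matrix(NA_integer_, nf, 3)
  pos <- 1
  for (i in seq_len(nf)) {
    k <- rest[pos]
    if (k != 3) stop("only triangle faces are supported (face ", i, " has ", k, " vertices)")
    f[i, ] <- rest[pos + 1:3] + 1L
    pos <- pos + k + 1
  }
  list(vertices = v, faces = f, label = NULL)
}

#' Write a mesh as OFF (geometry) plus a sidecar label CSV
#'
#' @param mesh a \code{\link{labeled_mesh}}.
#' @param path output .off path; labels go to \code{<path>.labels.csv}.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(format(r, digits = 10), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  lab_path <- paste0(path, ".labels.csv")
  write.csv(data.frame(face_index = seq_len(nrow(mesh$faces)),
                       label = mesh$face_label),
            lab_path, row.names = FALSE)
  invisible(path)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", 1, size = sz, endian = "little")
  else
    readBin(con, "integer", 1, size = sz, endian = "little",
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()  # each: list(name, count, props = list(list(name,type,list_count_type)))
  cur <- NULL
  repeat {
    l <- trimws(readLines(con, n = 1))
    if (length(l) == 0) stop("unexpected end of PLY header")
    tok <- strsplit(l, "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      p <- if (tok[2] == "list")
        list(name = tok[5], type = tok[4], list_count_type = tok[3])
      else list(name = tok[3], type = tok[2], list_count_type = NULL)
      cur$props[[p$name]] <- p
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY file lacks vertex/face elements")
  ascii <- identical(fmt, "ascii")
  if (!ascii && !identical(fmt, "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  if (ascii) {
    rest <- scan(con, what = double(), quiet = TRUE)
    pos <- 1
    take <- function(n) { out <- rest[pos:(pos + n - 1)]; pos <<- pos + n; out }
  }
  out <- list()
  for (el in elements) {
    nprop <- length(el$props)
    pnames <- names(el$props)
    vals <- vector("list", nprop)
    names(vals) <- pnames
    for (p in pnames) vals[[p]] <- vector("list", el$count)
    for (i in seq_len(el$count)) {
      for (p in pnames) {
        pr <- el$props[[p]]
        if (is.null(pr$list_count_type)) {
          vals[[p]][[i]] <- if (ascii) take(1) else ply_read_scalar(con, pr$type)
        } else {
          k <- if (ascii) take(1) else ply_read_scalar(con, pr$list_count_type)
          vals[[p]][[i]] <- if (ascii) take(k)
            else vapply(seq_len(k), function(j) ply_read_scalar(con, pr$type), numeric(1))
        }
      }
    }
    out[[el$name]] <- vals
  }
  v <- cbind(unlist(out$vertex$x), unlist(out$vertex$y), unlist(out$vertex$z))
  idx_name <- intersect(c("vertex_indices", "vertex_index"), names(out$face))[1]
  if (is.na(idx_name)) stop("PLY face element lacks vertex_indices")
  fl <- out$face[[idx_name]]
  if (any(lengths(fl) != 3)) stop("only triangle faces are supported")
  f <- matrix(unlist(fl), ncol = 3, byrow = TRUE) + 1L
  lab <- NULL
  if ("label" %in% names(out$face)) {
    lv <- unlist(out$face$label)
    lab <- ifelse(lv != 0, "apical", "basolateral")
  }
  list(vertices = v, faces = f, label = lab)
}

#' Write a labeled mesh as ascii PLY with a per-face label property
#'
#' @param mesh a \code{\link{labeled_mesh}}.
#' @param path output .ply path.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "property int label",
               "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(format(r, digits = 10), collapse = " ")), con)
  lab <- as.integer(mesh$face_label == "apical")
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L, lab), con)
  invisible(path)
}
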