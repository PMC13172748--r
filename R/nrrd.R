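# Minimal NRRD I/O for 3-D scalar volumes with attached headers.
# Supports the fields produced by common research tools (3D Slicer, ITK):
# raw or gzip encoding, little/big endian, the usual integer/float types,
# spacing from either "spacings" or diagonal "space directions". Sufficient
# for binary structure masks; not a general NRRD implementation (no detached
# headers, no block type, no per-axis kinds beyond "domain").

nrrd_types <- list(
  "signed char" = list(what = "integer", size = 1L, signed = TRUE),
  "int8" = list(what = "integer", size = 1L, signed = TRUE),
  "uchar" = list(what = "integer", size = 1L, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1L, signed = FALSE),
  "uint8" = list(what = "integer", size = 1L, signed = FALSE),
  "short" = list(what = "integer", size = 2L, signed = TRUE),
  "int16" = list(what = "integer", size = 2L, signed = TRUE),
  "ushort" = list(what = "integer", size = 2L, signed = FALSE),
  "uint16" = list(what = "integer", size = 2L, signed = FALSE),
  "int" = list(what = "integer", size = 4L, signed = TRUE),
  "int32" = list(what = "integer", size = 4L, signed = TRUE),
  "uint" = list(what = "integer", size = 4L, signed = TRUE),
  "uint32" = list(what = "integer", size = 4L, signed = TRUE),
  "float" = list(what = "double", size = 4L, signed = TRUE),
  "double" = list(what = "double", size = 8L, signed = TRUE)
)

read_mask_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000[0-9]$", magic))
    stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop("truncated NRRD header: ", path, call. = FALSE)
    if (line == "") break              # blank line separates header and data
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[trimws(m[2])]] <- trimws(m[3])
  }

  dim_n <- as.integer(fields[["dimension"]])
  if (is.na(dim_n) || dim_n != 3L)
    stop("only 3-D NRRD volumes are supported: ", path, call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "[[:space:]]+")[[1]])
  type <- nrrd_types[[tolower(fields[["type"]])]]
  if (is.null(type))
    stop("unsupported NRRD type: ", fields[["type"]], call. = FALSE)
  endian <- if (identical(fields[["endian"]], "big")) "big" else "little"
  encoding <- tolower(fields[["encoding"]] %||% "raw")

  n <- prod(sizes)
  if (encoding == "raw") {
    vals <- readBin(con, what = type$what, n = n, size = type$size,
                    signed = type$signed, endian = endian)
  } else if (encoding %in% c("gzip", "gz")) {
    comp <- readBin(con, what = "raw", n = file.size(path))
    vals <- readBin(memDecompress(comp, type = "gzip"), what = type$what,
                    n = n, size = type$size, signed = type$signed,
                    endian = endian)
  } else {
    stop("unsupported NRRD encoding: ", encoding, call. = FALSE)
  }
  if (length(vals) < n)
    stop("NRRD data shorter than header sizes: ", path, call. = FALSE)

  spacing_mm <- nrrd_spacing(fields)
  origin_mm <- nrrd_origin(fields)
  unit_scale <- nrrd_unit_scale(fields)  # -> cm
  mask_volume(array(vals != 0, sizes),
              spacing = spacing_mm * unit_scale,
              origin = origin_mm * unit_scale)
}

nrrd_spacing <- function(fields) {
  if (!is.null(fields[["spacings"]]))
    return(abs(as.numeric(strsplit(fields[["spacings"]], "[[:space:]]+")[[1]])))
  sd <- fields[["space directions"]]
  if (!is.null(sd)) {
    vecs <- regmatches(sd, gregexpr("\\(([^)]*)\\)", sd))[[1]]
    rows <- lapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
    return(vapply(rows, function(r) sqrt(sum(r^2)), numeric(1)))
  }
  stop("NRRD header has neither 'spacings' nor 'space directions'",
       call. = FALSE)
}

nrrd_origin <- function(fields) {
  so <- fields[["space origin"]]
  if (is.null(so)) return(c(0, 0, 0))
  as.numeric(strsplit(gsub("[()]", "", so), ",")[[1]])
}

nrrd_unit_scale <- function(fields) {
  units <- fields[["space units"]] %||% fields[["units"]] %||% ""
  if (grepl("\"cm\"|\\bcm\\b", units)) 1 else 0.1  # default: mm
}

write_mask_nrrd <- function(mask, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# binary structure mask",
    "type: uchar",
    "dimension: 3",
    "space: left-posterior-superior",
    paste("sizes:", paste(dim(mask$grid), collapse = " ")),
    paste0("space directions: ",
           paste(sprintf("(%g,%g,%g)",
                         c(mask$spacing[1] * 10, 0, 0),
                         c(0, mask$spacing[2] * 10, 0),
                         c(0, 0, mask$spacing[3] * 10)), collapse = " ")),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    paste0("space origin: (", paste(mask$origin * 10, collapse = ","), ")"),
    "space units: \"mm\" \"mm\" \"mm\"",
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.raw(as.integer(mask$grid)), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
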