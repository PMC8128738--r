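# Minimal NRRD 3D scalar volume support. Covers the subset this package
# writes and needs to read back: dimension 3, little-endian, encodings
# "raw" and "gzip", scalar types double/float/short/int. The NRRD header is
# plain "key: value" text terminated by a blank line, followed by the data
# block in the same file.

nrrd_types <- list(
  double = list(size = 8L, what = "double", signed = TRUE),
  float  = list(size = 4L, what = "double", signed = TRUE),
  short  = list(size = 2L, what = "integer", signed = TRUE),
  int    = list(size = 4L, what = "integer", signed = TRUE)
)

nrrd_type_alias <- c("double" = "double", "float" = "float",
                     "short" = "short", "int16" = "short",
                     "signed short" = "short", "int" = "int",
                     "int32" = "int", "signed int" = "int")

read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic))
    stop("'", path, "' is not an NRRD file (bad magic '", magic, "')")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("NRRD header not terminated by blank line")
    if (line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) != 3L) stop("malformed NRRD header line: ", line)
    fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  need <- function(nm) {
    if (is.null(fields[[nm]])) stop("NRRD header missing field '", nm, "'")
    fields[[nm]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop("only 3D NRRD volumes are supported")
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  tname <- nrrd_type_alias[[tolower(need("type"))]]
  if (is.null(tname)) stop("unsupported NRRD type: ", fields$type)
  typ <- nrrd_types[[tname]]
  enc <- tolower(need("encoding"))
  endian <- if (!is.null(fields$endian)) tolower(fields$endian) else "little"
  if (endian != "little") stop("only little-endian NRRD data supported")
  n <- prod(sizes)
  if (enc == "raw") {
    vals <- readBin(con, typ$what, n = n, size = typ$size, endian = "little")
  } else if (enc %in% c("gzip", "gz")) {
    comp <- readBin(con, "raw", n = file.size(path))
    vals <- readBin(memDecompress(comp, type = "gzip"), typ$what, n = n,
                    size = typ$size, endian = "little")
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("NRRD data block truncated")
  # spacing: prefer "space directions" (diagonal) over "spacings"
  sp <- rep(1, 3)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    if (length(vecs) != 3L) stop("expected three space direction vectors")
    mat <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
    sp <- sqrt(colSums(mat^2))
  } else if (!is.null(fields$spacings)) {
    sp <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  thick <- if (!is.null(fields[["thicknesses"]]))
    as.numeric(strsplit(fields[["thicknesses"]], "\\s+")[[1]])[3] else sp[3]
  ct_volume(array(vals, sizes), pixel_spacing = sp[1:2],
            slice_thickness = thick, slice_spacing = sp[3], origin = origin)
}

write_nrrd_volume <- function(volume, path) {
  d <- dim(volume$voxels)
  hdr <- c("NRRD0004",
           "# written by macscore",
           "type: double",
           "dimension: 3",
           "space: left-posterior-superior",
           paste("sizes:", paste(d, collapse = " ")),
           sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
                   volume$pixel_spacing[1], volume$pixel_spacing[2],
                   volume$slice_spacing),
           sprintf("thicknesses: nan nan %.10g", volume$slice_thickness),
           "kinds: domain domain domain",
           "endian: little",
           "encoding: raw",
           sprintf("space origin: (%.10g,%.10g,%.10g)",
                   volume$origin[1], volume$origin[2], volume$origin[3]),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(volume$voxels), con, size = 8L, endian = "little")
  invisible(path)
}
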