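# Minimal MetaImage (ITK .mha/.mhd) support: uncompressed, axis-aligned,
# identity direction, element types MET_DOUBLE / MET_FLOAT / MET_SHORT /
# MET_UCHAR. Covers round-trip storage of CT-like volumes; not a general
# MetaIO implementation.

metaimage_types <- list(
  MET_DOUBLE = list(what = "double", size = 8L),
  MET_FLOAT  = list(what = "double", size = 4L),
  MET_SHORT  = list(what = "integer", size = 2L),
  MET_UCHAR  = list(what = "integer", size = 1L)
)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  # header is line-oriented ASCII; for .mha the raw payload follows the
  # "ElementDataFile = LOCAL" line in the same file
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("MetaImage: truncated header in ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(kv) != 3L) stop("MetaImage: bad header line: ", line)
    hdr[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "0")
  if (ndims != 3L) stop("MetaImage: payload is not 3D (NDims = ", ndims, ")")
  if (!is.null(hdr$BinaryData) && tolower(hdr$BinaryData) != "true")
    stop("MetaImage: only binary data supported")
  if (!is.null(hdr$CompressedData) && tolower(hdr$CompressedData) == "true")
    stop("MetaImage: compressed data not supported")
  dim3 <- as.integer(strsplit(trimws(hdr$DimSize), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(hdr$ElementSpacing %||% "1 1 1"),
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(hdr$Offset %||% hdr$Origin %||% "0 0 0"),
                                "\\s+")[[1]])
  type <- metaimage_types[[hdr$ElementType %||% "MET_DOUBLE"]]
  if (is.null(type)) stop("MetaImage: unsupported ElementType ", hdr$ElementType)
  swap <- !is.null(hdr$ElementByteOrderMSB) &&
    tolower(hdr$ElementByteOrderMSB) == "true"
  n <- prod(dim3)
  datafile <- hdr$ElementDataFile
  if (identical(datafile, "LOCAL")) {
    raw <- readBin(con, type$what, n = n, size = type$size,
                   endian = if (swap) "big" else "little")
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath)) stop("MetaImage: missing data file ", rawpath)
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, type$what, n = n, size = type$size,
                   endian = if (swap) "big" else "little")
  }
  if (length(raw) != n) stop("MetaImage: data truncated in ", path)
  volume_image(array(as.numeric(raw), dim3), spacing, origin)
}

write_metaimage <- function(v, path) {
  local_data <- grepl("\\.mha$", path)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %s", paste(format(v$origin, digits = 17), collapse = " ")),
    sprintf("ElementSpacing = %s",
            paste(format(v$spacing, digits = 17), collapse = " ")),
    sprintf("DimSize = %s", paste(dim(v$data), collapse = " ")),
    "ElementType = MET_DOUBLE"
  )
  if (local_data) {
    con <- file(path, "wb")
    on.exit(close(con))
    writLines <- paste0(c(header, "ElementDataFile = LOCAL"), "\n")
    writeChar(paste(writLines, collapse = ""), con, eos = NULL)
    writeBin(as.vector(v$data), con, size = 8L, endian = "little")
  } else {
    rawname <- sub("\\.mhd$", ".raw", basename(path))
    writeLines(c(header, sprintf("ElementDataFile = %s", rawname)), path)
    rcon <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(rcon))
    writeBin(as.vector(v$data), rcon, size = 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
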