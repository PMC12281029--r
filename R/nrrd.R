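# NRRD reader and writer (attached data, raw or gzip encoding, 3D scalar).
#
# The header is the text block up to the first blank line; voxel data follow
# immediately.  Geometry comes from `space directions` (one world-step vector
# per array axis = one affine column) and `space origin`; the writer declares
# RAS+ space.  Detached headers (`data file:`) are rejected.

.nrrd_type_name <- c(uint8 = "uint8", int16 = "short", int32 = "int",
                     float32 = "float", float64 = "double")

nrrd_parse_type <- function(s) {
  s <- trimws(s)
  switch(s,
    "uint8" = , "uchar" = , "unsigned char" = "uint8",
    "short" = , "int16" = , "signed short" = "int16",
    "int" = , "int32" = , "signed int" = "int32",
    "float" = "float32",
    "double" = "float64",
    vv_format_error(paste("unsupported NRRD type:", s)))
}

nrrd_parse_vectors <- function(s) {
  m <- gregexpr("\\(([^)]*)\\)", s)[[1]]
  vecs <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(vecs, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
}

read_nrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header ends at the first blank line (LF LF, optionally with CR)
  hdr_end <- NA_integer_
  for (i in seq_len(length(bytes) - 1L)) {
    if (bytes[i] == as.raw(10) &&
        (bytes[i + 1L] == as.raw(10) ||
         (bytes[i + 1L] == as.raw(13) && i + 2L <= length(bytes) &&
          bytes[i + 2L] == as.raw(10)))) {
      hdr_end <- i
      break
    }
  }
  if (is.na(hdr_end)) vv_corrupt_error("NRRD: no end-of-header blank line found")
  hdr_lines <- strsplit(rawToChar(bytes[1:hdr_end]), "\r?\n")[[1]]
  data_start <- hdr_end + if (bytes[hdr_end + 1L] == as.raw(13)) 3L else 2L
  if (!grepl("^NRRD000", hdr_lines[1]))
    vv_corrupt_error("not a NRRD file (missing NRRD000x magic line)")
  fields <- list()
  for (ln in hdr_lines[-1]) {
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    kv <- regmatches(ln, regexec("^([^:]+): *(.*)$", ln))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- kv[3]
  }
  if (!is.null(fields[["data file"]]) || !is.null(fields[["datafile"]]))
    vv_format_error("detached NRRD headers are not supported (attached data only)")
  if (as.integer(fields[["dimension"]]) != 3L)
    vv_format_error("only 3D scalar NRRD volumes are supported")
  dtname <- nrrd_parse_type(fields[["type"]])
  shape <- as.integer(strsplit(trimws(fields[["sizes"]]), "[ \t]+")[[1]])
  encoding <- trimws(fields[["encoding"]])
  endian <- if (!is.null(fields[["endian"]])) trimws(fields[["endian"]]) else "little"
  payload <- bytes[data_start:length(bytes)]
  if (encoding %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    vv_format_error(paste("unsupported NRRD encoding:", encoding))
  }
  dt <- .vv_datatypes[[dtname]]
  con <- rawConnection(payload)
  on.exit(close(con))
  data <- read_exact(con, dt$what, prod(shape), dt$size, endian, dt$signed)
  aff <- diag(4)
  if (!is.null(fields[["space directions"]])) {
    vecs <- nrrd_parse_vectors(fields[["space directions"]])
    for (i in seq_along(vecs)) aff[1:3, i] <- vecs[[i]]
  }
  if (!is.null(fields[["space origin"]]))
    aff[1:3, 4] <- nrrd_parse_vectors(fields[["space origin"]])[[1]]
  new_volume(array(data, dim = shape), affine = aff, datatype = dtname,
             source_format = "nrrd")
}

#' Write a volume as NRRD
#'
#' Attached-data NRRD with `space: right-anterior-superior`, declaring the
#' affine through `space directions` / `space origin`.
#'
#' @param vol a `vv_volume`.
#' @param path output path.
#' @param encoding `"raw"` or `"gzip"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(vol, path, encoding = "raw") {
  check_that(is_volume(vol), "vol must be a vv_volume")
  check_that(encoding %in% c("raw", "gzip"), "encoding must be raw or gzip")
  shape <- dim(vol$data)
  vec <- function(v) sprintf("(%s)", paste(sprintf("%.9g", v), collapse = ","))
  hdr <- c(
    "NRRD0004",
    "# voxview volume",
    sprintf("type: %s", .nrrd_type_name[[vol$datatype]]),
    "dimension: 3",
    sprintf("sizes: %s", paste(shape, collapse = " ")),
    "endian: little",
    sprintf("encoding: %s", encoding),
    "space: right-anterior-superior",
    sprintf("space directions: %s", paste(vapply(1:3, function(i)
      vec(vol$affine[1:3, i]), ""), collapse = " ")),
    sprintf("space origin: %s", vec(vol$affine[1:3, 4])),
    ""
  )
  dt <- .vv_datatypes[[vol$datatype]]
  dcon <- rawConnection(raw(0), "wb")
  writeBin(quantize_for(vol$data, vol$datatype), dcon, size = dt$size,
           endian = "little")
  payload <- rawConnectionValue(dcon)
  close(dcon)
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- tryCatch(file(path, "wb"),
                  error = function(e) vv_io_error(paste("cannot open", path)))
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(payload, con)
  invisible(path)
}
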