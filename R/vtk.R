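# Legacy VTK structured-points reader and writer.
#
# Supports DATASET STRUCTURED_POINTS with BINARY (big-endian, per the VTK
# standard) or ASCII scalar data.  Geometry is the ORIGIN + SPACING diagonal;
# VTK stores x-fastest, matching the in-memory array layout.

.vtk_type_name <- c(uint8 = "unsigned_char", int16 = "short", int32 = "int",
                    float32 = "float", float64 = "double")
.vtk_name_type <- c(unsigned_char = "uint8", short = "int16", int = "int32",
                    float = "float32", double = "float64")

read_vtk <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  nl <- which(bytes == as.raw(10))
  get_line <- function(idx) {
    from <- if (idx == 1L) 1L else nl[idx - 1L] + 1L
    trimws(rawToChar(bytes[from:(nl[idx] - 1L)]))
  }
  if (!grepl("^# vtk DataFile", get_line(1)))
    vv_corrupt_error("not a legacy VTK file (missing '# vtk DataFile' line)")
  fmt <- toupper(get_line(3))
  if (!fmt %in% c("BINARY", "ASCII"))
    vv_format_error(paste("unsupported VTK data format:", fmt))
  shape <- NULL; spacing <- c(1, 1, 1); origin <- c(0, 0, 0)
  dtname <- NULL; npoints <- NULL; data_line <- NULL
  i <- 4L
  while (i <= length(nl)) {
    ln <- get_line(i)
    up <- toupper(ln)
    if (grepl("^DATASET", up)) {
      if (!grepl("STRUCTURED_POINTS", up))
        vv_format_error("only STRUCTURED_POINTS VTK datasets are supported")
    } else if (grepl("^DIMENSIONS", up)) {
      shape <- as.integer(strsplit(ln, "[ \t]+")[[1]][2:4])
    } else if (grepl("^SPACING|^ASPECT_RATIO", up)) {
      spacing <- as.numeric(strsplit(ln, "[ \t]+")[[1]][2:4])
    } else if (grepl("^ORIGIN", up)) {
      origin <- as.numeric(strsplit(ln, "[ \t]+")[[1]][2:4])
    } else if (grepl("^POINT_DATA", up)) {
      npoints <- as.numeric(strsplit(ln, "[ \t]+")[[1]][2])
    } else if (grepl("^SCALARS", up)) {
      parts <- strsplit(ln, "[ \t]+")[[1]]
      dtname <- .vtk_name_type[[parts[3]]]
      if (is.null(dtname))
        vv_format_error(paste("unsupported VTK scalar type:", parts[3]))
    } else if (grepl("^LOOKUP_TABLE", up)) {
      data_line <- i
      break
    }
    i <- i + 1L
  }
  if (is.null(shape) || is.null(dtname) || is.null(data_line))
    vv_corrupt_error("VTK file missing DIMENSIONS/SCALARS/LOOKUP_TABLE")
  nvox <- prod(shape)
  if (!is.null(npoints) && npoints != nvox)
    vv_corrupt_error(sprintf("VTK POINT_DATA %d does not match DIMENSIONS product %d",
                             npoints, nvox))
  if (fmt == "BINARY") {
    dt <- .vv_datatypes[[dtname]]
    con <- rawConnection(bytes[(nl[data_line] + 1L):length(bytes)])
    on.exit(close(con))
    data <- read_exact(con, dt$what, nvox, dt$size, "big", dt$signed)
  } else {
    txt <- rawToChar(bytes[(nl[data_line] + 1L):length(bytes)])
    data <- as.numeric(strsplit(trimws(txt), "[ \t\r\n]+")[[1]])
    if (length(data) < nvox)
      vv_corrupt_error(sprintf("truncated VTK ASCII data: expected %d values, got %d",
                               nvox, length(data)))
    data <- data[seq_len(nvox)]
  }
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  new_volume(array(data, dim = shape), affine = aff, datatype = dtname,
             source_format = "vtk_legacy")
}

#' Write a volume as legacy VTK structured points
#'
#' The affine must be a translation + positive diagonal scaling (VTK's
#' structured-points geometry cannot express rotations); reorient with
#' [canonical_ras()] first if needed.
#'
#' @param vol a `vv_volume`.
#' @param path output path.
#' @param ascii write ASCII scalars instead of big-endian binary.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(vol, path, ascii = FALSE) {
  check_that(is_volume(vol), "vol must be a vv_volume")
  M <- vol$affine[1:3, 1:3]
  if (any(abs(M - diag(diag(M))) > 1e-9) || any(diag(M) <= 0))
    vv_validation_error("VTK writer requires a positive diagonal affine; reorient first")
  shape <- dim(vol$data)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) vv_io_error(paste("cannot open", path)))
  on.exit(close(con))
  hdr <- c(
    "# vtk DataFile Version 3.0",
    "voxview volume",
    if (ascii) "ASCII" else "BINARY",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", shape[1], shape[2], shape[3]),
    sprintf("SPACING %.9g %.9g %.9g", M[1, 1], M[2, 2], M[3, 3]),
    sprintf("ORIGIN %.9g %.9g %.9g",
            vol$affine[1, 4], vol$affine[2, 4], vol$affine[3, 4]),
    sprintf("POINT_DATA %d", prod(shape)),
    sprintf("SCALARS voxels %s", .vtk_type_name[[vol$datatype]]),
    "LOOKUP_TABLE default"
  )
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  payload <- quantize_for(vol$data, vol$datatype)
  if (ascii) {
    writeBin(charToRaw(paste0(paste(sprintf("%.9g", payload), collapse = "\n"), "\n")), con)
  } else {
    writeBin(payload, con, size = .vv_datatypes[[vol$datatype]]$size, endian = "big")
  }
  invisible(path)
}
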