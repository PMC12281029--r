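# Format sniffing and the common read entry point.

#' Identify a volume format from its leading bytes
#'
#' Detection order: gzip magic (the decompressed prefix is then sniffed),
#' NIfTI-1 magic `"n+1"`/`"ni1"` at byte offset 344, the NRRD `NRRD000x`
#' magic line, the legacy VTK `# vtk DataFile` line, AFNI HEAD attribute
#' structure, and finally the MGH version field.  `path_hint` breaks the tie
#' between `.mgz` and `.nii.gz` only when the compressed prefix is too short
#' to sniff the inner header.
#'
#' @param first_bytes raw vector: at least the first 352 bytes of the file
#'   (or the whole file when smaller).
#' @param path_hint optional file name used only for the mgz / nii.gz tie.
#' @return One of `"nifti1"`, `"nifti1_gz"`, `"mgh"`, `"mgz"`, `"afni"`,
#'   `"nrrd"`, `"vtk_legacy"`, `"unknown"`.
#' @export
sniff_format <- function(first_bytes, path_hint = "") {
  b <- as.raw(first_bytes)
  n <- length(b)
  if (n == 0L) return("unknown")
  if (n >= 2L && b[1] == as.raw(0x1f) && b[2] == as.raw(0x8b)) {
    inner <- tryCatch({
      con <- gzcon(rawConnection(b))
      on.exit(close(con), add = TRUE)
      readBin(con, "raw", n = 352L)
    }, error = function(e) raw(0), warning = function(w) raw(0))
    if (length(inner) > 0L) {
      inner_fmt <- sniff_format(inner, path_hint = "")
      if (inner_fmt == "nifti1") return("nifti1_gz")
      if (inner_fmt == "mgh") return("mgz")
    }
    if (grepl("\\.mgz$", path_hint, ignore.case = TRUE)) return("mgz")
    return("nifti1_gz")
  }
  if (n >= 348L) {
    magic <- rawToChar(b[345:347])
    if (magic %in% c("n+1", "ni1") && b[348] == as.raw(0)) return("nifti1")
  }
  # printable-ASCII prefix only: text magic lines never contain binary bytes
  printable <- b %in% as.raw(c(9L, 10L, 13L)) | (b >= as.raw(32L) & b <= as.raw(126L))
  cut <- if (all(printable)) n else which(!printable)[1] - 1L
  head_txt <- rawToChar(b[seq_len(min(cut, 512L))])
  if (grepl("^NRRD000", head_txt, useBytes = TRUE)) return("nrrd")
  if (grepl("^# vtk DataFile", head_txt, useBytes = TRUE)) return("vtk_legacy")
  if (grepl("DATASET_RANK", head_txt, fixed = TRUE, useBytes = TRUE) ||
      grepl("type *= *\\w+-attribute", head_txt, useBytes = TRUE)) return("afni")
  if (n >= 30L) {
    con <- rawConnection(b)
    on.exit(close(con), add = TRUE)
    version <- readBin(con, "integer", 1, 4, endian = "big")
    dims <- readBin(con, "integer", 4, 4, endian = "big")
    if (isTRUE(version == 1L) && all(dims >= 1) && all(dims <= 1e5)) return("mgh")
  }
  "unknown"
}

sniff_file <- function(path) {
  if (!file.exists(path)) vv_io_error(paste("file not found:", path))
  nb <- min(file.size(path), 4096L)
  sniff_format(readBin(path, "raw", n = nb), path_hint = path)
}

#' Read a volume in any supported format
#'
#' Sniffs the format from the file's leading bytes (see [sniff_format()]) and
#' dispatches to the matching reader.  Data are returned with any on-disk
#' scale/intercept applied (NIfTI `scl_slope` 0 is treated as 1), byte order
#' resolved, and 4D inputs truncated to their first volume with a warning.
#' The voxel-to-world affine is populated per format: NIfTI sform if
#' `sform_code > 0`, else qform, else a pixdim diagonal; MGH from
#' Mdc / Pxyz_c; AFNI from ORIENT_SPECIFIC / ORIGIN / DELTA; NRRD from
#' `space directions` + `space origin`; VTK from ORIGIN + SPACING.
#'
#' @param path path to a volume file (`.nii`, `.nii.gz`, `.voi`, `.mgh`,
#'   `.mgz`, `.HEAD`/`.BRIK`, `.nrrd`, `.vtk`).
#' @return A [new_volume()].
#' @export
read_volume <- function(path) {
  if (grepl("\\.(HEAD|BRIK)(\\.gz)?$", path)) return(read_afni(path))
  fmt <- sniff_file(path)
  switch(fmt,
    nifti1 = , nifti1_gz = read_nifti(path),
    mgh = , mgz = read_mgh(path),
    afni = read_afni(path),
    nrrd = read_nrrd(path),
    vtk_legacy = read_vtk(path),
    vv_format_error(paste("unsupported or unrecognized volume format:", path)))
}
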