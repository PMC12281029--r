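# AFNI HEAD/BRIK reader and writer.
#
# The .HEAD file is a text attribute list; the .BRIK file holds raw voxel
# data.  AFNI's native world axes are DICOM-ordered LPS+; the voxel->world
# mapping is reconstructed from ORIENT_SPECIFIC / ORIGIN / DELTA and then
# converted to RAS+ by negating the x and y rows (the same interpretation
# nibabel applies).  All 48 ORIENT_SPECIFIC code combinations are accepted
# on read; the writer emits axis-aligned datasets (reorient first if the
# affine has off-axis terms).  BRICK_FLOAT_FACS scaling is applied when
# nonzero and only sub-brick 0 is loaded.

.afni_brick_types <- c(`0` = "uint8", `1` = "int16", `3` = "float32")

parse_afni_head <- function(path) {
  lines <- readLines(path, warn = FALSE)
  attrs <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^type *=", ln)) {
      atype <- trimws(sub("^type *= *", "", ln))
      aname <- trimws(sub("^name *= *", "", lines[i + 1L]))
      count <- as.integer(trimws(sub("^count *= *", "", lines[i + 2L])))
      i <- i + 3L
      if (atype == "string-attribute") {
        val <- character(0)
        while (i <= length(lines) && length(val) == 0) {
          s <- lines[i]
          i <- i + 1L
          s <- sub("^ *'", "", s)
          s <- sub("~ *$", "", s)
          val <- s
        }
        attrs[[aname]] <- val
      } else {
        vals <- numeric(0)
        while (length(vals) < count && i <= length(lines)) {
          vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "[ \t]+")[[1]]))
          i <- i + 1L
        }
        attrs[[aname]] <- vals
      }
    } else {
      i <- i + 1L
    }
  }
  attrs
}

afni_paths <- function(path) {
  base <- sub("\\.(HEAD|BRIK)(\\.gz)?$", "", path)
  brik <- paste0(base, ".BRIK")
  if (!file.exists(brik) && file.exists(paste0(brik, ".gz")))
    brik <- paste0(brik, ".gz")
  list(head = paste0(base, ".HEAD"), brik = brik)
}

read_afni <- function(path) {
  p <- afni_paths(path)
  if (!file.exists(p$head)) vv_io_error(paste("missing HEAD file:", p$head))
  if (!file.exists(p$brik)) vv_io_error(paste("missing BRIK file:", p$brik))
  a <- parse_afni_head(p$head)
  shape <- as.integer(a$DATASET_DIMENSIONS[1:3])
  nvals <- if (!is.null(a$DATASET_RANK)) as.integer(a$DATASET_RANK[2]) else 1L
  if (nvals > 1L) warning("4D input: keeping only the first volume", call. = FALSE)
  tcode <- as.character(as.integer(a$BRICK_TYPES[1]))
  dtname <- .afni_brick_types[[tcode]]
  if (is.null(dtname)) vv_format_error(paste("unsupported BRICK_TYPES code:", tcode))
  endian <- if (!is.null(a$BYTEORDER_STRING) &&
                grepl("MSB", a$BYTEORDER_STRING)) "big" else "little"
  dt <- .vv_datatypes[[dtname]]
  con <- open_maybe_gz(p$brik)
  on.exit(close(con))
  data <- read_exact(con, dt$what, prod(shape), dt$size, endian, dt$signed)
  fac <- if (!is.null(a$BRICK_FLOAT_FACS)) a$BRICK_FLOAT_FACS[1] else 0
  if (!is.na(fac) && fac != 0) data <- data * fac
  orient <- as.integer(a$ORIENT_SPECIFIC[1:3])
  origin <- as.numeric(a$ORIGIN[1:3])
  delta <- as.numeric(a$DELTA[1:3])
  aff_lps <- diag(4) * 0; aff_lps[4, 4] <- 1
  for (i in 1:3) {
    d <- orient[i] %/% 2L + 1L          # 1=x(L), 2=y(P), 3=z(S) in LPS+
    aff_lps[d, i] <- delta[i]
    aff_lps[d, 4] <- origin[i]
  }
  aff <- diag(c(-1, -1, 1, 1)) %*% aff_lps   # LPS+ -> RAS+
  new_volume(array(data, dim = shape), affine = aff, datatype = dtname,
             source_format = "afni")
}

# orientation code for an LPS-space step s along world axis d (1=x,2=y,3=z)
afni_orient_code <- function(d, s_lps) {
  if (d == 1L) { if (s_lps > 0) 0L else 1L }        # R2L / L2R
  else if (d == 2L) { if (s_lps > 0) 3L else 2L }   # A2P / P2A
  else { if (s_lps > 0) 4L else 5L }                # I2S / S2I
}

#' Write a volume as an AFNI HEAD/BRIK pair
#'
#' The volume's affine must be axis-aligned (each column along one world
#' axis); reorient with [canonical_ras()] first if needed.  `int32`/`float64`
#' data are stored as AFNI `float` bricks.
#'
#' @param vol a `vv_volume`.
#' @param path path to the `.HEAD` file (the `.BRIK` is written alongside).
#' @return The `.HEAD` path, invisibly.
#' @export
write_afni <- function(vol, path) {
  check_that(is_volume(vol), "vol must be a vv_volume")
  p <- afni_paths(path)
  dtname <- switch(vol$datatype, int32 = "float32", float64 = "float32", vol$datatype)
  tcode <- c(uint8 = 0L, int16 = 1L, float32 = 3L)[[dtname]]
  shape <- dim(vol$data)
  M <- vol$affine[1:3, 1:3]
  orient <- integer(3); origin <- numeric(3); delta <- numeric(3)
  lps_sign <- c(-1, -1, 1)
  for (i in 1:3) {
    d <- which.max(abs(M[, i]))
    if (any(abs(M[-d, i]) > 1e-6 * abs(M[d, i])))
      vv_validation_error("AFNI writer requires an axis-aligned affine; reorient first")
    s_lps <- lps_sign[d] * M[d, i]
    orient[i] <- afni_orient_code(d, s_lps)
    delta[i] <- s_lps
    origin[i] <- lps_sign[d] * vol$affine[d, 4]
  }
  num_attr <- function(name, vals, type = "float-attribute") {
    vals_s <- if (type == "integer-attribute") sprintf("%d", as.integer(vals))
              else sprintf("%.9g", vals)
    paste(c(sprintf("type = %s", type), sprintf("name = %s", name),
            sprintf("count = %d", length(vals)),
            paste(" ", paste(vals_s, collapse = " "))), collapse = "\n")
  }
  str_attr <- function(name, s) {
    paste(c("type = string-attribute", sprintf("name = %s", name),
            sprintf("count = %d", nchar(s) + 1L), sprintf("'%s~", s)),
          collapse = "\n")
  }
  blocks <- c(
    num_attr("DATASET_RANK", c(3L, 1L, 0L, 0L, 0L, 0L, 0L, 0L), "integer-attribute"),
    num_attr("DATASET_DIMENSIONS", c(shape, 0L, 0L), "integer-attribute"),
    num_attr("ORIENT_SPECIFIC", orient, "integer-attribute"),
    num_attr("ORIGIN", origin),
    num_attr("DELTA", delta),
    num_attr("BRICK_TYPES", tcode, "integer-attribute"),
    num_attr("BRICK_FLOAT_FACS", 0),
    # the full voxel->DICOM(LPS+) affine, as modern AFNI writes it
    num_attr("IJK_TO_DICOM_REAL",
             as.numeric(t(diag(c(-1, -1, 1)) %*% vol$affine[1:3, ]))),
    str_attr("BYTEORDER_STRING", "LSB_FIRST"),
    str_attr("TYPESTRING", "3DIM_HEAD_ANAT")
  )
  writeLines(paste(blocks, collapse = "\n\n"), p$head)
  bcon <- file(sub("\\.gz$", "", p$brik), "wb")
  on.exit(close(bcon))
  dt <- .vv_datatypes[[dtname]]
  writeBin(quantize_for(vol$data, dtname), bcon, size = dt$size, endian = "little")
  invisible(p$head)
}
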