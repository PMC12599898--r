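#' @section DICOM support:
#' The package reads and writes single-frame axial CT DICOM files in the
#' explicit-VR little-endian transfer syntax (1.2.840.10008.1.2.1), covering
#' the attributes the simulation geometry depends on: Image Position
#' (Patient), Image Orientation (Patient), Slice Thickness, Spacing Between
#' Slices, Pixel Spacing, Rescale Slope/Intercept and the pixel module.
#' Compressed, implicit-VR and multi-frame enhanced objects are rejected.
#' @name dicom-support
NULL

.ts_explicit_le <- "1.2.840.10008.1.2.1"
.uid_ct_image <- "1.2.840.10008.5.1.4.1.1.2"
.uid_root <- "1.2.826.0.1.3680043.9.7484."

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

.pad_even <- function(r, pad = as.raw(0L)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

.dcm_element <- function(group, elem, vr, value_raw) {
  value_raw <- .pad_even(value_raw,
                         pad = if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" "))
  hdr <- c(.u16(group), .u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, raw(2L), .u32(length(value_raw)), value_raw)
  } else {
    if (length(value_raw) > 65534L) stop("value too long for short-form VR", call. = FALSE)
    c(hdr, .u16(length(value_raw)), value_raw)
  }
}

.el_str <- function(group, elem, vr, s) .dcm_element(group, elem, vr, charToRaw(s))
.el_us <- function(group, elem, x) .dcm_element(group, elem, "US", .u16(x))
.el_ds <- function(group, elem, x) {
  .el_str(group, elem, "DS", paste(sprintf("%.10g", x), collapse = "\\"))
}

# one single-frame CT file, explicit VR little endian
.dcm_write_file <- function(path, pixels, position, thickness, spacing,
                            series_uid, sop_uid, study_uid, instance_number,
                            slope = 1, intercept = -1024, spacing_between = NULL) {
  stored <- round((pixels - intercept) / slope)
  if (any(stored < -32768 | stored > 32767)) {
    stop("pixel values out of int16 range after rescale inversion", call. = FALSE)
  }
  # DICOM pixel data is row-major: emit row by row
  pix_raw <- writeBin(as.integer(t(stored)), raw(), size = 2L, endian = "little")
  meta <- c(
    .el_str(0x0002, 0x0002, "UI", .uid_ct_image),
    .el_str(0x0002, 0x0003, "UI", sop_uid),
    .el_str(0x0002, 0x0010, "UI", .ts_explicit_le)
  )
  meta <- c(.dcm_element(0x0002, 0x0000, "UL", .u32(length(meta))), meta)
  ds <- c(
    .el_str(0x0008, 0x0016, "UI", .uid_ct_image),
    .el_str(0x0008, 0x0018, "UI", sop_uid),
    .el_str(0x0008, 0x0060, "CS", "CT"),
    .el_ds(0x0018, 0x0050, thickness),
    if (!is.null(spacing_between)) .el_ds(0x0018, 0x0088, spacing_between),
    .el_str(0x0020, 0x000D, "UI", study_uid),
    .el_str(0x0020, 0x000E, "UI", series_uid),
    .el_str(0x0020, 0x0013, "IS", as.character(instance_number)),
    .el_ds(0x0020, 0x0032, c(0, 0, position)),
    .el_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
    .el_us(0x0028, 0x0002, 1L),
    .el_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .el_us(0x0028, 0x0010, nrow(pixels)),
    .el_us(0x0028, 0x0011, ncol(pixels)),
    .el_ds(0x0028, 0x0030, spacing),
    .el_us(0x0028, 0x0100, 16L),
    .el_us(0x0028, 0x0101, 16L),
    .el_us(0x0028, 0x0102, 15L),
    .el_us(0x0028, 0x0103, 1L),
    .el_ds(0x0028, 0x1052, intercept),
    .el_ds(0x0028, 0x1053, slope),
    .dcm_element(0x7FE0, 0x0010, "OW", pix_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# parse one explicit-VR little-endian file into a tag-keyed list
.dcm_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  }
  pos <- 133L
  n <- length(bytes)
  rd_u16 <- function(at) readBin(bytes[at:(at + 1L)], "integer", size = 2L,
                                 signed = FALSE, endian = "little")
  rd_u32 <- function(at) readBin(bytes[at:(at + 3L)], "integer", size = 4L,
                                 endian = "little")
  els <- list()
  while (pos + 7L <= n) {
    group <- rd_u16(pos); elem <- rd_u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("implicit-VR or corrupted element at byte ", pos, " in ", path,
           " (only explicit VR little endian is supported)", call. = FALSE)
    }
    if (vr %in% .long_vrs) {
      len <- rd_u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- rd_u16(pos + 6L); vstart <- pos + 8L
    }
    if (vr == "SQ" || len < 0L) {
      stop("unsupported element (sequence or undefined length) in ", path,
           call. = FALSE)
    }
    val <- if (len > 0L) bytes[vstart:(vstart + len - 1L)] else raw(0L)
    els[[sprintf("%04X,%04X", group, elem)]] <- list(vr = vr, value = val)
    pos <- vstart + len
  }
  ts <- .tag_str(els, "0002,0010")
  if (!is.null(ts) && ts != .ts_explicit_le) {
    stop("unsupported transfer syntax ", ts, " in ", path, call. = FALSE)
  }
  els
}

.tag_str <- function(els, key) {
  e <- els[[key]]
  if (is.null(e)) return(NULL)
  v <- e$value
  while (length(v) > 0L && v[length(v)] == as.raw(0L)) v <- v[-length(v)]
  sub(" +$", "", rawToChar(v))
}

.tag_num <- function(els, key) {
  s <- .tag_str(els, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1L]])
}

.tag_us <- function(els, key) {
  e <- els[[key]]
  if (is.null(e)) return(NULL)
  readBin(e$value, "integer", size = 2L, signed = FALSE, endian = "little")
}

#' Load an axial CT DICOM series as a volume
#'
#' Reads every file in `directory`, verifies that all belong to one series
#' with axial orientation, applies the HU rescale (slope, intercept), sorts
#' slices by the z-component of Image Position (Patient) and returns them
#' with their physical positions in mm. File order on disk is irrelevant:
#' geometry comes from the headers.
#'
#' @param directory Path containing the single-frame DICOM files of one series.
#' @return An [axial_volume()] in HU.
#' @export
load_dicom_series <- function(directory) {
  if (!dir.exists(directory)) stop("no such directory: ", directory, call. = FALSE)
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in ", directory, call. = FALSE)
  parsed <- lapply(files, .dcm_read_file)

  modality <- vapply(parsed, function(e) .tag_str(e, "0008,0060") %||% "", "")
  if (any(modality != "CT")) {
    stop("non-CT modality in series: ", paste(unique(modality), collapse = ", "),
         call. = FALSE)
  }
  uids <- vapply(parsed, function(e) .tag_str(e, "0020,000E") %||% "", "")
  if (length(unique(uids)) != 1L) {
    stop("mixed series UIDs in ", directory, ": ",
         paste(unique(uids), collapse = ", "), call. = FALSE)
  }
  zs <- vapply(parsed, function(e) {
    p <- .tag_num(e, "0020,0032")
    if (is.null(p) || length(p) != 3L) {
      stop("missing Image Position (Patient) tag", call. = FALSE)
    }
    p[3L]
  }, 0)
  for (e in parsed) {
    o <- .tag_num(e, "0020,0037")
    if (is.null(o) || length(o) != 6L) stop("missing orientation tag", call. = FALSE)
    if (max(abs(o - c(1, 0, 0, 0, 1, 0))) > 1e-3) {
      stop("non-axial orientation (cosines ", paste(format(o), collapse = " "),
           "); gantry-tilted or oblique series are not supported", call. = FALSE)
    }
  }
  ord <- order(zs)
  if (any(diff(zs[ord]) < 1e-3)) {
    i <- which(diff(zs[ord]) < 1e-3)[1L]
    stop(sprintf("duplicate z-position %.4f mm in files %s and %s",
                 zs[ord][i], basename(files[ord][i]), basename(files[ord][i + 1L])),
         call. = FALSE)
  }
  parsed <- parsed[ord]; zs <- zs[ord]

  first <- parsed[[1L]]
  rows <- .tag_us(first, "0028,0010"); cols <- .tag_us(first, "0028,0011")
  thickness <- .tag_num(first, "0018,0050")
  if (is.null(thickness)) stop("missing Slice Thickness tag", call. = FALSE)
  pix_spacing <- .tag_num(first, "0028,0030") %||% c(1, 1)

  vox <- array(0, dim = c(rows, cols, length(parsed)))
  for (k in seq_along(parsed)) {
    e <- parsed[[k]]
    if (.tag_us(e, "0028,0100") != 16L) stop("only 16-bit pixel data supported", call. = FALSE)
    signed <- (.tag_us(e, "0028,0103") %||% 0L) == 1L
    stored <- readBin(e[["7FE0,0010"]]$value, "integer", n = rows * cols,
                      size = 2L, signed = signed, endian = "little")
    slope <- .tag_num(e, "0028,1053") %||% 1
    intercept <- .tag_num(e, "0028,1052") %||% 0
    # stored row-major -> [row, col]
    vox[, , k] <- t(matrix(slope * stored + intercept, nrow = cols, ncol = rows))
  }
  axial_volume(vox, positions = zs, thickness = thickness, spacing = pix_spacing)
}

#' Load a NIfTI volume with stated slice thickness
#'
#' Positions are derived from the affine: origin plus k times the z spacing
#' along the slice (third) axis. NIfTI stores spacing, not slice thickness,
#' so the caller must state the thickness. A negative z step in the affine is
#' handled by flipping slices so positions come out ascending.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param thickness Slice thickness in mm (`> 0`); not stored by NIfTI.
#' @return An [axial_volume()].
#' @export
load_nifti <- function(path, thickness) {
  if (missing(thickness) || is.null(thickness)) {
    stop("`thickness` must be supplied: NIfTI stores slice spacing, not thickness",
         call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3D volume, got ", length(d), "D", call. = FALSE)
  }
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (max(abs(rot[row(rot) != col(rot)])) > 1e-6 * max(abs(diag(rot)))) {
    stop("non-orthogonal (oblique) affine not supported", call. = FALSE)
  }
  dz <- rot[3L, 3L]
  if (dz == 0) stop("degenerate affine: zero z spacing", call. = FALSE)
  z0 <- xf[3L, 4L]
  pos <- z0 + (seq_len(d[3L]) - 1L) * dz
  vox <- array(as.numeric(img), dim = d)
  if (dz < 0) {
    vox <- vox[, , rev(seq_len(d[3L])), drop = FALSE]
    pos <- rev(pos)
  }
  axial_volume(vox, positions = pos, thickness = thickness,
               spacing = abs(c(rot[1L, 1L], rot[2L, 2L])))
}

#' Save an axial volume to NIfTI or a DICOM-like file stack
#'
#' For `"nifti"`, slice positions must be uniformly spaced (they define the
#' affine z step) and a JSON sidecar (`<path>.json`) records thickness and
#' positions so the volume can be reloaded without re-stating the thickness.
#' For `"dicom_stack"`, one explicit-VR little-endian CT file is written per
#' slice into the directory `path`, with Slice Thickness carrying the
#' simulated thickness and Spacing Between Slices the slice interval.
#'
#' @param vol An [axial_volume()].
#' @param path Output file (`nifti`) or directory (`dicom_stack`).
#' @param format `"nifti"` or `"dicom_stack"`.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path, format = c("nifti", "dicom_stack")) {
  stopifnot(inherits(vol, "axial_volume"))
  format <- match.arg(format)
  n <- n_slices(vol)
  if (format == "nifti") {
    if (n > 1L) {
      dpos <- diff(vol$positions)
      if (max(dpos) - min(dpos) > 1e-6) {
        stop("NIfTI requires uniformly spaced slices; positions are irregular",
             call. = FALSE)
      }
      dz <- mean(dpos)
    } else dz <- vol$thickness
    affine <- diag(c(vol$spacing[1L], vol$spacing[2L], dz, 1))
    affine[3L, 4L] <- vol$positions[1L]
    img <- RNifti::asNifti(vol$voxels)
    img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
    RNifti::writeNifti(img, path, datatype = "float")
    jsonlite::write_json(
      list(thickness = vol$thickness, positions = vol$positions,
           spacing = vol$spacing),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    # deterministic UIDs so identical volumes produce identical bytes
    h <- sum(abs(vol$voxels)) + n * 7 + sum(vol$positions^2)
    tag <- sprintf("%.0f", (h %% 1e8) + 1)
    study_uid <- paste0(.uid_root, "1.", tag)
    series_uid <- paste0(.uid_root, "2.", tag)
    interval <- if (n > 1L) mean(diff(vol$positions)) else NULL
    for (k in seq_len(n)) {
      .dcm_write_file(
        file.path(path, sprintf("slice_%04d.dcm", k)),
        pixels = vol$voxels[, , k],
        position = vol$positions[k], thickness = vol$thickness,
        spacing = vol$spacing,
        series_uid = series_uid, study_uid = study_uid,
        sop_uid = paste0(.uid_root, "3.", tag, ".", k),
        instance_number = k, spacing_between = interval)
    }
  }
  invisible(path)
}

#' Load a volume from NIfTI (with sidecar) or a DICOM directory
#'
#' Dispatch on the path: a directory is read as a DICOM series; a `.nii` /
#' `.nii.gz` file is read with the thickness taken from the argument or, if
#' absent, from the JSON sidecar written by [save_volume()].
#'
#' @param path Volume file or DICOM directory.
#' @param thickness Slice thickness in mm; optional when a sidecar exists.
#' @return An [axial_volume()].
#' @export
load_volume <- function(path, thickness = NULL) {
  if (dir.exists(path)) return(load_dicom_series(path))
  if (is.null(thickness)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      thickness <- jsonlite::read_json(sidecar)$thickness
    } else {
      stop("`thickness` not given and no sidecar found at ", sidecar, call. = FALSE)
    }
  }
  load_nifti(path, thickness)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
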