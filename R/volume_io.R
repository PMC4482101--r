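#' CT volume container
#'
#' A `ct_volume` holds a 3D scalar grid of Hounsfield units together with its
#' voxel spacing, physical origin, and acquisition metadata. Axis convention:
#' `i` runs right-to-left, `j` anterior-to-posterior, `k` superior-to-inferior
#' (slice `k + 1` is closer to the feet than slice `k`). Voxel indices are
#' 1-based. Physical coordinates are reported in the DICOM LPS frame; because
#' `k` increases towards the feet while LPS `z` points towards the head, the
#' physical position of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 1) * spacing * c(1, 1, -1)`.
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing numeric length-3, mm per voxel along `(i, j, k)`; all
#'   components must be strictly positive.
#' @param origin numeric length-3, LPS coordinates (mm) of voxel `(1, 1, 1)`.
#' @param kernel_name reconstruction-kernel label (e.g. `"B30f"`, `"LUNG"`);
#'   empty string when unknown.
#' @param source one of `"dicom"`, `"nrrd"`, `"nifti"`, `"synthetic"`.
#' @return An object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `origin` and `meta` (`kernel_name`, `slice_count`, `source`).
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      kernel_name = "", source = "synthetic") {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers", call. = FALSE)
  rng <- range(voxels, finite = TRUE)
  if (rng[1] < -3024 || rng[2] > 3071)
    stop("HU values outside [-3024, 3071]", call. = FALSE)
  source <- match.arg(source, c("dicom", "nrrd", "nifti", "synthetic"))
  structure(list(
    voxels = voxels,
    spacing = spacing,
    origin = as.numeric(origin),
    meta = list(kernel_name = as.character(kernel_name)[1],
                slice_count = dim(voxels)[3],
                source = source)
  ), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%g, %g], kernel '%s', source %s\n",
              min(x$voxels), max(x$voxels),
              x$meta$kernel_name, x$meta$source))
  invisible(x)
}

ct_dim <- function(ct) dim(ct$voxels)

stopifnot_ct <- function(ct) {
  if (!inherits(ct, "ct_volume")) stop("expected a ct_volume", call. = FALSE)
}

#' Convert between voxel indices and physical LPS coordinates
#'
#' The mapping is affine and self-inverse up to voxel rounding:
#' `physical_to_ijk(ct, ijk_to_physical(ct, ijk))` returns `ijk` for any
#' in-bounds index.
#'
#' @param ct a [ct_volume].
#' @param ijk integer vector of length 3 (or matrix with 3 columns), 1-based.
#' @param xyz numeric vector of length 3 (or matrix with 3 columns), LPS mm.
#' @return `ijk_to_physical` returns LPS coordinates; `physical_to_ijk`
#'   returns the nearest 1-based voxel index.
#' @export
ijk_to_physical <- function(ct, ijk) {
  stopifnot_ct(ct)
  ijk <- rbind(ijk)
  sw <- ct$spacing * c(1, 1, -1)
  out <- sweep(sweep(ijk - 1, 2, sw, "*"), 2, ct$origin, "+")
  if (nrow(out) == 1L) as.numeric(out) else out
}

#' @rdname ijk_to_physical
#' @export
physical_to_ijk <- function(ct, xyz) {
  stopifnot_ct(ct)
  xyz <- rbind(xyz)
  sw <- ct$spacing * c(1, 1, -1)
  out <- round(sweep(sweep(xyz, 2, ct$origin, "-"), 2, sw, "/")) + 1
  storage.mode(out) <- "integer"
  if (nrow(out) == 1L) out[1, ] else out
}

in_bounds <- function(ct, ijk) {
  d <- ct_dim(ct)
  all(ijk >= 1L) && all(ijk <= d)
}

# ---------------------------------------------------------------------------
# NRRD (hand-written: no installed R package reads NRRD)

nrrd_type <- function(storage) {
  switch(storage,
         "short" = , "int16" = , "signed short" = list(size = 2L, what = "integer", signed = TRUE),
         "ushort" = , "uint16" = , "unsigned short" = list(size = 2L, what = "integer", signed = FALSE),
         "int" = , "int32" = , "signed int" = list(size = 4L, what = "integer", signed = TRUE),
         "uchar" = , "uint8" = , "unsigned char" = list(size = 1L, what = "integer", signed = FALSE),
         "float" = list(size = 4L, what = "double", signed = TRUE),
         "double" = list(size = 8L, what = "double", signed = TRUE),
         stop("unsupported NRRD type: ", storage, call. = FALSE))
}

parse_nrrd_vectors <- function(txt) {
  # "(a,b,c) (d,e,f) (g,h,i)" -> 3x3 matrix (rows = vectors)
  m <- regmatches(txt, gregexpr("\\(([^)]*)\\)", txt))[[1]]
  vs <- lapply(m, function(s) as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]))
  do.call(rbind, vs)
}

read_nrrd <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line
  nl <- which(raw == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { hdr_end <- p; break }
    # tolerate \r\n
    if (p == prev + 2L && raw[p - 1L] == as.raw(13L)) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end)) stop("malformed NRRD: no header terminator", call. = FALSE)
  hdr <- strsplit(rawToChar(raw[seq_len(hdr_end)]), "\r?\n")[[1]]
  if (!grepl("^NRRD", hdr[1])) stop("not an NRRD file: ", path, call. = FALSE)
  hdr <- hdr[-1]
  hdr <- hdr[!grepl("^#", hdr) & nzchar(hdr)]
  kv <- strsplit(hdr, ":\\s*")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), "")
  field <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported", call. = FALSE)
  ty <- nrrd_type(field("type"))
  enc <- tolower(field("encoding", "raw"))
  endian <- tolower(field("endian", "little"))
  if (endian == "big") stop("big-endian NRRD not supported", call. = FALSE)
  payload <- raw[(hdr_end + 1L):length(raw)]
  if (enc %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (enc != "raw") stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  n <- prod(sizes)
  vox <- readBin(payload, ty$what, n = n, size = ty$size,
                 signed = ty$signed, endian = "little")
  arr <- array(as.numeric(vox), dim = sizes)
  sd_txt <- field("space directions")
  spacing <- c(1, 1, 1); zdir <- -1; origin <- c(0, 0, 0)
  if (!is.null(sd_txt)) {
    M <- parse_nrrd_vectors(sd_txt)
    offd <- M; diag(offd) <- 0
    if (any(abs(offd) > 1e-6))
      stop("oblique NRRD orientations are not supported", call. = FALSE)
    if (diag(M)[1] <= 0 || diag(M)[2] <= 0)
      stop("unsupported NRRD axis orientation (negative i/j direction)", call. = FALSE)
    spacing <- abs(diag(M)); zdir <- sign(diag(M)[3])
  }
  so_txt <- field("space origin")
  if (!is.null(so_txt)) origin <- as.numeric(parse_nrrd_vectors(so_txt)[1, ])
  if (zdir > 0) {
    # k was increasing superiorly; flip so k increases towards the feet
    arr <- arr[, , rev(seq_len(sizes[3])), drop = FALSE]
    origin[3] <- origin[3] + (sizes[3] - 1) * spacing[3]
  }
  ct_volume(arr, spacing, origin, kernel_name = "", source = "nrrd")
}

write_nrrd <- function(arr, spacing, origin, path, type = "double") {
  ty <- nrrd_type(type)
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", type),
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", dim(arr)[1], dim(arr)[2], dim(arr)[3]),
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
            spacing[1], spacing[2], -spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: gzip",
    sprintf("space origin: (%.10g,%.10g,%.10g)", origin[1], origin[2], origin[3]),
    ""
  )
  vals <- if (ty$what == "integer") as.integer(round(arr)) else as.numeric(arr)
  payload <- memCompress(writeBin(vals, raw(), size = ty$size, endian = "little"),
                         type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(payload, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# NIfTI via RNifti (RAS headers converted to the internal LPS convention)

read_nifti_ct <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L)
    stop("only 3D NIfTI volumes are supported", call. = FALSE)
  arr <- array(as.vector(arr), dim = dim(arr))     # strip RNifti attributes
  A <- RNifti::xform(img)                       # voxel (0-based) -> RAS mm
  M <- diag(c(-1, -1, 1)) %*% A[1:3, , drop = FALSE]  # -> LPS
  R3 <- M[, 1:3]
  offd <- R3; diag(offd) <- 0
  if (any(abs(offd) > 1e-4))
    stop("oblique NIfTI orientations are not supported", call. = FALSE)
  if (diag(R3)[1] <= 0 || diag(R3)[2] <= 0)
    stop("unsupported NIfTI axis orientation (negative i/j direction)", call. = FALSE)
  spacing <- abs(diag(R3))
  origin <- M[, 4]
  if (diag(R3)[3] > 0) {
    nk <- dim(arr)[3]
    arr <- arr[, , rev(seq_len(nk)), drop = FALSE]
    origin[3] <- origin[3] + (nk - 1) * spacing[3]
  }
  ct_volume(arr, spacing, origin, kernel_name = "", source = "nifti")
}

write_nifti_vol <- function(arr, spacing, origin, path) {
  # internal LPS origin/spacing back to a RAS affine
  A <- diag(4)
  A[1, 1] <- -spacing[1]; A[2, 2] <- -spacing[2]; A[3, 3] <- -spacing[3]
  A[1:3, 4] <- c(-origin[1], -origin[2], origin[3])
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, spacing)          # before the xforms
  img <- RNifti::`sform<-`(img, structure(A, code = 2L))
  img <- RNifti::`qform<-`(img, structure(A, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Read a CT volume
#'
#' Reads an NRRD (`.nrrd`) or NIfTI (`.nii`, `.nii.gz`) volume into a
#' [ct_volume]. Geometry (spacing, origin) is taken from the file header;
#' axial ordering is normalized so that `k` always increases towards the
#' feet. DICOM series input is not supported by this build and raises an
#' error.
#'
#' @param path path to an NRRD or NIfTI file.
#' @return A [ct_volume].
#' @export
read_ct <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path)
    if (length(files) == 0L)
      stop("no DICOM files found in directory: ", path, call. = FALSE)
    stop("DICOM series reading is not supported; convert to NRRD or NIfTI",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lw <- tolower(path)
  if (grepl("\\.nrrd$", lw)) return(read_nrrd(path))
  if (grepl("\\.nii(\\.gz)?$", lw)) return(read_nifti_ct(path))
  stop("unrecognized volume format (expected .nrrd, .nii or .nii.gz): ",
       path, call. = FALSE)
}

#' Write a CT volume
#'
#' @param ct a [ct_volume].
#' @param path output path; format chosen by extension (`.nrrd`, `.nii`,
#'   `.nii.gz`).
#' @export
write_ct <- function(ct, path) {
  stopifnot_ct(ct)
  lw <- tolower(path)
  if (grepl("\\.nrrd$", lw)) {
    type <- if (all(ct$voxels == round(ct$voxels))) "short" else "double"
    write_nrrd(ct$voxels, ct$spacing, ct$origin, path, type = type)
  } else if (grepl("\\.nii(\\.gz)?$", lw)) {
    write_nifti_vol(ct$voxels, ct$spacing, ct$origin, path)
  } else stop("unrecognized output format: ", path, call. = FALSE)
  invisible(path)
}

#' Write a binary label map
#'
#' @param label logical 3D array on the same grid as `ref`.
#' @param ref the reference [ct_volume] supplying the geometry.
#' @param path output path (`.nrrd`, `.nii`, `.nii.gz`); voxel values are 0/1.
#' @export
write_label <- function(label, ref, path) {
  stopifnot_ct(ref)
  if (!identical(dim(label), ct_dim(ref)))
    stop("label grid does not match the reference volume", call. = FALSE)
  arr <- array(as.integer(label), dim = dim(label))
  lw <- tolower(path)
  if (grepl("\\.nrrd$", lw)) {
    write_nrrd(arr, ref$spacing, ref$origin, path, type = "uchar")
  } else if (grepl("\\.nii(\\.gz)?$", lw)) {
    write_nifti_vol(arr, ref$spacing, ref$origin, path)
  } else stop("unrecognized output format: ", path, call. = FALSE)
  invisible(path)
}

#' Read a label map
#'
#' @param path label file written by [write_label()] (or any 0/1 volume).
#' @return logical 3D array.
#' @export
read_label <- function(path) {
  ct <- read_ct(path)
  array(ct$voxels != 0, dim = dim(ct$voxels))
}

# ---------------------------------------------------------------------------
# Seed points

#' Read seed points from a fiducial or JSON file
#'
#' Supports 3D Slicer `.fcsv` fiducial files (RAS or LPS, per the
#' `CoordinateSystem` header line; RAS coordinates are converted to LPS) and
#' JSON files containing either a list of `{"x":, "y":, "z":}` objects or a
#' list of `[x, y, z]` triples. Malformed rows are skipped with a warning.
#'
#' @param path path to a `.fcsv` or `.json` file.
#' @return data.frame with columns `x`, `y`, `z` (LPS mm) and `label`.
#' @export
read_seeds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.fcsv$", tolower(path))) {
    lines <- readLines(path, warn = FALSE)
    cs <- grep("CoordinateSystem", lines, value = TRUE)
    ras <- TRUE                                  # Slicer default is RAS (0)
    if (length(cs)) {
      v <- trimws(sub(".*=", "", cs[1]))
      ras <- v %in% c("RAS", "0")
    }
    rows <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    pts <- list()
    for (r in rows) {
      f <- strsplit(r, ",")[[1]]
      xyz <- suppressWarnings(as.numeric(f[2:4]))
      if (length(f) < 4L || any(is.na(xyz))) {
        warning("skipping malformed fiducial row: ", r, call. = FALSE)
        next
      }
      if (ras) xyz[1:2] <- -xyz[1:2]
      lab <- if (length(f) >= 12L) f[12] else ""
      pts[[length(pts) + 1L]] <- data.frame(x = xyz[1], y = xyz[2], z = xyz[3],
                                            label = lab)
    }
    if (!length(pts)) stop("no parsable seed points in ", path, call. = FALSE)
    out <- do.call(rbind, pts)
    rownames(out) <- NULL
    return(out)
  }
  if (grepl("\\.json$", tolower(path))) {
    j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    pts <- list()
    for (e in j) {
      xyz <- if (is.list(e) && all(c("x", "y", "z") %in% names(e)))
        c(e$x, e$y, e$z)
      else if (is.numeric(unlist(e)) && length(unlist(e)) >= 3L)
        unlist(e)[1:3]
      else NULL
      if (is.null(xyz) || any(!is.finite(as.numeric(xyz)))) {
        warning("skipping malformed seed entry", call. = FALSE)
        next
      }
      pts[[length(pts) + 1L]] <- data.frame(x = xyz[1], y = xyz[2],
                                            z = xyz[3], label = "")
    }
    if (!length(pts)) stop("no parsable seed points in ", path, call. = FALSE)
    out <- do.call(rbind, pts)
    rownames(out) <- NULL
    return(out)
  }
  stop("unrecognized seed file format (expected .fcsv or .json): ", path,
       call. = FALSE)
}

#' Resolve a seed to a voxel index
#'
#' Accepts a 1-based voxel index triple, a physical LPS triple, or a
#' data.frame row from [read_seeds()], and returns the in-bounds 1-based
#' voxel index.
#'
#' @param ct a [ct_volume].
#' @param seed integer ijk triple, numeric LPS triple (`physical = TRUE`), or
#'   one-row data.frame with `x`, `y`, `z`.
#' @param physical interpret a bare numeric triple as LPS mm.
#' @export
resolve_seed <- function(ct, seed, physical = FALSE) {
  stopifnot_ct(ct)
  if (is.data.frame(seed)) {
    ijk <- physical_to_ijk(ct, as.numeric(seed[1, c("x", "y", "z")]))
  } else if (physical) {
    ijk <- physical_to_ijk(ct, as.numeric(seed))
  } else {
    ijk <- as.integer(round(seed))
  }
  if (length(ijk) != 3L || !in_bounds(ct, ijk))
    stop("seed point outside the volume", call. = FALSE)
  ijk
}
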