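#' Write a volume as MetaImage MHD/RAW
#'
#' Writes a plain-text `.mhd` header and a little-endian raw data file
#' next to it.  Data are written in column-major order, matching the
#' MetaImage fastest-axis-first `DimSize` convention.
#'
#' @param vol a [volume_grid()].
#' @param path output path ending in `.mhd`.
#' @param element_type `"float"` (32-bit, default) or `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, element_type = c("float", "double")) {
  stopifnot(inherits(vol, "volume_grid"))
  element_type <- match.arg(element_type)
  write_mhd(vol$values, vol$geometry$spacing, vol$geometry$origin,
            path, element_type)
}

#' Read a MetaImage MHD/RAW volume
#'
#' @param path path to a `.mhd` header; the raw file named by
#'   `ElementDataFile` is read from the same directory.
#' @return a [volume_grid()] (double precision in memory) whose geometry
#'   spacing/origin come from `ElementSpacing` / `Offset`.
#' @export
read_volume <- function(path) {
  m <- read_mhd(path)
  volume_grid(m$values, volume_geometry(m$dims, m$spacing, m$origin))
}

#' Write a projection stack as MHD/RAW
#'
#' Views are stored as slices: the file has dimensions
#' `(detector..., n_views)` so each slice is one projection image/row.
#' The scan geometry itself travels in the sidecar YAML config
#' ([write_geometry_config()]).
#'
#' @param stack a [projection_stack()].
#' @param path output `.mhd` path.
#' @param element_type `"float"` or `"double"`.
#' @return `path`, invisibly.
#' @export
write_projection_stack <- function(stack, path,
                                   element_type = c("float", "double")) {
  stopifnot(inherits(stack, "projection_stack"))
  element_type <- match.arg(element_type)
  vals <- stack$values
  nd <- length(dim(vals))
  perm <- c(seq_len(nd)[-1], 1L)               # views last
  arr <- aperm(vals, perm)
  det <- stack$geometry$detector
  write_mhd(arr, c(det$spacing, delta_beta(stack$geometry)),
            c(det$offset - (det$shape - 1) / 2 * det$spacing,
              stack$geometry$start_angle),
            path, element_type)
}

#' Read a projection stack from MHD/RAW
#'
#' @param path `.mhd` path written by [write_projection_stack()].
#' @param geom the [scan_geometry()] the stack belongs to (the header
#'   stores only sampling metadata).
#' @return a [projection_stack()].
#' @export
read_projection_stack <- function(path, geom) {
  m <- read_mhd(path)
  nd <- length(m$dims)
  arr <- array(m$values, m$dims)
  projection_stack(aperm(arr, c(nd, seq_len(nd - 1L))), geom)
}

#' Export projections as multi-page TIFF
#'
#' Convenience export (one page per view) via the `tiff` package.  TIFF
#' stores samples in `[0, 1]`, so values are scaled by `1 / scale` with
#' `scale = max(|values|)` before writing; the scale factor is returned so
#' the line integrals can be recovered.
#'
#' @param stack a [projection_stack()].
#' @param path output `.tif` path.
#' @return the applied `scale` (multiply pixels by it to recover
#'   value*mm), invisibly.
#' @export
write_projection_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  vals <- stack$values
  scale <- max(abs(vals), 1e-300)
  pages <- lapply(seq_len(dim(vals)[1]), function(v) {
    pg <- if (length(dim(vals)) == 2) matrix(vals[v, ], nrow = 1)
          else t(vals[v, , ])
    pmax(pg / scale, 0)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(scale)
}

# ---- MHD primitives ----------------------------------------------------

write_mhd <- function(values, spacing, offset, path, element_type = "float") {
  if (!grepl("\\.mhd$", path)) stop("path must end in .mhd")
  dims <- dim(values) %||% length(values)
  rawname <- sub("\\.mhd$", ".raw", basename(path))
  met <- if (element_type == "float") "MET_FLOAT" else "MET_DOUBLE"
  hdr <- c(
    "ObjectType = Image",
    sprintf("NDims = %d", length(dims)),
    sprintf("DimSize = %s", paste(dims, collapse = " ")),
    sprintf("ElementSpacing = %s",
            paste(sprintf("%.17g", spacing), collapse = " ")),
    sprintf("Offset = %s",
            paste(sprintf("%.17g", offset), collapse = " ")),
    "ByteOrderMSB = False",
    sprintf("ElementType = %s", met),
    sprintf("ElementDataFile = %s", rawname))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  writeBin(as.numeric(values), con,
           size = if (element_type == "float") 4L else 8L,
           endian = "little")
  invisible(path)
}

read_mhd <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  need <- function(key) {
    if (is.null(kv[[key]]))
      stop(sprintf("MHD header missing required field '%s'", key))
    kv[[key]]
  }
  ndims <- as.integer(need("NDims"))
  dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  if (length(dims) != ndims)
    stop("MHD header field 'DimSize' does not match 'NDims'")
  spacing <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]]) else rep(1, ndims)
  offset <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else rep(0, ndims)
  et <- need("ElementType")
  size <- switch(et, MET_FLOAT = 4L, MET_DOUBLE = 8L,
                 stop(sprintf("unsupported ElementType '%s'", et)))
  if (!is.null(kv$ByteOrderMSB) && toupper(kv$ByteOrderMSB) == "TRUE")
    stop("big-endian MHD data are not supported")
  rawpath <- file.path(dirname(path), need("ElementDataFile"))
  if (!file.exists(rawpath))
    stop(sprintf("ElementDataFile '%s' not found", rawpath))
  n <- prod(dims)
  con <- file(rawpath, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n + 1, size = size, endian = "little")
  if (length(vals) != n)
    stop(sprintf(
      "raw data size does not match DimSize: expected %d values, found %d",
      n, length(vals)))
  list(values = array(vals, dims), dims = dims, spacing = spacing,
       origin = offset)
}

# ---- projection matrices ----------------------------------------------

#' Write projection matrices as plain text
#'
#' One matrix per view: three rows of four whitespace-separated floats
#' (17 significant digits), views separated by blank lines.
#'
#' @param matrices list of 3x4 matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_projection_matrices <- function(matrices, path) {
  blocks <- vapply(matrices, function(P) {
    stopifnot(is.matrix(P), all(dim(P) == c(3, 4)))
    paste(apply(P, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")),
      collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Read projection matrices from plain text
#'
#' @param path file written in the format of
#'   [write_projection_matrices()].
#' @return list of 3x4 numeric matrices.
#' @export
read_projection_matrices <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  out <- list()
  rows <- list()
  flush_block <- function() {
    if (length(rows) == 0) return()
    if (length(rows) != 3)
      stop(sprintf("projection matrix block ending near line %d has %d rows, expected 3",
                   i, length(rows)))
    out[[length(out) + 1]] <<- do.call(rbind, rows)
    rows <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { flush_block(); next }
    vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
    if (length(vals) != 4 || anyNA(vals))
      stop(sprintf("line %d: expected 4 numeric entries", i))
    rows[[length(rows) + 1]] <- vals
  }
  flush_block()
  if (length(out) == 0) stop("no projection matrices found")
  out
}

# ---- geometry config ---------------------------------------------------

#' Write a scan geometry as a YAML config
#'
#' Keys: `beam`, `volume_shape`, `volume_spacing`, `detector_shape`,
#' `detector_spacing`, `detector_offset`, `n_views`, `angular_range_deg`,
#' `start_angle_deg`, and for divergent beams `sid_mm`, `sdd_mm`.  Angles
#' are stored in degrees (explicit `_deg` keys); internally the package
#' uses radians.
#'
#' @param geom a [scan_geometry()].
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_geometry_config <- function(geom, path) {
  stopifnot(inherits(geom, "scan_geometry"))
  cfg <- list(beam = geom$beam,
              volume_shape = as.integer(geom$volume$shape),
              volume_spacing = geom$volume$spacing,
              detector_shape = as.integer(geom$detector$shape),
              detector_spacing = geom$detector$spacing,
              detector_offset = geom$detector$offset,
              n_views = geom$n_views,
              angular_range_deg = geom$angular_range * 180 / pi,
              start_angle_deg = geom$start_angle * 180 / pi)
  if (!is.null(geom$sid)) { cfg$sid_mm <- geom$sid; cfg$sdd_mm <- geom$sdd }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a scan geometry from a YAML config
#'
#' @param path config written by [write_geometry_config()] (or by hand
#'   with the same keys).
#' @param matrices optional path to a projection-matrix file for cone
#'   geometries; when omitted, circular-orbit matrices are generated.
#' @return a [scan_geometry()].
#' @export
read_geometry_config <- function(path, matrices = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  cfg <- yaml::read_yaml(path)
  for (key in c("beam", "volume_shape", "detector_shape", "n_views",
                "angular_range_deg"))
    if (is.null(cfg[[key]]))
      stop(sprintf("geometry config missing required key '%s'", key))
  vol <- volume_geometry(cfg$volume_shape, cfg$volume_spacing %||% 1)
  det <- detector_geometry(cfg$detector_shape, cfg$detector_spacing %||% 1,
                           cfg$detector_offset %||% 0)
  mats <- if (!is.null(matrices)) read_projection_matrices(matrices)
  scan_geometry(cfg$beam, vol, det, cfg$n_views,
                angular_range = cfg$angular_range_deg * pi / 180,
                start_angle = (cfg$start_angle_deg %||% 0) * pi / 180,
                sid = cfg$sid_mm, sdd = cfg$sdd_mm, matrices = mats)
}

#' Save a learned frequency filter as plain text
#'
#' Two whitespace-separated columns: frequency index and weight, preceded
#' by comment lines recording the pad length and detector spacing.
#'
#' @param filt a [frequency_filter()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frequency_filter <- function(filt, path) {
  stopifnot(inherits(filt, "frequency_filter"))
  hdr <- c(sprintf("# pad_length %d", filt$pad_length),
           sprintf("# detector_spacing %.17g", filt$detector_spacing))
  body <- sprintf("%d %.17g", seq_along(filt$weights) - 1L, filt$weights)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a frequency filter saved by [write_frequency_filter()]
#' @param path input path.
#' @return a [frequency_filter()].
#' @export
read_frequency_filter <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  pad <- as.integer(sub("^# pad_length\\s+", "",
                        meta[grepl("pad_length", meta)][1]))
  tau <- as.numeric(sub("^# detector_spacing\\s+", "",
                        meta[grepl("detector_spacing", meta)][1]))
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  w <- vapply(strsplit(body, "\\s+"), function(p) as.numeric(p[2]), numeric(1))
  frequency_filter(w, pad, if (is.na(tau)) 1 else tau)
}
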