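# Reading and writing label volumes, geometry models and measurement tables.
#
# Two on-disk volume formats are supported: multi-page TIFF with a JSON
# sidecar (voxel size + label table; TIFF itself carries neither) and MRC
# (voxel size taken from the header; the label table still needs the
# sidecar). Voxel size is never silently defaulted.

#' Write a label volume to disk
#'
#' @param lv A [label_volume()].
#' @param path Output path; format chosen by extension (`.tif`/`.tiff` or
#'   `.mrc`).
#' @param sidecar Path for the JSON sidecar. Defaults to `<path>.json`.
#'   The sidecar records the voxel size (nm) and the label table.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(lv, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(lv, "label_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    mx <- max(lv$voxels)
    if (mx > 65535L) abort("TIFF label export supports labels up to 65535.")
    pages <- lapply(seq_len(dim(lv$voxels)[1L]), function(z) {
      lv$voxels[z, , ] / 65535
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  } else if (ext == "mrc") {
    write_mrc(lv$voxels, lv$voxel_size, path)
  } else {
    abort(paste0("Unknown volume format: .", ext, " (use .tif/.tiff or .mrc)"))
  }
  side <- list(
    voxel_size_nm = as.list(lv$voxel_size),
    label_table = lv$label_table
  )
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a label volume from disk
#'
#' TIFF stacks must be accompanied by a JSON sidecar giving the voxel size;
#' a missing voxel size is an error, never a silent default. For MRC the
#' voxel size is read from the file header; the sidecar supplies the label
#' table (and may omit `voxel_size_nm`).
#'
#' @param path Volume path (`.tif`/`.tiff` or `.mrc`).
#' @param sidecar JSON sidecar path. Defaults to `<path>.json`.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, sidecar = paste0(path, ".json")) {
  ext <- tolower(tools::file_ext(path))
  side <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    NULL
  }
  if (is.null(side) || is.null(side$label_table)) {
    abort(paste0(
      "Sidecar with a label table is required to interpret '", path,
      "' (looked for '", sidecar, "')."
    ))
  }
  if (ext %in% c("tif", "tiff")) {
    if (is.null(side$voxel_size_nm)) {
      abort("TIFF carries no voxel size: the JSON sidecar must provide `voxel_size_nm`.")
    }
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- c(length(pages), dim(pages[[1L]]))
    vox <- array(0L, dim = d)
    for (z in seq_along(pages)) vox[z, , ] <- as.integer(pages[[z]])
    voxel_size <- unlist(side$voxel_size_nm)
  } else if (ext == "mrc") {
    m <- read_mrc(path)
    vox <- m$voxels
    voxel_size <- m$voxel_size
    if (!is.null(side$voxel_size_nm)) {
      sv <- unlist(side$voxel_size_nm)[c("x", "y", "z")]
      if (max(abs(sv - voxel_size[c("x", "y", "z")])) > 1e-3) {
        abort("Sidecar voxel size disagrees with the MRC header.")
      }
    }
  } else {
    abort(paste0("Unknown volume format: .", ext))
  }
  label_volume(vox, voxel_size, as_tibble(side$label_table))
}

# ---- minimal MRC2014 support (modes 0, 1, 2) --------------------------------
# No R MRC package is available, and the format is a fixed 1024-byte header
# followed by raw voxel data (x fastest, then y, then z). Voxel size in nm is
# cella (Angstrom would be conventional for EM maps, but label volumes here
# store nm directly) divided by mx/my/mz; we write cella in nm and document it.

write_mrc <- function(vox, voxel_size, path) {
  d <- dim(vox) # (z, y, x)
  nx <- d[3L]; ny <- d[2L]; nz <- d[1L]
  mx_val <- max(vox)
  mode <- if (mx_val <= 32767L) 1L else 2L
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(nx, ny, nz, mode))
  wi(c(0L, 0L, 0L))           # nxstart/nystart/nzstart
  wi(c(nx, ny, nz))           # mx, my, mz
  wf(c(nx * voxel_size[["x"]], ny * voxel_size[["y"]], nz * voxel_size[["z"]])) # cella (nm)
  wf(c(90, 90, 90))           # cellb
  wi(c(1L, 2L, 3L))           # mapc, mapr, maps
  wf(c(min(vox), max(vox), mean(vox))) # dmin, dmax, dmean
  wi(c(1L, 0L))               # ispg, nsymbt
  writeBin(raw(100L), con)    # extra
  wf(c(0, 0, 0))              # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian machine stamp
  wf(stats::sd(as.numeric(vox))) # rms
  wi(0L)                      # nlabl
  writeBin(raw(800L), con)    # labels
  dat <- as.vector(aperm(vox, c(3L, 2L, 1L))) # x fastest
  if (mode == 1L) {
    writeBin(as.integer(dat), con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(dat), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")
  h1 <- ri(4L) # nx ny nz mode
  ri(3L)       # nstart
  m <- ri(3L)  # mx my mz
  cella <- rf(3L)
  rf(3L)       # cellb
  ri(3L)       # mapc/mapr/maps
  rf(3L)       # dmin dmax dmean
  ri(2L)       # ispg nsymbt
  seek(con, 1024L)
  nx <- h1[1L]; ny <- h1[2L]; nz <- h1[3L]; mode <- h1[4L]
  n <- nx * ny * nz
  dat <- switch(as.character(mode),
    "0" = as.integer(readBin(con, "integer", n = n, size = 1L, signed = FALSE)),
    "1" = readBin(con, "integer", n = n, size = 2L, endian = "little"),
    "2" = as.integer(round(readBin(con, "numeric", n = n, size = 4L, endian = "little"))),
    abort(paste0("Unsupported MRC mode ", mode))
  )
  vox <- aperm(array(dat, dim = c(nx, ny, nz)), c(3L, 2L, 1L))
  voxel_size <- c(x = cella[1L] / m[1L], y = cella[2L] / m[2L], z = cella[3L] / m[3L])
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    abort("MRC header carries no usable voxel size (cella/mx..mz).")
  }
  list(voxels = vox, voxel_size = voxel_size)
}

# ---- geometry models --------------------------------------------------------

#' Read / write geometry models (spheres, polylines, tubes) as JSON
#'
#' Geometry models are the interchange format for reconstructed objects:
#' a list of objects, each with `kind` (`sphere`, `polyline` or `tube`),
#' `id`, nm coordinates, and a radius where applicable (tube radius
#' defaults to 50 nm, the half-gap between consecutive sections).
#'
#' @param objects A tibble with columns `kind`, `id`, `coords` (list of
#'   matrices with columns x, y, z in nm) and `radius_nm`.
#' @param path JSON path.
#' @return `read_geometry()` returns the tibble; `write_geometry()` returns
#'   `path` invisibly.
#' @export
write_geometry <- function(objects, path) {
  stopifnot(all(c("kind", "id", "coords") %in% names(objects)))
  if (!"radius_nm" %in% names(objects)) objects$radius_nm <- NA_real_
  objects$radius_nm[objects$kind == "tube" & is.na(objects$radius_nm)] <- 50
  payload <- purrr::pmap(
    list(objects$kind, objects$id, objects$coords, objects$radius_nm),
    function(kind, id, coords, radius_nm) {
      out <- list(
        kind = kind, id = id,
        coords_nm = unname(as.matrix(coords))
      )
      if (!is.na(radius_nm)) out$radius_nm <- radius_nm
      out
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  tibble(
    kind = map_chr(raw, "kind"),
    id = map_int(raw, ~ as.integer(.x$id)),
    coords = map(raw, function(o) {
      m <- do.call(rbind, lapply(o$coords_nm, unlist))
      colnames(m) <- c("x", "y", "z")
      m
    }),
    radius_nm = map_dbl(raw, function(o) {
      r <- o[["radius_nm"]]
      if (is.null(r) || !length(r)) NA_real_ else as.numeric(r)
    })
  )
}

# ---- measurement tables -----------------------------------------------------

# unit suffixes accepted on numeric measurement columns
UNIT_SUFFIX_RE <- paste0(
  "(_nm|_um|_nm2|_um2|_nm3|_um3|_frac|_pct|_count|_n|_se|_sd|_p|_stat|_df|",
  "_per_um2|_deg|_id|_index)$"
)

#' Write a measurement table as CSV with unit-annotated columns
#'
#' Every numeric column must carry a unit suffix in its name (`_nm`, `_um2`,
#' `_frac`, `_count`, ...); a unit-less numeric column is refused, so no
#' number leaves the package without units. Rows are sorted (by `cell_id`
#' then `object_id` where present, otherwise by all columns), making
#' re-export of the same records byte-identical.
#'
#' @param records A data frame of measurements.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  records <- as_tibble(records)
  num <- names(records)[vapply(records, is.numeric, logical(1))]
  bad <- num[!grepl(UNIT_SUFFIX_RE, num)]
  if (length(bad)) {
    abort(paste0(
      "Numeric measurement column(s) without a unit suffix: ",
      paste(bad, collapse = ", "),
      ". Rename with a unit suffix such as _nm, _um2, _frac, _count."
    ))
  }
  keys <- intersect(c("cell_id", "object_id"), names(records))
  if (length(keys) == 0L) keys <- names(records)
  if (nrow(records) > 0L && length(keys) > 0L) {
    records <- arrange(records, across(dplyr::all_of(keys)))
  }
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}
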