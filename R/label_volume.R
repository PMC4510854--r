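#' Segmented 3D label volume with physical voxel size
#'
#' `label_volume()` is the universal input container of the package: a 3D
#' integer array of segmentation labels indexed `[z, y, x]` (z is the
#' sectioning axis), a strictly positive per-axis voxel size in nanometres,
#' and a label table mapping every non-zero label to a semantic class
#' (`cell`, `nucleus`, `membrane`, `mitochondrion`, `ribbon`, `terminal`,
#' `vesicle`, `tether`). Label 0 is background.
#'
#' All public operations in the package speak physical nanometres; voxel
#' indices never cross module boundaries. Voxel coordinates are 0-based,
#' voxel-centre: the centre of the voxel with (1-based) index `i` lies at
#' `(i - 0.5) * pitch` nm along its axis.
#'
#' @param voxels 3D integer array, indexed `[z, y, x]`.
#' @param voxel_size Named numeric `c(x=, y=, z=)`, nm per voxel, all > 0.
#' @param label_table Data frame with columns `label` (integer), `class`
#'   (character, one of the class vocabulary) and optionally `object_id`
#'   (integer identity of the biological object; several labels may share a
#'   class but not an object id).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, voxel_size, label_table) {
  if (length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3D array indexed [z, y, x].")
  }
  storage.mode(voxels) <- "integer"
  voxel_size <- unlist(voxel_size)
  if (!all(c("x", "y", "z") %in% names(voxel_size))) {
    abort("`voxel_size` must be named c(x=, y=, z=) in nm.")
  }
  voxel_size <- voxel_size[c("x", "y", "z")]
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    abort("`voxel_size` must be strictly positive (nm).")
  }
  label_table <- as_tibble(label_table)
  if (!all(c("label", "class") %in% names(label_table))) {
    abort("`label_table` needs columns `label` and `class`.")
  }
  if (!"object_id" %in% names(label_table)) {
    label_table$object_id <- label_table$label
  }
  label_table$label <- as.integer(label_table$label)
  bad <- setdiff(unique(label_table$class), CLASS_VOCAB)
  if (length(bad)) {
    abort(paste0("Unknown label class(es): ", paste(bad, collapse = ", ")))
  }
  if (min(voxels) < 0L) abort("Labels must be non-negative integers.")
  counts <- tabulate(voxels + 1L)
  present <- which(counts > 0L) - 1L
  present <- present[present != 0L]
  missing <- setdiff(present, label_table$label)
  if (length(missing)) {
    abort(paste0(
      "Labels present in the volume but absent from label_table: ",
      paste(head(missing, 10L), collapse = ", ")
    ))
  }
  structure(
    list(voxels = voxels, voxel_size = voxel_size, label_table = label_table),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<label_volume> %d x %d x %d voxels [z,y,x], voxel size %g x %g x %g nm [x,y,z]\n",
    d[1], d[2], d[3], x$voxel_size[["x"]], x$voxel_size[["y"]], x$voxel_size[["z"]]
  ))
  tab <- dplyr::count(x$label_table, .data$class)
  cat(sprintf(
    "  classes: %s\n",
    paste(sprintf("%s (%d labels)", tab$class, tab$n), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$voxels)

#' Physical extent of a label volume in nm
#'
#' @param lv A [label_volume()].
#' @return Named numeric `c(x=, y=, z=)`, nm.
#' @export
volume_extent_nm <- function(lv) {
  d <- dim(lv$voxels)
  c(
    x = d[3] * lv$voxel_size[["x"]],
    y = d[2] * lv$voxel_size[["y"]],
    z = d[1] * lv$voxel_size[["z"]]
  )
}

# labels belonging to a set of semantic classes
labels_of_class <- function(lv, classes) {
  lv$label_table$label[lv$label_table$class %in% classes]
}

#' Logical mask of one or more semantic classes
#'
#' @param lv A [label_volume()].
#' @param classes Character vector of class names.
#' @return Logical array of the same dimensions as the volume.
#' @export
class_mask <- function(lv, classes) {
  labs <- labels_of_class(lv, classes)
  lut <- logical(max(lv$label_table$label, 0L) + 1L)
  lut[labs + 1L] <- TRUE
  m <- lut[lv$voxels + 1L]
  dim(m) <- dim(lv$voxels)
  m
}

# (z,y,x) 1-based index matrix of voxels carrying any of `labels`
label_idx <- function(lv, labels) {
  which(array(lv$voxels %in% labels, dim = dim(lv$voxels)), arr.ind = TRUE) |>
    unname_idx()
}

unname_idx <- function(m) {
  m <- as.matrix(m)
  colnames(m) <- c("z", "y", "x")
  m
}

# centroid of a label's voxels in nm (x,y,z)
label_centroid_nm <- function(lv, label) {
  idx <- label_idx(lv, label)
  if (nrow(idx) == 0L) return(c(x = NA_real_, y = NA_real_, z = NA_real_))
  nm <- idx_to_nm(idx, lv$voxel_size)
  c(x = mean(nm[, "x"]), y = mean(nm[, "y"]), z = mean(nm[, "z"]))
}

# one-pass centroids for a set of labels: tibble(label, x_nm, y_nm, z_nm,
# n_voxels)
label_centroids_nm <- function(lv, labels) {
  idx <- label_idx(lv, labels)
  labs <- lv$voxels[idx]
  nm <- idx_to_nm(idx, lv$voxel_size)
  agg <- rowsum(cbind(nm, n = 1), labs)
  found <- as.integer(rownames(agg))
  n <- agg[, "n"]
  out <- tibble(
    label = found,
    x_nm = unname(agg[, "x"] / n),
    y_nm = unname(agg[, "y"] / n),
    z_nm = unname(agg[, "z"] / n),
    n_voxels = as.integer(n)
  )
  left_join(tibble(label = as.integer(labels)), out, by = "label")
}

#' Summarise the objects present in a label volume
#'
#' One row per label: class, object id, voxel count, volume in µm^3 and
#' centroid in nm.
#'
#' @param lv A [label_volume()].
#' @return A tibble.
#' @export
object_summary <- function(lv) {
  vox_vol_nm3 <- prod(lv$voxel_size)
  tt <- lv$label_table |> arrange(.data$label)
  cent <- label_centroids_nm(lv, tt$label)
  tt |>
    mutate(
      n_voxels = ifelse(is.na(cent$n_voxels), 0L, cent$n_voxels),
      volume_um3 = .data$n_voxels * vox_vol_nm3 / 1e9,
      centroid_x_nm = cent$x_nm,
      centroid_y_nm = cent$y_nm,
      centroid_z_nm = cent$z_nm
    )
}
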