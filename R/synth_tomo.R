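#' Parameters for the tomogram-scale synthetic volume
#'
#' Emulates an electron-tomography reconstruction of the infranuclear
#' RER-mitochondria-vesicle neighbourhood at isotropic nm-scale voxels:
#' an RER sheet, a mitochondrion facing it, a synaptic ribbon with its
#' vesicle pool, and tethers (thin filamentous links) in the five observed
#' contexts with planted surface-to-surface lengths. Default link-length
#' means are the printed ones (30.9 mito-RER, 52.9 vesicle-RER, 45.4
#' vesicle-vesicle at the RER, 22.3 vesicle-vesicle at the ribbon, 26.8
#' vesicle-ribbon, nm); default per-context spreads are the printed
#' standard errors scaled back to standard deviations at the printed n.
#' Lengths are drawn lognormal (strictly positive, mean exactly the
#' target); vesicle diameters are normal around 37.3 nm (RER pool) and
#' 36.3 nm (ribbon pool).
#'
#' @param voxel_size_nm Isotropic voxel size, nm.
#' @param extent_nm Named volume extent `c(x=, y=, z=)`, nm.
#' @param vesicle_diameter_mean Named `c(at_RER=, at_ribbon=)` mean
#'   diameters, nm.
#' @param vesicle_diameter_sd Diameter standard deviation, nm.
#' @param link_length_means Named per-context mean lengths, nm.
#' @param link_length_sds Named per-context standard deviations, nm.
#' @param link_counts Named per-context tether counts.
#' @param n_free_vesicles Unlinked vesicles placed around the ribbon.
#' @param n_unattached_tethers Tethers attached at one end only.
#' @param seed Integer seed.
#' @return A validated parameter list of class `tomo_gen_params`.
#' @export
tomo_gen_params <- function(voxel_size_nm = 2,
                            extent_nm = c(x = 1300, y = 800, z = 460),
                            vesicle_diameter_mean = c(at_RER = 37.3, at_ribbon = 36.3),
                            vesicle_diameter_sd = 5,
                            link_length_means = c(
                              "mito-RER" = 30.9,
                              "vesicle-RER" = 52.9,
                              "vesicle-vesicle@RER" = 45.4,
                              "vesicle-vesicle@ribbon" = 22.3,
                              "vesicle-ribbon" = 26.8
                            ),
                            link_length_sds = c(
                              "mito-RER" = 8.6,
                              "vesicle-RER" = 26.2,
                              "vesicle-vesicle@RER" = 23.4,
                              "vesicle-vesicle@ribbon" = 6.2,
                              "vesicle-ribbon" = 10.8
                            ),
                            link_counts = c(
                              "mito-RER" = 44L,
                              "vesicle-RER" = 63L,
                              "vesicle-vesicle@RER" = 61L,
                              "vesicle-vesicle@ribbon" = 78L,
                              "vesicle-ribbon" = 36L
                            ),
                            n_free_vesicles = 10L,
                            n_unattached_tethers = 3L,
                            seed = 1L) {
  bad <- setdiff(names(link_counts), LINK_CONTEXTS)
  if (length(bad)) {
    abort(paste0(
      "Unknown link context(s): ", paste(bad, collapse = ", "),
      " (vocabulary: ", paste(LINK_CONTEXTS, collapse = ", "), ")"
    ))
  }
  if (voxel_size_nm <= 0) abort("voxel_size_nm must be > 0.")
  if (any(link_length_means <= 0) || any(link_length_sds <= 0)) {
    abort("Link lengths must be > 0.")
  }
  if (length(vesicle_diameter_mean) == 1L && is.null(names(vesicle_diameter_mean))) {
    vesicle_diameter_mean <- c(
      at_RER = unname(vesicle_diameter_mean),
      at_ribbon = unname(vesicle_diameter_mean)
    )
  }
  if (any(vesicle_diameter_mean <= 0)) abort("Vesicle diameters must be > 0.")
  if (any(link_counts < 0)) abort("Link counts must be >= 0.")
  structure(
    list(
      voxel_size_nm = voxel_size_nm,
      extent_nm = unlist(extent_nm)[c("x", "y", "z")],
      vesicle_diameter_mean = vesicle_diameter_mean,
      vesicle_diameter_sd = vesicle_diameter_sd,
      link_length_means = link_length_means[LINK_CONTEXTS],
      link_length_sds = link_length_sds[LINK_CONTEXTS],
      link_counts = vapply(LINK_CONTEXTS, function(ct) {
        if (ct %in% names(link_counts)) as.integer(link_counts[[ct]]) else 0L
      }, integer(1)),
      n_free_vesicles = as.integer(n_free_vesicles),
      n_unattached_tethers = as.integer(n_unattached_tethers),
      seed = as.integer(seed)
    ),
    class = "tomo_gen_params"
  )
}

rlnorm_mean <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

# pre-drawn planted sample: iid lognormal lengths, resampled into [lo, hi]
# (the sample is drawn once per context and then placed as-is, so placement
# difficulty cannot bias the planted distribution)
draw_lengths <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    L <- rlnorm_mean(n, mean, sd)
    out <- c(out, L[L >= lo & L <= hi])
  }
  out[seq_len(n)]
}

draw_diams <- function(n, mean, sd, lo = 16) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- rnorm(n, mean, sd)
    out <- c(out, d[d >= lo])
  }
  out[seq_len(n)]
}

#' Generate a tomogram-scale label volume with planted tether truth
#'
#' The RER sheet occupies one half of the field with a mitochondrion facing
#' it; the synaptic ribbon and its vesicle pool sit in the other half, well
#' beyond the ribbon-context cutoff from the sheet. Each tether is a
#' straight rasterised segment whose endpoints lie exactly on the analytic
#' surfaces of its two structures, so the planted surface-to-surface length
#' is exact in nm. Deterministic for a fixed seed.
#'
#' @param params A [tomo_gen_params()].
#' @return List with `volume` (a [label_volume()]) and `truth` (tibbles
#'   `structures`, `vesicles`, `links`).
#' @export
generate_tomogram_volume <- function(params) {
  stopifnot(inherits(params, "tomo_gen_params"))
  set.seed(params$seed)
  v <- params$voxel_size_nm
  vs <- c(x = v, y = v, z = v)
  ext <- params$extent_nm
  dims <- c(
    ceiling(ext[["z"]] / v), ceiling(ext[["y"]] / v), ceiling(ext[["x"]] / v)
  )
  lab <- array(0L, dim = dims)

  # ---- structures ---------------------------------------------------------
  # RER sheet: a slab at low z over the left half of the field
  slab_lo <- 40; slab_hi <- 70
  slab_x_max <- 0.48 * ext[["x"]]
  zi <- which(vox_centre_nm(seq_len(dims[1L]), v) >= slab_lo &
    vox_centre_nm(seq_len(dims[1L]), v) <= slab_hi)
  xi <- which(vox_centre_nm(seq_len(dims[3L]), v) <= slab_x_max)
  lab[zi, , xi] <- 1L
  slab_top <- slab_hi

  r_mito <- 140
  gap_mito <- 12
  mito_c <- c(0.18 * ext[["x"]], 0.5 * ext[["y"]], slab_top + gap_mito + r_mito)
  lab[raster_sphere(mito_c, r_mito, dims, vs)] <- 2L

  r_rib <- 130
  rib_c <- c(
    min(0.80 * ext[["x"]], ext[["x"]] - r_rib - 120),
    0.5 * ext[["y"]],
    min(0.5 * ext[["z"]], ext[["z"]] - r_rib - 120)
  )
  lab[raster_sphere(rib_c, r_rib, dims, vs)] <- 3L
  if (rib_c[1L] - r_rib - slab_x_max < 150) {
    abort("Infeasible layout: ribbon too close to the RER sheet; enlarge extent_nm['x'].")
  }

  structures <- tibble(
    label = 1:3, kind = c("membrane", "mitochondrion", "ribbon"),
    x_nm = c(NA, mito_c[1L], rib_c[1L]),
    y_nm = c(NA, mito_c[2L], rib_c[2L]),
    z_nm = c(NA, mito_c[3L], rib_c[3L]),
    radius_nm = c(NA, r_mito, r_rib)
  )

  counts <- params$link_counts
  means <- params$link_length_means
  sds <- params$link_length_sds
  dmean <- params$vesicle_diameter_mean
  dsd <- params$vesicle_diameter_sd

  vesicles <- list()
  links <- list()
  next_ves <- 100L
  next_tet <- 5000L

  # candidate helpers: read-only, no array writes (writes happen at top level)
  sphere_candidate <- function(cen, radius) {
    idx <- raster_sphere(cen, radius, dims, vs)
    if (nrow(idx) == 0L || any(lab[idx] != 0L)) return(NULL)
    idx
  }
  # tether candidate between p and q; must not run through or alongside any
  # labeled voxel except `allowed` labels; `exclude_lin` are linear indices
  # of voxels reserved for the not-yet-committed endpoint structures
  seg_candidate <- function(p, q, allowed, exclude_lin = numeric(0)) {
    idx <- raster_segment(p, q, dims, vs)
    if (nrow(idx) == 0L) return(NULL)
    lin <- idx_to_lin(idx, dims)
    keep <- lab[idx] == 0L & !(lin %in% exclude_lin)
    idx <- idx[keep, , drop = FALSE]
    if (nrow(idx) == 0L) return(NULL)
    nb <- dilate_lin_1(idx, dims)
    touched <- setdiff(unique(lab[nb]), 0L)
    if (length(setdiff(touched, allowed))) return(NULL)
    idx
  }
  new_vesicle <- function(idx, cen, d, loc) {
    lb <- next_ves; next_ves <<- next_ves + 1L
    vesicles[[length(vesicles) + 1L]] <<- tibble(
      label = lb, diameter_nm = d, location = loc,
      x_nm = cen[1L], y_nm = cen[2L], z_nm = cen[3L]
    )
    lb
  }
  new_tether <- function(L, context, end1, end2, attached_both) {
    lb <- next_tet; next_tet <<- next_tet + 1L
    links[[length(links) + 1L]] <<- tibble(
      label = lb, context = context, length_nm = L,
      end1_label = end1, end2_label = end2,
      attached_both_ends = attached_both
    )
    lb
  }

  # ---- mito-RER tethers ---------------------------------------------------
  n <- counts[["mito-RER"]]
  h <- mito_c[3L] - slab_top
  Ls <- sort(draw_lengths(
    n, means[["mito-RER"]], sds[["mito-RER"]],
    lo = h - r_mito + 1.2, hi = 3.5 * means[["mito-RER"]]
  ), decreasing = TRUE)
  for (L in Ls) {
    done <- FALSE
    for (try in seq_len(2000L)) {
      s <- sqrt((L + r_mito)^2 - h^2)
      th <- runif(1, 0, 2 * pi)
      p <- c(mito_c[1L] + s * cos(th), mito_c[2L] + s * sin(th), slab_top)
      if (p[1L] < 30 || p[1L] > slab_x_max - 30 || p[2L] < 30 || p[2L] > ext[["y"]] - 30) next
      dirv <- (mito_c - p) / sqrt(sum((mito_c - p)^2))
      q <- mito_c - dirv * r_mito
      idx <- seg_candidate(p, q, allowed = c(1L, 2L))
      if (is.null(idx)) next
      lab[idx] <- new_tether(L, "mito-RER", 1L, 2L, TRUE)
      done <- TRUE
      break
    }
    if (!done) abort("Packing failure: mito-RER tethers.")
  }

  # ---- vesicle-RER tethers ------------------------------------------------
  n <- counts[["vesicle-RER"]]
  Ls <- sort(draw_lengths(
    n, means[["vesicle-RER"]], sds[["vesicle-RER"]],
    lo = 3 * v, hi = 3.5 * means[["vesicle-RER"]]
  ), decreasing = TRUE)
  ds <- draw_diams(n, dmean[["at_RER"]], dsd)
  for (i in seq_len(n)) {
    L <- Ls[i]; d <- ds[i]
    done <- FALSE
    for (try in seq_len(2000L)) {
      p <- c(runif(1, 40, slab_x_max - 40), runif(1, 40, ext[["y"]] - 40), slab_top)
      if (sqrt(sum((p[1:2] - mito_c[1:2])^2)) < r_mito + 30) next
      phi <- runif(1, 0, 25 / 180 * pi)
      thd <- runif(1, 0, 2 * pi)
      dirv <- c(sin(phi) * cos(thd), sin(phi) * sin(thd), cos(phi))
      q <- p + dirv * L
      cenv <- q + dirv * (d / 2)
      ves_idx <- sphere_candidate(cenv, d / 2)
      if (is.null(ves_idx)) next
      idx <- seg_candidate(p, q,
        allowed = 1L,
        exclude_lin = idx_to_lin(ves_idx, dims)
      )
      if (is.null(idx)) next
      vl <- new_vesicle(ves_idx, cenv, d, "at_RER")
      lab[ves_idx] <- vl
      lab[idx] <- new_tether(L, "vesicle-RER", vl, 1L, TRUE)
      done <- TRUE
      break
    }
    if (!done) abort("Packing failure: vesicle-RER tethers.")
  }

  # ---- vesicle-vesicle tethers (at RER and at ribbon) ---------------------
  for (context in c("vesicle-vesicle@RER", "vesicle-vesicle@ribbon")) {
    near_ribbon <- context == "vesicle-vesicle@ribbon"
    loc <- if (near_ribbon) "at_ribbon" else "at_RER"
    n <- counts[[context]]
    Ls <- sort(draw_lengths(
      n, means[[context]], sds[[context]],
      lo = 3 * v, hi = 3.5 * means[[context]]
    ), decreasing = TRUE)
    d1s <- draw_diams(n, dmean[[loc]], dsd)
    d2s <- draw_diams(n, dmean[[loc]], dsd)
    for (i in seq_len(n)) {
      L <- Ls[i]; d1 <- d1s[i]; d2 <- d2s[i]
      done <- FALSE
      for (try in seq_len(4000L)) {
      if (near_ribbon) {
        u <- runit3()
        gap1 <- runif(1, 4, 55)
        c1 <- rib_c + u * (r_rib + gap1 + d1 / 2)
      } else {
        c1 <- c(
          runif(1, 60, slab_x_max - 60), runif(1, 60, ext[["y"]] - 60),
          slab_top + runif(1, 8, 70) + d1 / 2
        )
        if (sqrt(sum((c1[1:2] - mito_c[1:2])^2)) < r_mito + 30 + d1 / 2) next
      }
      w <- runit3()
      if (!near_ribbon) w[3L] <- w[3L] * 0.3
      w <- w / sqrt(sum(w^2))
      c2 <- c1 + w * (d1 / 2 + L + d2 / 2)
      if (near_ribbon) {
        gap2 <- sqrt(sum((c2 - rib_c)^2)) - r_rib - d2 / 2
        if (gap2 < 2 || gap2 > 95) next
      } else if (c2[1L] > slab_x_max - 40) {
        next
      }
      if (any(c1 < 30) || any(c1 > ext[c("x", "y", "z")] - 30)) next
      if (any(c2 < 30) || any(c2 > ext[c("x", "y", "z")] - 30)) next
      i1 <- sphere_candidate(c1, d1 / 2)
      if (is.null(i1)) next
      i2 <- sphere_candidate(c2, d2 / 2)
      if (is.null(i2)) next
      p1 <- c1 + w * d1 / 2
      p2 <- c1 + w * (d1 / 2 + L)
      idx <- seg_candidate(p1, p2,
        allowed = integer(0),
        exclude_lin = c(idx_to_lin(i1, dims), idx_to_lin(i2, dims))
      )
      if (is.null(idx)) next
      l1 <- new_vesicle(i1, c1, d1, loc)
      l2 <- new_vesicle(i2, c2, d2, loc)
      lab[i1] <- l1
      lab[i2] <- l2
      lab[idx] <- new_tether(L, context, l1, l2, TRUE)
      done <- TRUE
      break
      }
      if (!done) abort(paste0("Packing failure: ", context, " tethers."))
    }
  }

  # ---- vesicle-ribbon tethers ---------------------------------------------
  n <- counts[["vesicle-ribbon"]]
  Ls <- sort(draw_lengths(
    n, means[["vesicle-ribbon"]], sds[["vesicle-ribbon"]],
    lo = 3 * v, hi = 3.5 * means[["vesicle-ribbon"]]
  ), decreasing = TRUE)
  ds <- draw_diams(n, dmean[["at_ribbon"]], dsd)
  for (i in seq_len(n)) {
    L <- Ls[i]; d <- ds[i]
    done <- FALSE
    for (try in seq_len(4000L)) {
      u <- runit3()
      p <- rib_c + u * r_rib
      q <- rib_c + u * (r_rib + L)
      cenv <- rib_c + u * (r_rib + L + d / 2)
      if (any(cenv < 30) || any(cenv > ext[c("x", "y", "z")] - 30)) next
      ves_idx <- sphere_candidate(cenv, d / 2)
      if (is.null(ves_idx)) next
      idx <- seg_candidate(p, q,
        allowed = 3L,
        exclude_lin = idx_to_lin(ves_idx, dims)
      )
      if (is.null(idx)) next
      vl <- new_vesicle(ves_idx, cenv, d, "at_ribbon")
      lab[ves_idx] <- vl
      lab[idx] <- new_tether(L, "vesicle-ribbon", vl, 3L, TRUE)
      done <- TRUE
      break
    }
    if (!done) abort("Packing failure: vesicle-ribbon tethers.")
  }

  # ---- free vesicles and unattached tethers -------------------------------
  placed <- 0L; tries <- 0L
  while (placed < params$n_free_vesicles) {
    tries <- tries + 1L
    if (tries > 500L * max(1L, params$n_free_vesicles)) break # cosmetic
    d <- rnorm(1L, dmean[["at_ribbon"]], dsd)
    if (d < 16) next
    u <- runit3()
    cenv <- rib_c + u * (r_rib + runif(1, 5, 90) + d / 2)
    if (any(cenv < 30) || any(cenv > ext[c("x", "y", "z")] - 30)) next
    idxv <- sphere_candidate(cenv, d / 2)
    if (is.null(idxv)) next
    lab[idxv] <- new_vesicle(idxv, cenv, d, "at_ribbon")
    placed <- placed + 1L
  }
  placed <- 0L; tries <- 0L
  while (placed < params$n_unattached_tethers) {
    tries <- tries + 1L
    if (tries > 500L * max(1L, params$n_unattached_tethers)) break
    L <- rlnorm_mean(1L, means[["vesicle-ribbon"]], sds[["vesicle-ribbon"]])
    d <- rnorm(1L, dmean[["at_ribbon"]], dsd)
    if (d < 16 || L < 3 * v) next
    u <- runit3()
    cenv <- rib_c + u * (r_rib + runif(1, 30, 80) + d / 2)
    if (any(cenv < 30) || any(cenv > ext[c("x", "y", "z")] - 30)) next
    idxv <- sphere_candidate(cenv, d / 2)
    if (is.null(idxv)) next
    w <- runit3()
    p <- cenv + w * d / 2
    q <- cenv + w * (d / 2 + L)
    idx <- seg_candidate(p, q,
      allowed = integer(0),
      exclude_lin = idx_to_lin(idxv, dims)
    )
    if (is.null(idx)) next
    vl <- new_vesicle(idxv, cenv, d, "at_ribbon")
    lab[idxv] <- vl
    lab[idx] <- new_tether(L, NA_character_, vl, NA_integer_, FALSE)
    placed <- placed + 1L
  }

  vesicles <- if (length(vesicles)) {
    bind_rows(vesicles) |> mutate(vesicle_id = dplyr::row_number(), .before = 1L)
  } else {
    tibble(
      vesicle_id = integer(), label = integer(), diameter_nm = numeric(),
      location = character(), x_nm = numeric(), y_nm = numeric(), z_nm = numeric()
    )
  }
  links <- if (length(links)) {
    bind_rows(links) |> mutate(link_id = dplyr::row_number(), .before = 1L)
  } else {
    tibble(
      link_id = integer(), label = integer(), context = character(),
      length_nm = numeric(), end1_label = integer(), end2_label = integer(),
      attached_both_ends = logical()
    )
  }

  label_table <- bind_rows(
    tibble(label = 1L, class = "membrane", object_id = 1L),
    tibble(label = 2L, class = "mitochondrion", object_id = 2L),
    tibble(label = 3L, class = "ribbon", object_id = 3L),
    if (nrow(vesicles)) {
      tibble(label = vesicles$label, class = "vesicle", object_id = vesicles$label)
    },
    if (nrow(links)) {
      tibble(label = links$label, class = "tether", object_id = links$label)
    }
  )
  lv <- label_volume(lab, vs, label_table)
  list(
    volume = lv,
    truth = list(structures = structures, vesicles = vesicles, links = links)
  )
}
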