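#' Parameters for the cell-scale synthetic label volume
#'
#' Defaults emulate the acquisition geometry and the printed summaries of the
#' system that motivates the package: SBF-SEM voxels of 19 x 19 x 50 nm, a
#' flask-shaped asymmetric cell (one flattened and one rounded side), an
#' infranuclear membrane--mitochondria network concentrated on the flattened
#' side (hemisphere volume fractions 0.23 flattened vs 0.16 rounded, 0.21
#' anterior vs 0.19 posterior), 16 surface terminals placed on the flattened
#' hemisphere with probability 0.63, mitochondria touching a membrane strand
#' with probability 0.96, and ribbons whose nearest small (Type 3) membrane
#' sheet lies at a mean distance of 515 nm. Cell dimensions are
#' order-of-magnitude choices (the geometry of real cells is not printed as
#' numbers) and are fully configurable; analyses scale with them.
#'
#' @param voxel_size nm per voxel, named `c(x=, y=, z=)`. z is the
#'   sectioning axis; the cell's longitudinal (apex-base) axis is y.
#' @param cell_width_um Full cell width along x (flattened-rounded axis).
#' @param cell_depth_um Full cell depth along z (anterior-posterior axis).
#' @param infranuclear_um Longitudinal extent of the infranuclear region
#'   (base of the cell up to the basal pole of the nucleus).
#' @param nucleus_um Longitudinal diameter of the nucleus.
#' @param neck_um Longitudinal extent of the neck/apical portion above the
#'   nucleus (the neck constriction sits inside it).
#' @param flatness_contrast Ratio of rounded-side to flattened-side boundary
#'   deviation amplitude (>1 means one side is flatter).
#' @param bulge_amplitude_nm Maximal boundary deviation of the rounded side
#'   from a longitudinal tangent line, nm.
#' @param superellipse_exp Cross-section superellipse exponents per side,
#'   `c(flat=, round=)`; higher = boxier (flatter in section).
#' @param n_terminals,p_flat_terminal Number of afferent terminals and the
#'   probability that a terminal is placed on the flattened hemisphere
#'   (0.63 ~ 10.1/16.1 from the printed per-side means).
#' @param terminal_radius_nm Bouton sphere radius.
#' @param n_ribbons,ribbon_radius_nm Synaptic ribbon count and radius.
#' @param ribbon_type3_distance_nm,ribbon_type3_distance_sd_nm Mean and sd of
#'   the planted ribbon-centre-to-nearest-Type-3-sheet distance (lognormal).
#' @param membrane_fraction_flat,membrane_fraction_round Target
#'   membrane+mitochondria volume fractions of the flattened / rounded
#'   hemisphere of the infranuclear region.
#' @param membrane_fraction_ant,membrane_fraction_post Same for the
#'   anterior / posterior hemispheres; their mean must equal the mean of the
#'   flattened/rounded pair.
#' @param sheet_area_mixture Planted sheet-size mixture: a list with
#'   `counts` (Type 1, Type 2, Type 3 sheet counts), `mean_area_um2`
#'   (per-type mean face area) and `sdlog` (per-type lognormal spread).
#' @param region_volume_share,region_area_share The "sheet-c" analysis
#'   region: a flattened-side slab enclosing this share of infranuclear
#'   cytoplasm volume and receiving this share of total membrane area.
#' @param p_mito_association Probability a mitochondrion is planted touching
#'   a membrane strand (0.96 = midpoint of the reported 95-98%).
#' @param strand_thickness_px In-plane membrane strand thickness, pixels.
#' @param flat_faces Which anatomical side the flattened hemisphere faces
#'   (`"pillar"` or `"modiolar"`); orientation varies from cell to cell.
#' @param seed Integer seed; fixed seed gives bit-identical volumes.
#' @return A validated parameter list of class `cell_gen_params`.
#' @export
cell_gen_params <- function(voxel_size = c(x = 19, y = 19, z = 50),
                            cell_width_um = 15,
                            cell_depth_um = 10,
                            infranuclear_um = 11,
                            nucleus_um = 6,
                            neck_um = 3,
                            flatness_contrast = 4,
                            bulge_amplitude_nm = 800,
                            superellipse_exp = c(flat = 3, round = 2),
                            n_terminals = 16,
                            p_flat_terminal = 0.63,
                            terminal_radius_nm = 600,
                            n_ribbons = 16,
                            ribbon_radius_nm = 150,
                            ribbon_type3_distance_nm = 515,
                            ribbon_type3_distance_sd_nm = 370,
                            membrane_fraction_flat = 0.23,
                            membrane_fraction_round = 0.16,
                            membrane_fraction_ant = 0.21,
                            membrane_fraction_post = 0.19,
                            sheet_area_mixture = list(
                              counts = c(3L, 8L, 200L),
                              mean_area_um2 = c(40, 3, 0.3),
                              sdlog = c(0.25, 0.25, 0.5)
                            ),
                            region_volume_share = 0.369,
                            region_area_share = 0.688,
                            p_mito_association = 0.96,
                            strand_thickness_px = 2L,
                            flat_faces = c("pillar", "modiolar"),
                            seed = 1L) {
  p <- list(
    voxel_size = unlist(voxel_size)[c("x", "y", "z")],
    cell_width_um = cell_width_um, cell_depth_um = cell_depth_um,
    infranuclear_um = infranuclear_um, nucleus_um = nucleus_um,
    neck_um = neck_um,
    flatness_contrast = flatness_contrast,
    bulge_amplitude_nm = bulge_amplitude_nm,
    superellipse_exp = superellipse_exp,
    n_terminals = as.integer(n_terminals),
    p_flat_terminal = p_flat_terminal,
    terminal_radius_nm = terminal_radius_nm,
    n_ribbons = as.integer(n_ribbons),
    ribbon_radius_nm = ribbon_radius_nm,
    ribbon_type3_distance_nm = ribbon_type3_distance_nm,
    ribbon_type3_distance_sd_nm = ribbon_type3_distance_sd_nm,
    membrane_fraction_flat = membrane_fraction_flat,
    membrane_fraction_round = membrane_fraction_round,
    membrane_fraction_ant = membrane_fraction_ant,
    membrane_fraction_post = membrane_fraction_post,
    sheet_area_mixture = sheet_area_mixture,
    region_volume_share = region_volume_share,
    region_area_share = region_area_share,
    p_mito_association = p_mito_association,
    strand_thickness_px = as.integer(strand_thickness_px),
    flat_faces = match.arg(flat_faces),
    seed = as.integer(seed)
  )
  probs <- c(
    p_flat_terminal = p$p_flat_terminal,
    p_mito_association = p$p_mito_association,
    membrane_fraction_flat = p$membrane_fraction_flat,
    membrane_fraction_round = p$membrane_fraction_round,
    membrane_fraction_ant = p$membrane_fraction_ant,
    membrane_fraction_post = p$membrane_fraction_post,
    region_volume_share = p$region_volume_share,
    region_area_share = p$region_area_share
  )
  if (any(probs < 0 | probs > 1)) {
    abort(paste0(
      "Probabilities/fractions must lie in [0,1]; offending: ",
      paste(names(probs)[probs < 0 | probs > 1], collapse = ", ")
    ))
  }
  if (any(p$voxel_size <= 0)) abort("voxel_size must be > 0.")
  mix <- p$sheet_area_mixture
  if (any(mix$counts < 0)) abort("sheet_area_mixture counts must be >= 0.")
  # The two hemisphere pairs describe the same total volume fraction, so
  # their means should agree. Small mismatches (as in summaries pooled over
  # different cell cohorts) are absorbed additively: the flattened/rounded
  # targets are honoured exactly and the anterior/posterior offset is
  # applied around the flattened/rounded mean.
  if (abs(mean(c(membrane_fraction_flat, membrane_fraction_round)) -
    mean(c(membrane_fraction_ant, membrane_fraction_post))) > 0.02) {
    abort(paste0(
      "Inconsistent hemisphere fractions: mean(flat, round) and ",
      "mean(anterior, posterior) describe the same total and differ by > 0.02."
    ))
  }
  if (p$flatness_contrast <= 0) abort("flatness_contrast must be > 0.")
  if (p$n_terminals < 0 || p$n_ribbons < 0) abort("counts must be >= 0.")
  structure(p, class = "cell_gen_params")
}

#' Generate a cell-scale label volume with planted ground truth
#'
#' Builds a flask-shaped asymmetric cell on an anisotropic voxel grid and
#' plants, with complete ground truth: a nucleus; membrane sheets (stacks of
#' thin in-plane strands on consecutive sections, with guaranteed in-plane
#' overlap so the adjacent-section linkage rule has a planted answer) in a
#' three-component size mixture; mitochondria (ellipsoids) touching a strand
#' with probability `p_mito_association`, filled adaptively until each
#' hemisphere's membrane+mitochondria volume fraction matches its target to
#' within +/-0.01; ribbons (spheres near the basolateral membrane), each
#' with a dedicated nearest Type 3 sheet at a planted distance; and surface
#' terminal boutons with a biased hemisphere placement. Every labeled voxel
#' traces to exactly one ground-truth object, and labels of different
#' objects are mutually exclusive.
#'
#' @param params A [cell_gen_params()].
#' @return A list with elements `volume` (a [label_volume()]) and `truth`
#'   (ground-truth tables; see Details in the package vignette).
#' @export
generate_cell_volume <- function(params) {
  stopifnot(inherits(params, "cell_gen_params"))
  set.seed(params$seed)
  vs <- params$voxel_size
  vx <- vs[["x"]]; vy <- vs[["y"]]; vz <- vs[["z"]]

  # ---- physical layout (nm); base of the cell at y = margin ---------------
  a0 <- params$cell_width_um * 1000 / 2 # half-width, x
  c0 <- params$cell_depth_um * 1000 / 2 # half-depth, z
  I <- params$infranuclear_um * 1000
  N <- params$nucleus_um * 1000
  neck <- params$neck_um * 1000
  marg_xy <- 2 * params$terminal_radius_nm + 6 * vx
  marg_z <- 2 * params$terminal_radius_nm + 6 * vz
  H <- I + N + neck
  x0 <- a0 + marg_xy
  z0 <- c0 + marg_z
  ybase <- marg_xy
  nx <- ceiling((2 * a0 + 2 * marg_xy) / vx)
  ny <- ceiling((H + 2 * marg_xy) / vy)
  nz <- ceiling((2 * c0 + 2 * marg_z) / vz)
  dims <- c(nz, ny, nx)

  A_round <- params$bulge_amplitude_nm
  A_flat <- A_round / params$flatness_contrast
  if (A_round >= 0.45 * a0) {
    abort("Infeasible geometry: bulge_amplitude_nm must be < 45% of the cell half-width.")
  }
  p_flat_exp <- params$superellipse_exp[["flat"]]
  p_round_exp <- params$superellipse_exp[["round"]]

  # taper along the length: elliptical base cap, straight body, neck
  # constriction above the nucleus flaring back toward the cuticular top
  b_cap <- min(1500, 0.35 * I)
  y_neckstart <- I + N
  taper <- function(yrel) {
    t <- rep(1, length(yrel))
    cap <- yrel < b_cap & yrel >= 0
    t[cap] <- sqrt(pmax(0, 1 - ((b_cap - yrel[cap]) / b_cap)^2))
    nk <- yrel > y_neckstart
    s <- pmin(1, (yrel[nk] - y_neckstart) / neck)
    t[nk] <- 1 - 0.45 * sin(pi * s)
    t[yrel < 0 | yrel > H] <- 0
    t
  }
  # longitudinal bulge: deviation u(yrel) in [0,1], 0 at the widest point
  y_peak <- 0.65 * y_neckstart
  h_bulge <- 0.75 * y_neckstart
  ufun <- function(yrel) pmin(1, ((yrel - y_peak) / h_bulge)^2)

  r_flat <- function(yrel) pmax(0, a0 * taper(yrel) - A_flat * ufun(yrel))
  r_round <- function(yrel) pmax(0, a0 * taper(yrel) - A_round * ufun(yrel))
  r_depth <- function(yrel) pmax(0, c0 * taper(yrel))

  # ---- rasterise the cell mask --------------------------------------------
  lab <- array(0L, dim = dims)
  xc_nm <- vox_centre_nm(seq_len(nx), vx)
  zc_nm <- vox_centre_nm(seq_len(nz), vz)
  yc_nm <- vox_centre_nm(seq_len(ny), vy)
  dxp <- xc_nm - x0 # + = flattened side
  dzp <- zc_nm - z0
  for (iy in seq_len(ny)) {
    yrel <- yc_nm[iy] - ybase
    if (yrel < 0 || yrel > H) next
    rf <- r_flat(yrel); rr <- r_round(yrel); rc <- r_depth(yrel)
    if (rf <= 0 || rr <= 0 || rc <= 0) next
    tz <- (abs(dzp) / rc)^2
    txf <- (pmax(dxp, 0) / rf)^p_flat_exp
    txr <- (pmax(-dxp, 0) / rr)^p_round_exp
    inside <- outer(tz, txf + txr, "+") <= 1
    lab[, iy, ][inside] <- 1L
  }
  if (!any(lab == 1L)) abort("Infeasible geometry: empty cell mask.")

  # ---- nucleus -------------------------------------------------------------
  nuc_centre <- c(x0, ybase + I + N / 2, z0)
  nuc_semi <- c(0.72 * a0, N / 2, min(0.72 * c0, N / 2 * 1.2))
  nuc_idx <- raster_ellipsoid(nuc_centre, nuc_semi, dims, vs)
  nuc_idx <- nuc_idx[lab[nuc_idx] == 1L, , drop = FALSE]
  if (nrow(nuc_idx) == 0L) abort("Infeasible geometry: nucleus does not fit inside the cell.")
  lab[nuc_idx] <- 2L

  # ---- frames of reference (truth) ----------------------------------------
  # per-section (z) area centroid of the cell mask = planted dynamic midline
  cellmask_counts <- function() {
    ok <- lab > 0L
    zc <- integer(nz)
    xc <- numeric(nz)
    for (iz in seq_len(nz)) {
      m <- ok[iz, , ]
      n <- sum(m)
      zc[iz] <- n
      xc[iz] <- if (n > 0) sum(colSums(m) * xc_nm) / n else NA_real_
    }
    list(n = zc, xmid = xc)
  }
  cc <- cellmask_counts()
  z_present <- which(cc$n > 0L)
  z_mid <- floor((min(z_present) + max(z_present)) / 2)
  midline_x <- cc$xmid

  # infranuclear region: basal (lower y) to the nucleus' basal-most voxel
  y_nuc_min <- min(nuc_idx[, 2L])
  infra_y_max <- y_nuc_min - 1L
  # peri-nuclear window: nucleus z-midline +/- 1.5 um of sections
  nuc_zmid_nm <- mean(vox_centre_nm(nuc_idx[, 1L], vz))
  win_half <- 1500
  win_z <- c(
    nm_to_vox(nuc_zmid_nm - win_half + vz / 2, vz, nz),
    nm_to_vox(nuc_zmid_nm + win_half - vz / 2, vz, nz)
  )

  vox_is_flat <- function(idx) xc_nm[idx[, 3L]] > midline_x[idx[, 1L]]
  vox_is_ant <- function(idx) idx[, 1L] <= z_mid
  vox_is_infra <- function(idx) idx[, 2L] <= infra_y_max

  # infranuclear quadrant voxel counts of the cell (targets denominator)
  infra_counts <- matrix(0, 2, 2, dimnames = list(c("flat", "round"), c("ant", "post")))
  for (iz in z_present) {
    m <- lab[iz, seq_len(infra_y_max), , drop = FALSE] > 0L
    perx <- colSums(m[1, , ])
    fl <- xc_nm > midline_x[iz]
    side <- if (iz <= z_mid) "ant" else "post"
    infra_counts["flat", side] <- infra_counts["flat", side] + sum(perx[fl])
    infra_counts["round", side] <- infra_counts["round", side] + sum(perx[!fl])
  }
  m_fr <- mean(c(params$membrane_fraction_flat, params$membrane_fraction_round))
  b_ant <- params$membrane_fraction_ant - m_fr
  f_q <- matrix(
    c(
      params$membrane_fraction_flat + b_ant, params$membrane_fraction_flat - b_ant,
      params$membrane_fraction_round + b_ant, params$membrane_fraction_round - b_ant
    ),
    2, 2, byrow = TRUE, dimnames = dimnames(infra_counts)
  )
  target_q <- round(infra_counts * f_q)

  # ---- analysis region (flattened-side slab with given volume share) -----
  infra_cols <- numeric(nx) # infranuclear cell voxels per x column
  for (iz in z_present) {
    m <- lab[iz, seq_len(infra_y_max), , drop = FALSE] > 0L
    infra_cols <- infra_cols + colSums(m[1, , ])
  }
  tot_infra <- sum(infra_cols)
  csum <- rev(cumsum(rev(infra_cols))) # voxels with x index >= k
  kx <- which.min(abs(csum / tot_infra - params$region_volume_share))
  region_xmin_idx <- kx
  region_share_true <- csum[kx] / tot_infra

  # ---- ribbons -------------------------------------------------------------
  next_label <- 10L
  excl <- array(as.raw(0L), dim = dims) # membrane separation / reservation mask
  ribbons <- list()
  rr <- params$ribbon_radius_nm
  d3_sdlog <- sqrt(log(1 + (params$ribbon_type3_distance_sd_nm /
    params$ribbon_type3_distance_nm)^2))
  d3_meanlog <- log(params$ribbon_type3_distance_nm) - d3_sdlog^2 / 2
  d3 <- stats::rlnorm(params$n_ribbons, d3_meanlog, d3_sdlog)
  d3 <- pmin(d3, 0.6 * min(a0, c0))
  if (params$n_ribbons > 0L) {
    placed <- 0L
    tries <- 0L
    tries_this <- 0L
    centres <- matrix(numeric(0), ncol = 3L)
    while (placed < params$n_ribbons) {
      tries <- tries + 1L
      tries_this <- tries_this + 1L
      if (tries > 1000L * params$n_ribbons) {
        abort(paste0(
          "Infeasible packing: could not place ", params$n_ribbons,
          " ribbons with the required Type-3 distance clearances; ",
          "reduce n_ribbons or ribbon_type3_distance_nm."
        ))
      }
      if (tries_this > 150L) {
        # an unluckily large planted distance can be unplaceable in a small
        # cell; redraw it (a mild truncation of the upper tail)
        d3[placed + 1L] <- min(
          stats::rlnorm(1L, d3_meanlog, d3_sdlog), 0.6 * min(a0, c0)
        )
        tries_this <- 0L
      }
      yrel <- runif(1, max(b_cap, 400), min(0.6 * I, 3000))
      on_flat <- runif(1) < params$p_flat_terminal
      zeta <- runif(1, -0.75, 0.75)
      rs <- if (on_flat) r_flat(yrel) else r_round(yrel)
      pexp <- if (on_flat) p_flat_exp else p_round_exp
      dx_b <- rs * (1 - zeta^2)^(1 / pexp)
      sgn <- if (on_flat) 1 else -1
      inward <- rr + 180
      cen <- c(
        x0 + sgn * (dx_b - inward),
        ybase + yrel,
        z0 + zeta * r_depth(yrel)
      )
      j <- placed + 1L
      if (nrow(centres) > 0L) {
        dd <- sqrt(rowSums((t(t(centres) - cen))^2))
        need <- d3[seq_len(placed)] + d3[j] + 2 * rr
        if (any(dd < need)) next
      }
      idx <- raster_sphere(cen, rr, dims, vs)
      if (nrow(idx) == 0L || any(lab[idx] != 1L)) next
      lb <- next_label
      next_label <- next_label + 1L
      lab[idx] <- lb
      excl[dilate_lin_1(idx, dims)] <- as.raw(1L)
      centres <- rbind(centres, cen)
      ribbons[[j]] <- list(
        id = j, label = lb, centre = cen, radius_nm = rr,
        d3_target_nm = d3[j], side = if (on_flat) "flattened" else "rounded"
      )
      placed <- j
      tries_this <- 0L
    }
  }
  ribbon_centres <- if (length(ribbons)) {
    do.call(rbind, lapply(ribbons, `[[`, "centre"))
  } else {
    matrix(numeric(0), ncol = 3L)
  }
  ribbon_d3 <- vapply(ribbons, `[[`, numeric(1), "d3_target_nm")

  # ---- membrane sheets -----------------------------------------------------
  mix <- params$sheet_area_mixture
  n_types <- length(mix$counts)
  sheet_plan <- list()
  sid <- 0L
  for (k in seq_len(n_types)) {
    nk <- mix$counts[k]
    if (nk == 0L) next
    meanlog <- log(mix$mean_area_um2[k] * 1e6) - mix$sdlog[k]^2 / 2
    areas <- stats::rlnorm(nk, meanlog, mix$sdlog[k])
    for (i in seq_len(nk)) {
      sid <- sid + 1L
      sheet_plan[[sid]] <- list(type = k, area_nm2 = areas[i], dedicated_ribbon = NA_integer_)
    }
  }
  # dedicate the smallest Type-3 sheets (one per ribbon) to the planted
  # ribbon-to-Type-3 distances
  t3_ids <- which(vapply(sheet_plan, function(s) s$type == 3L, logical(1)))
  if (length(ribbons) > length(t3_ids)) {
    abort("Infeasible plan: need at least one Type-3 sheet per ribbon (increase mixture counts[3]).")
  }
  if (length(ribbons)) {
    for (j in seq_along(ribbons)) {
      sheet_plan[[t3_ids[j]]]$dedicated_ribbon <- j
    }
  }
  # order: dedicated first (placement is most constrained), then by area desc
  ord <- order(
    !vapply(sheet_plan, function(s) !is.na(s$dedicated_ribbon), logical(1)),
    -vapply(sheet_plan, `[[`, numeric(1), "area_nm2")
  )
  sheet_plan <- sheet_plan[ord]

  A_tot <- sum(vapply(sheet_plan, `[[`, numeric(1), "area_nm2"))
  target_region_area <- params$region_area_share * A_tot

  thick <- params$strand_thickness_px
  lin_of <- function(idx) idx_to_lin(idx, dims)
  in_region_fun <- function(idx) idx[, 3L] >= region_xmin_idx

  # step-validity for the curve walker: the point must be free cytoplasm on
  # every section the sheet will occupy, below the nucleus, outside the
  # exclusion shell, on the requested side of the region boundary, and (for
  # Type-3 strands) outside every ribbon's planted-distance clearance ball.
  step_ok <- function(xnm, ynm, zsecs, want_region, is_t3, ribbon_free = 0L,
                      d_override = NULL) {
    ixv <- nm_to_vox(xnm, vx, nx)
    iyv <- nm_to_vox(ynm, vy, ny)
    if (iyv > infra_y_max - 1L || iyv < 2L) return(FALSE)
    if (want_region >= 0L) {
      if (want_region == 1L && ixv < region_xmin_idx) return(FALSE)
      if (want_region == 0L && ixv >= region_xmin_idx) return(FALSE)
    }
    lins <- idx_to_lin(cbind(zsecs, iyv, ixv), dims)
    if (any(lab[lins] != 1L) || any(excl[lins] != as.raw(0L))) return(FALSE)
    if (is_t3 && nrow(ribbon_centres) > 0L) {
      dd2 <- (ribbon_centres[, 1L] - xnm)^2 + (ribbon_centres[, 2L] - ynm)^2
      zr <- vox_centre_nm(zsecs, vz)
      clear <- ribbon_d3 + 140
      if (!is.null(d_override)) clear[ribbon_free] <- d_override
      for (zz in zr) {
        d <- sqrt(dd2 + (ribbon_centres[, 3L] - zz)^2)
        if (any(d < clear)) return(FALSE)
      }
    }
    TRUE
  }

  # draw one strand curve of a given arc length with a constrained random walk
  draw_curve <- function(start, theta0, length_nm, zsecs, want_region, is_t3,
                         ribbon_free = 0L, d_override = NULL) {
    step <- 40
    nstep <- max(2L, ceiling(length_nm / step))
    pts <- matrix(NA_real_, nrow = nstep + 1L, ncol = 2L)
    pts[1L, ] <- start
    theta <- theta0
    for (i in seq_len(nstep)) {
      placedstep <- FALSE
      for (attempt in seq_len(14L)) {
        cand_theta <- theta + rnorm(1, 0, 0.25) +
          (if (attempt > 1L) runif(1, -pi / 2, pi / 2) else 0)
        nxp <- pts[i, 1L] + cos(cand_theta) * step
        nyp <- pts[i, 2L] + sin(cand_theta) * step
        if (step_ok(nxp, nyp, zsecs, want_region, is_t3, ribbon_free, d_override)) {
          pts[i + 1L, ] <- c(nxp, nyp)
          theta <- cand_theta
          placedstep <- TRUE
          break
        }
      }
      if (!placedstep) return(NULL)
    }
    pts
  }

  place_sheet <- function(plan_entry, want_region) {
    type <- plan_entry$type
    area <- plan_entry$area_nm2
    ded <- plan_entry$dedicated_ribbon
    is_t3 <- type == 3L
    # z-extent by type: large sheets traverse many sections
    z_lo <- min(z_present) + 2L; z_hi <- max(z_present) - 2L
    nz_avail <- z_hi - z_lo + 1L
    nsec_target <- switch(type,
      max(6L, round(0.55 * nz_avail)),
      max(4L, round(0.22 * nz_avail)),
      sample(2:4, 1L)
    )
    for (retry in seq_len(120L)) {
      nsec <- min(nsec_target, nz_avail)
      len <- area / (nsec * vz)
      # keep single-section strands drawable inside the cell footprint
      while (len > 18 * a0 && nsec < nz_avail) {
        nsec <- min(nz_avail, nsec + max(1L, round(0.2 * nz_avail)))
        len <- area / (nsec * vz)
      }
      if (len > 30 * a0) {
        return(structure(list(), failed = "sheet area too large for the cell footprint"))
      }
      zstart <- if (!is.na(ded)) {
        zr <- nm_to_vox(ribbons[[ded]]$centre[3L], vz, nz)
        max(z_lo, min(zr - sample.int(nsec, 1L) + 1L, z_hi - nsec + 1L))
      } else {
        zr_range <- z_lo:(z_hi - nsec + 1L)
        zr_range[sample.int(length(zr_range), 1L)]
      }
      zsecs <- zstart:(zstart + nsec - 1L)
      # start point
      if (!is.na(ded)) {
        cenr <- ribbons[[ded]]$centre
        # pad for brush half-width + section jitter so the realised
        # voxel-surface distance lands on the planted value, not below it
        pad <- 0.5 * thick * vx + 1.0 * vx
        dmin <- ribbon_d3[ded] + pad
        # in-plane direction, mostly toward the cell's x-axis interior
        phi <- atan2(runif(1, -0.6, 0.6), sign(x0 - cenr[1L]) + runif(1, -0.3, 0.3))
        start <- c(cenr[1L] + cos(phi) * dmin, cenr[2L] + sin(phi) * dmin)
        theta0 <- phi + pi / 2
        if (!step_ok(start[1L], start[2L], zsecs, want_region = -1L, is_t3 = TRUE,
                     ribbon_free = ded, d_override = dmin)) next
        pts <- draw_curve(start, theta0, len, zsecs, want_region = -1L,
                          is_t3 = TRUE, ribbon_free = ded, d_override = dmin)
      } else {
        # sample a free cytoplasm start voxel on the wanted side
        for (s in seq_len(40L)) {
          iz1 <- zsecs[sample.int(length(zsecs), 1L)]
          iy1 <- sample.int(infra_y_max - 2L, 1L) + 1L
          ix1 <- if (want_region == 1L) {
            region_xmin_idx + sample.int(nx - region_xmin_idx + 1L, 1L) - 1L
          } else {
            sample.int(max(2L, region_xmin_idx - 1L), 1L)
          }
          if (lab[iz1, iy1, ix1] == 1L) break
        }
        start <- c(vox_centre_nm(ix1, vx), vox_centre_nm(iy1, vy))
        if (!step_ok(start[1L], start[2L], zsecs, want_region, is_t3)) next
        pts <- draw_curve(start, runif(1, 0, 2 * pi), len, zsecs, want_region, is_t3)
      }
      if (is.null(pts)) next
      # rasterise on each section with a bounded jitter walk (guaranteed
      # in-plane overlap between consecutive sections: |shift| <= 1 px)
      shifts <- matrix(0, nrow = nsec, ncol = 2L)
      for (s in 2:max(2L, nsec)) {
        if (s > nsec) break
        shifts[s, ] <- shifts[s - 1L, ] + c(
          runif(1, -vx, vx) * 0.9,
          runif(1, -vy, vy) * 0.9
        )
        shifts[s, ] <- pmax(pmin(shifts[s, ], 2.5 * vx), -2.5 * vx)
      }
      vox_list <- vector("list", nsec)
      ok <- TRUE
      for (s in seq_len(nsec)) {
        pp <- cbind(pts[, 1L] + shifts[s, 1L], pts[, 2L] + shifts[s, 2L])
        vxs <- raster_curve_section(pp, zsecs[s], thick, dims, vs)
        if (nrow(vxs) == 0L ||
          any(lab[vxs] != 1L) || any(excl[vxs] != as.raw(0L)) ||
          any(vxs[, 2L] > infra_y_max)) {
          ok <- FALSE
          break
        }
        vox_list[[s]] <- vxs
      }
      if (!ok) next
      return(list(
        type = type, area_nm2 = len * nsec * vz, length_nm = len,
        zsecs = zsecs, pts = pts, vox = do.call(rbind, vox_list),
        dedicated_ribbon = ded
      ))
    }
    structure(list(), failed = "could not place sheet (packing too dense)")
  }

  sheets <- list()
  region_area_acc <- 0
  for (i in seq_along(sheet_plan)) {
    pe <- sheet_plan[[i]]
    want_region <- if (!is.na(pe$dedicated_ribbon)) {
      -1L
    } else if (region_area_acc < target_region_area) 1L else 0L
    res <- place_sheet(pe, want_region)
    if (!is.null(attr(res, "failed"))) {
      abort(paste0("Membrane sheet packing failed: ", attr(res, "failed")))
    }
    lb <- next_label
    next_label <- next_label + 1L
    lab[res$vox] <- lb
    excl[dilate_lin_1(res$vox, dims)] <- as.raw(1L)
    res$label <- lb
    res$id <- i
    in_reg <- mean(in_region_fun(res$vox))
    region_area_acc <- region_area_acc + in_reg * res$area_nm2
    res$region_area_frac <- in_reg
    sheets[[i]] <- res
  }
  area_share_true <- region_area_acc / A_tot

  # ---- mitochondria: adaptive fill to the quadrant volume targets ---------
  memb_labels <- vapply(sheets, `[[`, integer(1), "label")
  memb_vox <- do.call(rbind, lapply(sheets, `[[`, "vox"))
  memb_infra <- memb_vox[vox_is_infra(memb_vox), , drop = FALSE]
  quad_of <- function(idx) {
    paste(
      ifelse(vox_is_flat(idx), "flat", "round"),
      ifelse(vox_is_ant(idx), "ant", "post"),
      sep = "."
    )
  }
  filled <- matrix(0, 2, 2, dimnames = dimnames(infra_counts))
  add_counts <- function(filled, idx) {
    q <- table(quad_of(idx))
    for (nmq in names(q)) {
      parts <- strsplit(nmq, ".", fixed = TRUE)[[1L]]
      filled[parts[1L], parts[2L]] <- filled[parts[1L], parts[2L]] + q[[nmq]]
    }
    filled
  }
  filled <- add_counts(filled, memb_infra)
  if (any(filled > target_q)) {
    abort("Membrane volume already exceeds a hemisphere target; reduce sheet_area_mixture.")
  }
  memb_quad <- quad_of(memb_infra)

  # Mitochondria are grown as compact connected blobs through free cytoplasm
  # from a seed voxel (adjacent to a membrane strand for the associated
  # fraction, well clear of any strand otherwise). Growth is voxel-exact, so
  # the per-hemisphere volume fractions can be driven to their targets, and
  # collision-free by construction even in crowded neighbourhoods.
  grow_blob <- function(seed, k_target, max_r_nm) {
    # bounding box around the seed
    rx <- ceiling(max_r_nm / vx) + 1L
    ry <- ceiling(max_r_nm / vy) + 1L
    rz <- ceiling(max_r_nm / vz) + 1L
    zr <- max(1L, seed[1L] - rz):min(nz, seed[1L] + rz)
    yr <- max(1L, seed[2L] - ry):min(infra_y_max, seed[2L] + ry)
    xr <- max(1L, seed[3L] - rx):min(nx, seed[3L] + rx)
    box <- lab[zr, yr, xr, drop = FALSE] == 1L
    bd <- dim(box)
    s_loc <- c(seed[1L] - zr[1L] + 1L, seed[2L] - yr[1L] + 1L, seed[3L] - xr[1L] + 1L)
    if (!box[s_loc[1L], s_loc[2L], s_loc[3L]]) return(NULL)
    # anisotropic nm distance of every box voxel from the seed
    dz2 <- ((seq_along(zr) - s_loc[1L]) * vz)^2
    dy2 <- ((seq_along(yr) - s_loc[2L]) * vy)^2
    dx2 <- ((seq_along(xr) - s_loc[3L]) * vx)^2
    dist2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
    cand_ok <- box & dist2 <= max_r_nm^2
    # take the k nearest candidates, then keep the seed's connected component
    ord <- order(dist2[cand_ok])
    lin_ok <- which(cand_ok)[ord]
    lin_ok <- lin_ok[seq_len(min(length(lin_ok), ceiling(1.35 * k_target)))]
    sel <- array(FALSE, dim = bd)
    sel[lin_ok] <- TRUE
    # BFS from seed through sel (26-connectivity), frontier-at-once
    seen <- array(FALSE, dim = bd)
    s_lin <- s_loc[1L] + (s_loc[2L] - 1L) * bd[1L] + (s_loc[3L] - 1L) * bd[1L] * bd[2L]
    seen[s_lin] <- TRUE
    shifts <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    frontier <- s_lin
    comp_lin <- s_lin
    while (length(frontier) > 0L) {
      fz <- (frontier - 1L) %% bd[1L] + 1L
      fy <- ((frontier - 1L) %/% bd[1L]) %% bd[2L] + 1L
      fx <- (frontier - 1L) %/% (bd[1L] * bd[2L]) + 1L
      n <- length(frontier)
      nz_ <- rep(fz, 27L) + rep(shifts[, 1L], each = n)
      ny_ <- rep(fy, 27L) + rep(shifts[, 2L], each = n)
      nx_ <- rep(fx, 27L) + rep(shifts[, 3L], each = n)
      keep <- nz_ >= 1L & nz_ <= bd[1L] & ny_ >= 1L & ny_ <= bd[2L] &
        nx_ >= 1L & nx_ <= bd[3L]
      lin <- nz_[keep] + (ny_[keep] - 1L) * bd[1L] + (nx_[keep] - 1L) * bd[1L] * bd[2L]
      lin <- lin[sel[lin] & !seen[lin]]
      if (!length(lin)) break
      lin <- unique(lin)
      seen[lin] <- TRUE
      frontier <- lin
      comp_lin <- c(comp_lin, lin)
    }
    comp <- cbind(
      (comp_lin - 1L) %% bd[1L] + 1L,
      ((comp_lin - 1L) %/% bd[1L]) %% bd[2L] + 1L,
      (comp_lin - 1L) %/% (bd[1L] * bd[2L]) + 1L
    )
    if (nrow(comp) > k_target) {
      # trim to the k nearest-by-distance voxels of the component
      d <- dist2[comp]
      comp <- comp[order(d)[seq_len(k_target)], , drop = FALSE]
      # trimming by distance keeps the blob star-shaped around the seed, so
      # connectivity survives
    }
    cbind(
      z = comp[, 1L] + zr[1L] - 1L,
      y = comp[, 2L] + yr[1L] - 1L,
      x = comp[, 3L] + xr[1L] - 1L
    )
  }

  mitos <- list()
  mid <- 0L
  vox_vol <- prod(vs)
  tol_vox <- pmax(0.0015 * infra_counts, 30)
  fail_streak <- 0L
  free_seed_pool <- NULL
  while (TRUE) {
    deficit <- target_q - filled
    rel <- deficit / infra_counts
    if (all(deficit <= tol_vox)) break
    q <- which(rel == max(rel), arr.ind = TRUE)[1L, ]
    qname <- paste(rownames(infra_counts)[q[1L]], colnames(infra_counts)[q[2L]], sep = ".")
    want_flat <- rownames(infra_counts)[q[1L]] == "flat"
    want_ant <- colnames(infra_counts)[q[2L]] == "ant"
    def_k <- deficit[q[1L], q[2L]]
    # target size ~ 0.05-0.25 um^3, clipped to the remaining deficit
    k_target <- round(min(
      def_k + tol_vox[q[1L], q[2L]],
      stats::rlnorm(1, log(5500), 0.35)
    ))
    k_target <- max(k_target, 60L)
    attach <- runif(1) < params$p_mito_association
    # attachment is only possible where the wanted quadrant holds membrane;
    # otherwise the mitochondrion is placed free (the truth records reality)
    pool <- if (nrow(memb_infra) > 0L) which(memb_quad == qname) else integer(0)
    if (!length(pool)) attach <- FALSE
    idx <- NULL
    for (try in seq_len(80L)) {
      # if the quadrant's strand neighbourhood is saturated, place free
      if (try > 40L) attach <- FALSE
      if (attach) {
        mv <- memb_infra[pool[sample.int(length(pool), 1L)], ]
        # a free voxel 26-adjacent to this membrane voxel
        nb <- dilate_lin_1(matrix(mv, ncol = 3L), dims)
        nb <- nb[lab[nb] == 1L]
        if (!length(nb)) next
        lin <- nb[sample.int(length(nb), 1L)]
        seed <- c(
          as.integer((lin - 1) %% dims[1L] + 1),
          as.integer(((lin - 1) %/% dims[1L]) %% dims[2L] + 1),
          as.integer((lin - 1) %/% (as.double(dims[1L]) * dims[2L]) + 1)
        )
        if (seed[2L] > infra_y_max) next
      } else {
        iz1 <- z_present[sample.int(length(z_present), 1L)]
        iy1 <- sample.int(infra_y_max, 1L)
        ix1 <- sample.int(nx, 1L)
        if (lab[iz1, iy1, ix1] != 1L) next
        isflat <- xc_nm[ix1] > midline_x[iz1]
        if (isflat != want_flat || (iz1 <= z_mid) != want_ant) next
        seed <- c(iz1, iy1, ix1)
        # keep unassociated mitochondria clearly away from every strand
        sgap <- local_box_gap_nm(matrix(seed, ncol = 3L), memb_vox, vs,
          margin_nm = 12 * vx
        )
        if (!is.na(sgap) && sgap < 10 * vx) next
      }
      max_r <- max(3.5 * vz, 1.45 * (3 * k_target * vox_vol / (4 * pi))^(1 / 3))
      if (!attach) max_r <- min(max_r, 6 * vx) # stay inside the seed clearance
      blob <- grow_blob(seed, k_target, max_r)
      if (is.null(blob) || nrow(blob) < 50L) next
      if (!attach) {
        g <- local_box_gap_nm(blob, memb_vox, vs, margin_nm = 4 * vx)
        if (is.na(g) || g < 3.2 * vx) next
      }
      idx <- blob
      break
    }
    if (is.null(idx)) {
      fail_streak <- fail_streak + 1L
      if (fail_streak > 40L) {
        abort(paste0(
          "Infeasible packing: cannot reach the planted hemisphere volume ",
          "fractions with mitochondria (quadrant ",
          rownames(infra_counts)[q[1L]], "/", colnames(infra_counts)[q[2L]], ")."
        ))
      }
      next
    }
    fail_streak <- 0L
    mid <- mid + 1L
    lb <- next_label
    next_label <- next_label + 1L
    lab[idx] <- lb
    filled <- add_counts(filled, idx[vox_is_infra(idx), , drop = FALSE])
    nmc <- idx_to_nm(idx, vs)
    mitos[[mid]] <- list(
      id = mid, label = lb,
      centre = c(mean(nmc[, "x"]), mean(nmc[, "y"]), mean(nmc[, "z"])),
      attached = attach
    )
  }

  # ---- terminals -----------------------------------------------------------
  terminals <- list()
  rt <- params$terminal_radius_nm
  t_centres <- matrix(numeric(0), ncol = 3L)
  for (j in seq_len(params$n_terminals)) {
    on_flat <- runif(1) < params$p_flat_terminal
    done <- FALSE
    for (try in seq_len(300L)) {
      yrel <- runif(1, max(0.25 * b_cap, 300), 0.9 * I)
      zeta <- runif(1, -0.8, 0.8)
      rs <- if (on_flat) r_flat(yrel) else r_round(yrel)
      if (rs <= 0) next
      pexp <- if (on_flat) p_flat_exp else p_round_exp
      dx_b <- rs * (1 - zeta^2)^(1 / pexp)
      sgn <- if (on_flat) 1 else -1
      surf <- c(x0 + sgn * dx_b, ybase + yrel, z0 + zeta * r_depth(yrel))
      dir <- surf - c(x0, surf[2L], z0)
      dir <- dir / sqrt(sum(dir^2))
      cen <- surf + dir * (0.85 * rt)
      if (nrow(t_centres) > 0L &&
        min(sqrt(rowSums((t(t(t_centres) - cen))^2))) < 2.1 * rt) {
        next
      }
      idx <- raster_sphere(cen, rt, dims, vs)
      idx <- idx[lab[idx] == 0L, , drop = FALSE]
      if (nrow(idx) < 20L) next
      lb <- next_label
      next_label <- next_label + 1L
      lab[idx] <- lb
      t_centres <- rbind(t_centres, cen)
      terminals[[j]] <- list(
        id = j, label = lb, centre = cen, radius_nm = rt,
        side = if (on_flat) "flattened" else "rounded",
        y_nm = cen[2L] - ybase
      )
      done <- TRUE
      break
    }
    if (!done) {
      abort("Infeasible packing: could not place all terminals on the cell surface.")
    }
  }

  # ---- post-hoc truths -----------------------------------------------------
  # exact nearest planted-sheet distance per ribbon and sheet type
  type_vox <- lapply(seq_len(n_types), function(k) {
    vv <- lapply(sheets, function(s) if (s$type == k) s$vox else NULL)
    vv <- vv[!vapply(vv, is.null, logical(1))]
    if (length(vv)) do.call(rbind, vv) else matrix(integer(0), ncol = 3L)
  })
  ribbon_truth <- purrr::map(ribbons, function(rb) {
    dists <- vapply(seq_len(n_types), function(k) {
      point_box_dist_nm(rb$centre, type_vox[[k]], vs)$dist
    }, numeric(1))
    tibble(
      ribbon_id = rb$id, label = rb$label,
      x_nm = rb$centre[1L], y_nm = rb$centre[2L], z_nm = rb$centre[3L],
      d3_target_nm = rb$d3_target_nm,
      d_type1_nm = dists[1L], d_type2_nm = dists[2L], d_type3_nm = dists[3L]
    )
  }) |> bind_rows()

  achieved_frac <- c(
    flat = sum(filled["flat", ]) / sum(infra_counts["flat", ]),
    round = sum(filled["round", ]) / sum(infra_counts["round", ]),
    ant = sum(filled[, "ant"]) / sum(infra_counts[, "ant"]),
    post = sum(filled[, "post"]) / sum(infra_counts[, "post"])
  )

  label_table <- bind_rows(
    tibble(label = 1L, class = "cell", object_id = 1L),
    tibble(label = 2L, class = "nucleus", object_id = 2L),
    tibble(
      label = vapply(sheets, `[[`, integer(1), "label"),
      class = "membrane",
      object_id = vapply(sheets, `[[`, integer(1), "label")
    ),
    if (length(ribbons)) {
      tibble(
        label = vapply(ribbons, `[[`, integer(1), "label"),
        class = "ribbon",
        object_id = vapply(ribbons, `[[`, integer(1), "label")
      )
    },
    if (length(mitos)) {
      tibble(
        label = vapply(mitos, `[[`, integer(1), "label"),
        class = "mitochondrion",
        object_id = vapply(mitos, `[[`, integer(1), "label")
      )
    },
    if (length(terminals)) {
      tibble(
        label = vapply(terminals, `[[`, integer(1), "label"),
        class = "terminal",
        object_id = vapply(terminals, `[[`, integer(1), "label")
      )
    }
  )
  lv <- label_volume(lab, vs, label_table)

  mod_of_side <- function(side) {
    flat_is <- params$flat_faces # which anatomical side the flattened face looks at
    if (side == "flattened") {
      if (flat_is == "modiolar") "modiolar" else "pillar"
    } else {
      if (flat_is == "modiolar") "pillar" else "modiolar"
    }
  }

  truth <- list(
    params = params,
    dims = dims,
    base_y_nm = ybase,
    neck_y_nm = ybase + y_neckstart + neck / 2,
    midline = tibble(
      z_index = seq_len(nz), x_nm = midline_x,
      n_cell_voxels = cc$n
    ),
    z_mid_index = z_mid,
    infranuclear = list(
      y_max_index = infra_y_max,
      y_boundary_nm = infra_y_max * vy,
      window_z_range = win_z
    ),
    fractions = tibble(
      hemisphere = c("flattened", "rounded", "anterior", "posterior"),
      target_frac = c(
        params$membrane_fraction_flat, params$membrane_fraction_round,
        params$membrane_fraction_ant, params$membrane_fraction_post
      ),
      planted_frac = as.numeric(achieved_frac)
    ),
    quadrant_counts = list(cell = infra_counts, organelle = filled),
    region = list(
      x_min_index = region_xmin_idx,
      x_min_nm = (region_xmin_idx - 1L) * vx,
      volume_share_true = region_share_true,
      area_share_true = area_share_true
    ),
    sheets = tibble(
      sheet_id = vapply(sheets, `[[`, integer(1), "id"),
      label = vapply(sheets, `[[`, integer(1), "label"),
      type = vapply(sheets, `[[`, integer(1), "type"),
      n_strands = vapply(sheets, function(s) length(s$zsecs), integer(1)),
      z_first = vapply(sheets, function(s) min(s$zsecs), integer(1)),
      z_last = vapply(sheets, function(s) max(s$zsecs), integer(1)),
      strand_length_nm = vapply(sheets, `[[`, numeric(1), "length_nm"),
      area_um2 = vapply(sheets, `[[`, numeric(1), "area_nm2") / 1e6,
      region_area_frac = vapply(sheets, `[[`, numeric(1), "region_area_frac"),
      dedicated_ribbon = vapply(sheets, function(s) {
        as.integer(s$dedicated_ribbon %||% NA_integer_)
      }, integer(1))
    ),
    mitochondria = tibble(
      mito_id = vapply(mitos, `[[`, integer(1), "id"),
      label = vapply(mitos, `[[`, integer(1), "label"),
      attached = vapply(mitos, `[[`, logical(1), "attached"),
      x_nm = vapply(mitos, function(m) m$centre[1L], numeric(1)),
      y_nm = vapply(mitos, function(m) m$centre[2L], numeric(1)),
      z_nm = vapply(mitos, function(m) m$centre[3L], numeric(1))
    ),
    ribbons = ribbon_truth,
    terminals = tibble(
      terminal_id = vapply(terminals, `[[`, integer(1), "id"),
      label = vapply(terminals, `[[`, integer(1), "label"),
      side = vapply(terminals, `[[`, character(1), "side"),
      radial = vapply(terminals, function(t) mod_of_side(t$side), character(1)),
      y_nm = vapply(terminals, `[[`, numeric(1), "y_nm"),
      x_nm = vapply(terminals, function(t) t$centre[1L], numeric(1)),
      z_nm = vapply(terminals, function(t) t$centre[3L], numeric(1))
    )
  )
  list(volume = lv, truth = truth)
}
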