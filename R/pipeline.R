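# Orchestration: simulate -> frame -> stereology -> sheets -> stats -> tomo,
# with a single config, mandatory seeds for stochastic stages, an output
# manifest echoing every threshold, and deterministic file output (identical
# config + seed => byte-identical tables).

#' Build a pipeline run configuration
#'
#' All thresholds of the analysis live here and are echoed into the run
#' manifest, so a run is reproducible from its manifest alone and
#' sensitivity analyses are one-argument changes.
#'
#' @param cell_params A [cell_gen_params()], or `NULL` to skip cell stages.
#' @param tomo_params A [tomo_gen_params()], or `NULL` to skip the tomogram
#'   stage.
#' @param input_volume Path to an existing label volume (alternative to
#'   `cell_params`).
#' @param stages Character vector of stages to run, in dependency order.
#' @param seed Integer; mandatory if any stochastic stage runs.
#' @param grid_spacing_nm Whole-cell stereology grid spacing.
#' @param overlap_min Strand-linkage overlap rule.
#' @param gap_threshold_nm Mito-membrane association criterion.
#' @param ribbon_context_nm Ribbon-context cutoff for tether classification.
#' @param area_mode Sheet-area convention.
#' @param class_method Sheet classification method.
#' @param class_boundaries Manual thresholds (list with `t1`, `t2`), if any.
#' @param write_volumes Also export the simulated volumes as TIFF+sidecar.
#' @return A `run_config` list.
#' @export
run_config <- function(cell_params = cell_gen_params(),
                       tomo_params = NULL,
                       input_volume = NULL,
                       stages = c("simulate", "frame", "stereology", "sheets", "stats", "tomo"),
                       seed = NULL,
                       grid_spacing_nm = c(x = 200, y = 200, z = 200),
                       overlap_min = 1L,
                       gap_threshold_nm = NULL,
                       ribbon_context_nm = 100,
                       area_mode = "sheet_face",
                       class_method = "largest_gap",
                       class_boundaries = NULL,
                       write_volumes = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  stochastic <- any(c("simulate", "stereology") %in% stages)
  if (stochastic && is.null(seed)) {
    abort("A seed is mandatory when stochastic stages (simulate, stereology) run.")
  }
  structure(
    list(
      cell_params = cell_params, tomo_params = tomo_params,
      input_volume = input_volume, stages = stages,
      seed = if (is.null(seed)) NULL else as.integer(seed),
      grid_spacing_nm = unlist(grid_spacing_nm),
      overlap_min = as.integer(overlap_min),
      gap_threshold_nm = gap_threshold_nm,
      ribbon_context_nm = ribbon_context_nm,
      area_mode = area_mode,
      class_method = class_method,
      class_boundaries = class_boundaries,
      write_volumes = isTRUE(write_volumes)
    ),
    class = "run_config"
  )
}

config_digest <- function(config) {
  # small deterministic digest (djb2 over the deparsed config) - enough to
  # spot a manifest/config mismatch without external dependencies
  s <- paste(deparse(unclass(config)), collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order, writing CSV tables
#' (via [write_measurements()], deterministic row order) and a JSON
#' manifest into `out_dir`. A stage failure aborts the run with the failing
#' stage named; tables of completed stages are kept next to a
#' `FAILED` marker file.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  manifest <- list(
    package = "cytoarch3d",
    version = as.character(utils::packageVersion("cytoarch3d")),
    config_digest = config_digest(config),
    seed = config$seed,
    stages = config$stages,
    thresholds = list(
      grid_spacing_nm = as.list(config$grid_spacing_nm),
      overlap_min = config$overlap_min,
      gap_threshold_nm = config$gap_threshold_nm,
      ribbon_context_nm = config$ribbon_context_nm,
      area_mode = config$area_mode,
      class_method = config$class_method,
      class_boundaries = config$class_boundaries
    )
  )
  fail <- function(stage, e) {
    writeLines(
      paste0("stage: ", stage, "\n", conditionMessage(e)),
      file.path(out_dir, "FAILED")
    )
    abort(paste0("Pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) fail(stage, e))
  }

  cellish <- intersect(config$stages, c("simulate", "frame", "stereology", "sheets", "stats"))
  if (length(cellish)) {
    if ("simulate" %in% config$stages && !is.null(config$cell_params)) {
      res$cell <- run_stage("simulate", {
        p <- config$cell_params
        p$seed <- config$seed
        generate_cell_volume(p)
      })
      lv <- res$cell$volume
      if (config$write_volumes) {
        write_label_volume(lv, file.path(out_dir, "cell_volume.tif"))
      }
    } else if (!is.null(config$input_volume)) {
      lv <- run_stage("simulate", read_label_volume(config$input_volume))
      res$cell <- list(volume = lv, truth = NULL)
    } else {
      lv <- NULL
    }
    if (!is.null(lv)) {
      if ("frame" %in% config$stages) {
        res$frame <- run_stage("frame", cell_frame(lv))
        readr::write_csv(res$frame$centre_line, file.path(out_dir, "centre_line.csv"),
          progress = FALSE
        )
        write_measurements(
          as_tibble(res$frame$flatness) |>
            dplyr::rename(n_rows_count = "n_rows"),
          file.path(out_dir, "flatness.csv")
        )
      }
      if ("stereology" %in% config$stages && !is.null(res$frame)) {
        res$stereology <- run_stage("stereology", {
          grid <- make_point_grid(lv,
            spacing_nm = config$grid_spacing_nm,
            mode = "whole", frame = res$frame, offset = "sur",
            seed = config$seed
          )
          pts <- classify_points(grid, lv, res$frame)
          infra <- dplyr::filter(pts, .data$infranuclear)
          bind_rows(
            volume_fraction(infra, by = "hemi_fr") |>
              dplyr::rename(region = "hemi_fr"),
            volume_fraction(infra, by = "hemi_ap") |>
              dplyr::rename(region = "hemi_ap")
          )
        })
        write_measurements(res$stereology, file.path(out_dir, "fractions.csv"))
      }
      if ("sheets" %in% config$stages) {
        res$sheets <- run_stage("sheets", {
          strands <- extract_strands(lv)
          sheets <- link_strands(strands, overlap_min = config$overlap_min)
          sheets <- sheet_area(sheets, strands, lv, mode = config$area_mode)
          cl <- classify_sheets(sheets,
            method = config$class_method,
            boundaries = config$class_boundaries
          )
          list(
            strands = strands, sheets = cl$assignments,
            classification = cl
          )
        })
        write_measurements(
          res$sheets$sheets |>
            select(
              "sheet_id", "class", "area_um2", "n_strands_count",
              "z_first_index", "z_last_index"
            ),
          file.path(out_dir, "sheets.csv")
        )
        write_measurements(
          generics::tidy(res$sheets$classification),
          file.path(out_dir, "sheet_types.csv")
        )
      }
      if ("stats" %in% config$stages && !is.null(res$sheets) && !is.null(res$frame)) {
        res$stats <- run_stage("stats", {
          smap <- sheet_voxel_map(lv, res$sheets$strands, res$sheets$sheets)
          scl <- res$sheets$sheets |> select("sheet_id", "class")
          assoc <- mito_membrane_association(lv,
            gap_threshold_nm = config$gap_threshold_nm,
            sheet_map = smap, sheet_classes = scl
          )
          dens <- mito_density_per_type(
            assoc,
            generics::tidy(res$sheets$classification) |>
              select("class", "total_area_um2"),
            scl
          )
          rib <- ribbon_to_sheet_distances(lv, smap, scl)
          term <- terminal_distribution(lv, res$frame)
          list(
            associations = assoc, densities = dens,
            ribbon_distances = rib, terminals = term
          )
        })
        write_measurements(
          res$stats$associations |> select(-"sheet_ids") |>
            dplyr::rename(mito_index_id = "mito_id", label_id = "label"),
          file.path(out_dir, "associations.csv")
        )
        write_measurements(res$stats$densities, file.path(out_dir, "mito_densities.csv"))
        write_measurements(
          res$stats$ribbon_distances |>
            dplyr::rename(ribbon_index_id = "ribbon_id", label_id = "label"),
          file.path(out_dir, "ribbon_distances.csv")
        )
        write_measurements(
          as_tibble(res$stats$terminals) |>
            dplyr::rename(terminal_index_id = "terminal_id", label_id = "label"),
          file.path(out_dir, "terminals.csv")
        )
      }
    }
  }
  if ("tomo" %in% config$stages && !is.null(config$tomo_params)) {
    res$tomo <- run_stage("tomo", {
      p <- config$tomo_params
      p$seed <- config$seed
      g <- generate_tomogram_volume(p)
      links <- measure_links(g$volume, ribbon_context_nm = config$ribbon_context_nm)
      ves <- vesicle_diameters(g$volume)
      ctx <- compare_contexts(links)
      list(gen = g, links = links, vesicles = ves, contexts = ctx)
    })
    if (config$write_volumes) {
      write_label_volume(res$tomo$gen$volume, file.path(out_dir, "tomo_volume.tif"))
    }
    write_measurements(
      res$tomo$links |>
        dplyr::rename(link_index_id = "link_id", label_id = "label") |>
        dplyr::rename(end1_id = "end1_label", end2_id = "end2_label"),
      file.path(out_dir, "links.csv")
    )
    write_measurements(
      res$tomo$vesicles |>
        dplyr::rename(vesicle_index_id = "vesicle_id", label_id = "label"),
      file.path(out_dir, "vesicles.csv")
    )
    write_measurements(
      res$tomo$contexts$by_context,
      file.path(out_dir, "link_contexts.csv")
    )
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(res)
}

#' Summarise a completed pipeline run
#'
#' Reads the CSV tables of a run directory back into a per-cell summary
#' mirroring the reporting shape of the analysis: hemisphere fractions,
#' terminal counts, per-type sheet statistics, ribbon distance means,
#' link-context means. Only blocks whose stage ran appear.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return A `run_report` list; print it for a readable summary.
#' @export
make_report <- function(run_dir) {
  if (!dir.exists(run_dir)) abort(paste0("No run directory: ", run_dir))
  if (file.exists(file.path(run_dir, "FAILED"))) {
    abort(paste0(
      "Run is marked FAILED: ",
      paste(readLines(file.path(run_dir, "FAILED")), collapse = "; ")
    ))
  }
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) abort("Run directory has no manifest.json.")
  rd <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) readr::read_csv(p, show_col_types = FALSE) else NULL
  }
  out <- list(
    manifest = jsonlite::read_json(manifest_path, simplifyVector = TRUE),
    fractions = rd("fractions.csv"),
    flatness = rd("flatness.csv"),
    sheet_types = rd("sheet_types.csv"),
    terminals = rd("terminals.csv"),
    ribbon_distances = rd("ribbon_distances.csv"),
    densities = rd("mito_densities.csv"),
    link_contexts = rd("link_contexts.csv")
  )
  if (all(vapply(out[-1], is.null, logical(1)))) {
    abort("Run directory contains no stage tables.")
  }
  structure(out, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> cytoarch3d", x$manifest$version %||% "", "\n")
  if (!is.null(x$fractions)) {
    cat("\nMembrane+mitochondria volume fractions by hemisphere:\n")
    print(as.data.frame(x$fractions))
  }
  if (!is.null(x$terminals)) {
    tc <- table(x$terminals$hemi_fr)
    cat("\nTerminals per hemisphere:", paste(names(tc), tc, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$sheet_types)) {
    cat("\nSheet type statistics:\n")
    print(as.data.frame(x$sheet_types))
  }
  if (!is.null(x$ribbon_distances)) {
    agg <- stats::aggregate(
      distance_nm ~ class,
      data = x$ribbon_distances, FUN = mean
    )
    cat("\nMean ribbon-to-sheet distance by type (nm):\n")
    print(agg)
  }
  if (!is.null(x$link_contexts)) {
    cat("\nTether lengths by context (nm):\n")
    print(as.data.frame(x$link_contexts))
  }
  invisible(x)
}
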