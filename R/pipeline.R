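#' Pipeline configuration
#'
#' Collects the per-stage settings of the full workflow (separation, row
#' segmentation, trunk detection, canopy profiling) with the published
#' defaults. Unknown keys are rejected so typos cannot silently fall back
#' to defaults.
#'
#' @param input path to the input cloud, or `NULL` when a `point_cloud` is
#'   passed to [run_pipeline()] directly.
#' @param output_dir directory for artifacts; `NULL` disables writing.
#' @param seed random seed recorded in the manifest.
#' @param ground list: `gr`, `dt`, `iterations`, `rigidness`, `cell_size`,
#'   `use_class_field` (take a pre-classified ground class 2 instead of
#'   running the cloth filter).
#' @param rows list: `eps`, `min_points`, `voxel`, `merge_distance`.
#' @param trunks list: `radius`, `voxel`, `eps`, `min_points`, `otsu_bins`.
#' @param canopy list: `n_segments` or `segment_length`, `alpha`,
#'   `upper_pct`, `lower_pct`, `sor_k`, `sor_mult`, `width_axis`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, output_dir = NULL, seed = 1L,
                            ground = list(), rows = list(),
                            trunks = list(), canopy = list()) {
  defaults <- list(
    ground = list(gr = 0.3, dt = 0.3, iterations = 500L, rigidness = 2L,
                  cell_size = 0.3, use_class_field = FALSE),
    rows = list(eps = 0.35, min_points = 40L, voxel = 0.1,
                merge_distance = 1.0),
    trunks = list(radius = 0.25, voxel = 0.05, eps = 0.10, min_points = 5L,
                  otsu_bins = 256L),
    canopy = list(n_segments = 250L, segment_length = NULL, alpha = 0.3,
                  upper_pct = 90, lower_pct = 10, sor_k = 10L,
                  sor_mult = 2.0, width_axis = "cross"))
  merge_section <- function(section, user) {
    unknown <- setdiff(names(user), names(defaults[[section]]))
    if (length(unknown))
      stop(sprintf("unknown %s config key(s): %s", section,
                   paste(unknown, collapse = ", ")))
    utils::modifyList(defaults[[section]], user, keep.null = TRUE)
  }
  structure(list(input = input, output_dir = output_dir,
                 seed = as.integer(seed),
                 ground = merge_section("ground", ground),
                 rows = merge_section("rows", rows),
                 trunks = merge_section("trunks", trunks),
                 canopy = merge_section("canopy", canopy)),
            class = "pipeline_config")
}

#' Run the full vineyard pipeline
#'
#' Executes ground/plant separation, terrain modeling, height
#' normalization, row segmentation (plant then ground), per-row trunk
#' detection and per-row canopy profiling, and optionally writes all
#' artifacts (per-row clouds, trunk and profile CSVs, a manifest JSON
#' linking outputs to the configuration).
#'
#' @param config a [pipeline_config()] object.
#' @param cloud optional in-memory `point_cloud`; otherwise `config$input`
#'   is read.
#' @param do_trunks,do_profiles disable the trunk-detection or
#'   canopy-profiling stage (row segmentation always runs).
#' @return an object of class `pipeline_result`: `separation`, `terrain`,
#'   `model` (the `row_model` with ground rows), `trunks` (tibble of all
#'   detected trunks in original world coordinates), `trunk_sets` (per-row
#'   detail), `profiles` (per-row `segment_profile`), `counts` (points in
#'   and out per stage) and the `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), cloud = NULL,
                         do_trunks = TRUE, do_profiles = TRUE) {
  t_start <- Sys.time()
  if (is.null(cloud)) {
    if (is.null(config$input)) stop("no input: give `cloud` or config$input")
    cloud <- read_point_cloud(config$input)
  }
  counts <- list(input = n_points(cloud))

  gp <- config$ground
  cls <- pc_attr(cloud, "class")
  if (isTRUE(gp$use_class_field) && !is.null(cls)) {
    gi <- which(cls == 2L)
    sep <- structure(list(ground = pc_subset(cloud, gi),
                          plant = pc_subset(cloud, setdiff(seq_len(n_points(cloud)), gi)),
                          ground_idx = gi,
                          plant_idx = setdiff(seq_len(n_points(cloud)), gi),
                          cloth = NULL,
                          params = ground_filter_params(gp$gr, gp$dt)),
                     class = "ground_separation")
  } else {
    sep <- csf_ground_filter(cloud, ground_filter_params(
      gr = gp$gr, dt = gp$dt, iterations = gp$iterations,
      rigidness = gp$rigidness))
  }
  counts$ground <- n_points(sep$ground)
  counts$plant <- n_points(sep$plant)

  terrain <- build_terrain_model(sep$ground, cell_size = gp$cell_size)
  plant_norm <- normalize_heights(sep$plant, terrain)

  rp <- config$rows
  model <- segment_rows(plant_norm,
                        cluster = cluster_params(rp$eps, rp$min_points),
                        merge = merge_params(rp$merge_distance),
                        voxel = rp$voxel)
  model <- segment_ground_rows(sep$ground, model)
  counts$rows <- model$n_rows

  tp <- config$trunks
  feat <- feature_params(tp$radius, tp$voxel)
  tcl <- cluster_params(tp$eps, tp$min_points)
  ground_rot <- rotate_xy(sep$ground, model$theta, model$pivot)
  trunk_sets <- list()
  trunk_rows <- list()
  if (do_trunks) for (r in model$rows) {
    if (!length(r$ground_idx)) next
    ts <- detect_trunks(pc_subset(ground_rot, r$ground_idx), feat, tcl,
                        otsu_bins = tp$otsu_bins)
    trunk_sets[[as.character(r$id)]] <- ts
    if (nrow(ts$positions)) {
      # back to the original frame: inverse rotation, then origin
      world <- rotate_xy_mat(ts$positions[, 1:2, drop = FALSE],
                             -model$theta, model$pivot)
      trunk_rows[[length(trunk_rows) + 1]] <- tibble::tibble(
        row_id = r$id, trunk_id = seq_len(nrow(ts$positions)),
        x = world[, 1] + cloud$origin[1],
        y = world[, 2] + cloud$origin[2],
        z = ts$positions[, 3] + cloud$origin[3],
        cluster_size = lengths(ts$members),
        mean_sphericity = vapply(ts$members, function(ix)
          mean(pc_attr(ts$field$cloud, "sphericity")[ix]), 0))
    }
  }
  trunks <- if (length(trunk_rows)) do.call(rbind, trunk_rows)
            else tibble::tibble(row_id = integer(), trunk_id = integer(),
                                x = numeric(), y = numeric(), z = numeric(),
                                cluster_size = integer(),
                                mean_sphericity = numeric())
  counts$trunks <- nrow(trunks)

  cp <- config$canopy
  scheme <- if (!is.null(cp$segment_length))
    segmentation_scheme(segment_length = cp$segment_length)
  else segmentation_scheme(n_segments = cp$n_segments)
  cpar <- canopy_params(alpha = cp$alpha, upper_pct = cp$upper_pct,
                        lower_pct = cp$lower_pct, sor_k = cp$sor_k,
                        sor_mult = cp$sor_mult, width_axis = cp$width_axis)
  plant_rot <- rotate_xy(plant_norm, model$theta, model$pivot)
  profiles <- list()
  if (do_profiles) {
    profiles <- lapply(model$rows, function(r)
      profile_row(pc_subset(plant_rot, r$plant_idx), scheme, cpar))
    names(profiles) <- vapply(model$rows, function(r) as.character(r$id), "")
  }

  result <- structure(list(
    separation = sep, terrain = terrain, model = model,
    trunks = trunks, trunk_sets = trunk_sets, profiles = profiles,
    counts = counts, config = config,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_outputs(result, cloud)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d points -> %d ground / %d plant | %d rows | %d trunks (%.1f s)\n",
              x$counts$input, x$counts$ground, x$counts$plant,
              x$counts$rows, x$counts$trunks, x$elapsed_s))
  invisible(x)
}

write_pipeline_outputs <- function(result, cloud) {
  dir.create(result$config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(result$config$output_dir, f)
  plant_rot <- NULL
  for (r in result$model$rows) {
    row_cloud <- pc_subset(result$separation$plant, r$plant_idx)
    write_point_cloud(row_cloud, out(sprintf("row_%02d_plant.xyz", r$id)),
                      format = "xyz")
  }
  data.table::fwrite(result$trunks, out("trunks.csv"))
  for (id in names(result$profiles))
    data.table::fwrite(result$profiles[[id]],
                       out(sprintf("row_%02d_profile.csv", as.integer(id))))
  rows_summary <- do.call(rbind, lapply(result$model$rows, function(r)
    data.frame(row_id = r$id, n_plant_points = length(r$plant_idx),
               n_ground_points = length(r$ground_idx),
               theta_deg = result$model$theta * 180 / pi,
               box_x_m = r$plant_box$max[1] - r$plant_box$min[1],
               box_y_m = r$plant_box$max[2] - r$plant_box$min[2],
               box_z_m = r$plant_box$max[3] - r$plant_box$min[3])))
  data.table::fwrite(rows_summary, out("rows_summary.csv"))
  cfg_json <- jsonlite::toJSON(unclass(result$config), auto_unbox = TRUE,
                               null = "null", digits = NA)
  writeLines(cfg_json, out("config.json"))
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = unname(tools::md5sum(out("config.json"))),
    counts = result$counts,
    outputs = list.files(result$config$output_dir))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             out("manifest.json"))
  invisible(NULL)
}

#' Render per-row diagnostic plots and a summary table
#'
#' For every row: the height and lower-bound curves along the row with
#' detected trunk positions overlaid, the width curve, the volume curve
#' and histograms of the three parameters; plus a summary CSV of per-row
#' means and standard deviations.
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory for PNGs and the summary CSV.
#' @return invisibly, the summary table.
#' @export
pipeline_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!length(result$profiles)) {
    writeLines("no rows", file.path(out_dir, "REPORT.txt"))
    return(invisible(NULL))
  }
  summaries <- list()
  for (id in names(result$profiles)) {
    prof <- result$profiles[[id]]
    mid <- (prof$y_start + prof$y_end) / 2
    dfl <- tibble::tibble(y = rep(mid, 2),
                          value = c(prof$height_m, prof$lower_bound_m),
                          what = rep(c("plant height", "canopy lower bound"),
                                     each = nrow(prof)))
    p1 <- ggplot2::ggplot(dfl, ggplot2::aes(x = y, y = value,
                                            colour = what)) +
      ggplot2::geom_line(na.rm = TRUE) +
      ggplot2::labs(x = "along-row position [m]", y = "height [m]",
                    colour = NULL,
                    title = sprintf("Row %s: height and lower bound", id))
    tr <- result$trunks[result$trunks$row_id == as.integer(id), ]
    if (nrow(tr)) {
      # trunk positions projected to the row axis (rotated-frame y)
      txy <- rotate_xy_mat(as.matrix(tr[, c("x", "y")]), result$model$theta,
                           result$model$pivot)
      p1 <- p1 + ggplot2::geom_point(
        data = tibble::tibble(y = txy[, 2], value = 0),
        ggplot2::aes(x = y, y = value), inherit.aes = FALSE,
        colour = "blue", size = 1.5)
    }
    ggplot2::ggsave(file.path(out_dir, sprintf("row_%s_height.png", id)),
                    p1, width = 8, height = 3, dpi = 110)
    for (col in c("width_m", "volume_m3")) {
      p <- ggplot2::ggplot(prof, ggplot2::aes(x = mid, y = .data[[col]])) +
        ggplot2::geom_line(na.rm = TRUE) +
        ggplot2::labs(x = "along-row position [m]", y = col,
                      title = sprintf("Row %s: %s", id, col))
      ggplot2::ggsave(file.path(out_dir, sprintf("row_%s_%s.png", id, col)),
                      p, width = 8, height = 3, dpi = 110)
    }
    hist_df <- tibble::tibble(
      value = c(prof$height_m, prof$width_m, prof$volume_m3),
      parameter = rep(c("height [m]", "width [m]", "volume [m3]"),
                      each = nrow(prof)))
    ph <- ggplot2::ggplot(hist_df, ggplot2::aes(x = value)) +
      ggplot2::geom_histogram(bins = 30, na.rm = TRUE) +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(title = sprintf("Row %s: parameter distributions", id))
    ggplot2::ggsave(file.path(out_dir, sprintf("row_%s_histograms.png", id)),
                    ph, width = 9, height = 3, dpi = 110)
    s <- attr(prof, "summary")
    s$row_id <- as.integer(id)
    summaries[[id]] <- s
  }
  summary_tbl <- do.call(rbind, summaries)
  data.table::fwrite(summary_tbl, file.path(out_dir, "row_parameters_summary.csv"))
  invisible(summary_tbl)
}
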