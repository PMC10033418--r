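#' Default pipeline configuration
#'
#' Nested list mirroring each stage's parameter set; every field has a
#' working default, so a fully-defaulted config is valid.  Unknown keys are
#' rejected with the offending path named.
#'
#' @return nested configuration list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    scene = list(grid_shape = c(64, 512, 512), voxel_size = c(50, 5, 5),
                 nucleus = list(semi_axes = c(700, 550, 550)),
                 n_mitochondria = 20L, fragmentation = "elongated",
                 placement = "dispersed", shell_width = 1000,
                 n_lipid_droplets = 5L,
                 mito = list(radius = 100, length_mean_um = 1.2,
                             length_sd_um = 0.4, curvature = 0.25,
                             step_nm = 100),
                 intensity = list(background = 0.8, nucleus = 0.45,
                                  mitochondria = 0.2, lipid_droplet = 0.9,
                                  noise_sd = 0.05)),
    classical = list(object = "dark", separate = FALSE, median_filter = TRUE),
    morphometry = list(length_method = "geodesic", connectivity = 26L),
    distance = list(mode = "surface"),
    contacts = list(ld_contact_max = 50, pnm_distance_max = 1000),
    motility = list(velocity_px_per_frame = 1, n_frames = 10L, dt_s = 20,
                    n_blobs = 6L, blob_radius = 3L, shape = c(64, 64)),
    net = list(encoder_filters = c(8, 16, 32, 64, 64),
               aspp_rates = c(6, 12, 18, 24), n_classes = 3,
               leaky_slope = 0.01, input_size = 64),
    train = list(epochs = 10L, batch_size = 8L, lr_initial = 1e-4,
                 lr_after = 1e-5, lr_step_epoch = 150L, augment = FALSE)
  ), class = "pipeline_config")
}

.check_keys <- function(user, defaults, path = "") {
  for (nm in names(user)) {
    here <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(defaults)) stop("unknown config key: ", here)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(user[[nm]]))
      .check_keys(user[[nm]], defaults[[nm]], here)
  }
  invisible(TRUE)
}

#' Build a pipeline configuration from a YAML file or list
#'
#' Values override the defaults of [default_config()]; unknown keys are an
#' error naming the offending path.  `pipeline_config()` with no argument
#' returns the defaults.
#'
#' @param x path to a YAML file, a named list of overrides, or `NULL`.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(x = NULL) {
  defaults <- default_config()
  if (is.null(x)) return(defaults)
  user <- if (is.character(x)) yaml::read_yaml(x) else x
  .check_keys(user, defaults)
  out <- utils::modifyList(defaults, user)
  class(out) <- "pipeline_config"
  out
}

#' Serialize a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path optional output path; otherwise the YAML string is returned.
#' @return the YAML string (invisibly when written to a file).
#' @export
config_to_yaml <- function(config, path = NULL) {
  s <- yaml::as.yaml(unclass(config))
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

.scene_from_config <- function(config) {
  sc <- config$scene
  scene_spec(grid_shape = sc$grid_shape, voxel_size = sc$voxel_size,
             nucleus = sc$nucleus,
             n_mitochondria = sc$n_mitochondria, mito = sc$mito,
             fragmentation = sc$fragmentation, placement = sc$placement,
             shell_width = sc$shell_width, n_lipid_droplets = sc$n_lipid_droplets,
             intensity = sc$intensity, seed = config$seed)
}

#' Run pipeline stages into an artifact directory
#'
#' Stages consume their upstream artifacts by documented filenames inside
#' `out_dir`; a missing upstream artifact is an error naming the stage to
#' run first.  A manifest (config echo, config hash, seed, package version,
#' accumulated warnings) is always written.  Rerunning with an identical
#' config reproduces identical tables.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of `simulate`, `instances`, `morph`,
#'   `distance`, `motility`, `compartments`, `phenotype`.
#' @param out_dir artifact directory (created if needed).
#' @param uptake optional data.frame of tracer measurements for the
#'   `phenotype` stage (defaults to a small demonstration table).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = character(),
                         out_dir = "mitoscape-artifacts", uptake = NULL) {
  known <- c("simulate", "instances", "morph", "distance", "motility",
             "compartments", "phenotype")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  notes <- character(0)
  p <- function(...) file.path(out_dir, ...)
  need <- function(path, producer) {
    if (!file.exists(path))
      stop(sprintf("missing upstream artifact %s: run stage '%s' first",
                   basename(path), producer))
    path
  }

  if ("simulate" %in% stages) {
    scene <- generate_cell_volume(.scene_from_config(config))
    write_volume(scene$grayscale, p("grayscale.tif"))
    write_volume(scene$truth$class_volume, p("class_volume.tif"))
    write_volume(scene$truth$instance_volume, p("instance_volume.tif"))
    write_table_csv(scene$truth$instance_table, p("instance_table.csv"),
                    "synthetic ground truth; volumes um^3, centroids um, radius nm")
  }
  if ("instances" %in% stages) {
    gray <- read_volume(need(p("grayscale.tif"), "simulate"))
    cl <- config$classical
    lab <- classical_instance_segmentation(gray, object = cl$object,
                                           separate = cl$separate,
                                           median_filter = cl$median_filter)
    write_volume(lab, p("instances_classical.tif"))
  }
  if ("morph" %in% stages) {
    inst <- read_volume(need(p("instance_volume.tif"), "simulate"))
    tab <- read_table_csv(need(p("instance_table.csv"), "simulate"))
    mito <- inst
    mito$data[!(inst$data %in% tab$instance_id[tab$class == 2L])] <- 0L
    rec <- measure_components(mito, length_method = config$morphometry$length_method)
    write_table_csv(rec, p("morphometry.csv"),
                    "per-mitochondrion morphometry; volume um^3, area um^2, length um")
  }
  if ("distance" %in% stages) {
    inst <- read_volume(need(p("instance_volume.tif"), "simulate"))
    cls <- read_volume(need(p("class_volume.tif"), "simulate"))
    tab <- read_table_csv(need(p("instance_table.csv"), "simulate"))
    mito <- inst
    mito$data[!(inst$data %in% tab$instance_id[tab$class == 2L])] <- 0L
    nuc <- cls
    nuc$data <- cls$data == 1L
    d <- mito_nucleus_distances_3d(mito, nuc, mode = config$distance$mode)
    write_table_csv(d, p("nucleus_distances.csv"), "distances in um")
  }
  if ("motility" %in% stages) {
    mo <- config$motility
    gen <- generate_motility_series(mask = list(shape = mo$shape,
                                                n_blobs = mo$n_blobs,
                                                blob_radius = mo$blob_radius),
                                    velocity_px_per_frame = mo$velocity_px_per_frame,
                                    n_frames = mo$n_frames, dt_s = mo$dt_s,
                                    seed = config$seed)
    res <- withCallingHandlers(
      motility_slope(displacement_ratios(gen$series)),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    write_table_csv(cbind(res$ratios,
                          slope = res$slope, intercept = res$intercept),
                    p("motility.csv"), "ratios dimensionless; slope s^-1")
  }
  if ("compartments" %in% stages) {
    inst <- read_volume(need(p("instance_volume.tif"), "simulate"))
    cls <- read_volume(need(p("class_volume.tif"), "simulate"))
    tab <- read_table_csv(need(p("instance_table.csv"), "simulate"))
    mito <- inst; mito$data[!(inst$data %in% tab$instance_id[tab$class == 2L])] <- 0L
    lds <- inst; lds$data[!(inst$data %in% tab$instance_id[tab$class == 3L])] <- 0L
    nuc <- cls; nuc$data <- cls$data == 1L
    params <- contact_params(ld_contact_max = config$contacts$ld_contact_max,
                             pnm_distance_max = config$contacts$pnm_distance_max)
    flags <- detect_contacts(mito, lds, nuc, params)
    cls_out <- classify_compartments(flags, params)
    write_table_csv(merge(flags, cls_out$labels, by = "instance_id"),
                    p("compartments.csv"), "distances nm")
    write_table_csv(data.frame(compartment = names(cls_out$percentages),
                               percent = as.numeric(cls_out$percentages)),
                    p("compartment_percentages.csv"))
    ldq <- quantify_lipid_droplets(lds)
    write_table_csv(ldq$droplets, p("lipid_droplets.csv"),
                    sprintf("count %d, total volume %.6g um^3",
                            ldq$count, ldq$total_volume_um3))
  }
  if ("phenotype" %in% stages) {
    if (is.null(uptake))
      uptake <- data.frame(tracer = c("FBnTP", "FBnTP", "FDG", "FDG"),
                           tumour_uptake = c(2.5, 1.2, 1.0, 0.5),
                           heart_uptake = c(4.0, 4.0, 4.0, 4.0))
    write_table_csv(classify_tracer_uptake(uptake), p("phenotypes.csv"),
                    "uptake as percentage injected dose per gram; ratio tumour/heart")
  }

  cfg_yaml <- config_to_yaml(config)
  cfg_path <- p("config.yaml")
  writeLines(cfg_yaml, cfg_path)
  manifest <- list(package = "mitoscape",
                   version = as.character(utils::packageVersion("mitoscape")),
                   stages = stages, seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   warnings = notes)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
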