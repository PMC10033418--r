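#' Contact and proximity parameters for compartment classification
#'
#' The subpopulations are defined by organelle interactions: peri-droplet
#' mitochondria (PDM) contact lipid droplets, perinuclear mitochondria (PNM)
#' localize to the nucleus, cytoplasmic mitochondria (CM) lack both
#' contacts.  The imaging work gives no numeric cutoffs, so the defaults use
#' conventional organelle contact-site scales: 50 nm surface-to-surface for
#' LD contact, 1 um for nucleus proximity.  Both are configurable and echoed
#' in the output.
#'
#' @param ld_contact_max nm; max surface distance counted as LD contact.
#' @param pnm_distance_max nm; max surface distance counted as perinuclear.
#' @param precedence order in which the labels are tested; must name PDM,
#'   PNM and CM exactly once.  The default resolves mitochondria with both
#'   contacts to PDM (the label defined by a specific physical contact).
#' @return object of class `contact_params`.
#' @export
contact_params <- function(ld_contact_max = 50, pnm_distance_max = 1000,
                           precedence = c("PDM", "PNM", "CM")) {
  if (ld_contact_max <= 0 || pnm_distance_max <= 0) stop("cutoffs must be > 0")
  if (!identical(sort(precedence), sort(c("PDM", "PNM", "CM"))))
    stop("precedence must contain PDM, PNM and CM exactly once")
  structure(list(ld_contact_max = ld_contact_max,
                 pnm_distance_max = pnm_distance_max,
                 precedence = precedence),
            class = "contact_params")
}

#' Detect nucleus proximity and lipid-droplet contact per mitochondrion
#'
#' Minimum surface-to-surface distances via anisotropy-aware Euclidean
#' distance transforms from the nucleus voxels and from the union of LD
#' voxels; a mitochondrion is `nucleus_near` if its minimum distance to the
#' nucleus is at most `pnm_distance_max`, and `ld_contact` if its minimum
#' distance to any LD is at most `ld_contact_max`.  With zero LDs all
#' `ld_contact` flags are `FALSE` (the LD-free squamous phenotype).
#'
#' @param mito_instances instance-labelled [volume_grid()] of mitochondria.
#' @param ld_instances instance-labelled [volume_grid()] of lipid droplets
#'   (may be empty).
#' @param nucleus_mask binary [volume_grid()]; must be nonempty.
#' @param params a [contact_params()].
#' @return data.frame: `instance_id`, `nucleus_distance_nm`,
#'   `ld_distance_nm`, `nucleus_near`, `ld_contact`.
#' @export
detect_contacts <- function(mito_instances, ld_instances, nucleus_mask,
                            params = contact_params()) {
  mito_instances <- as_volume_grid(mito_instances)
  ld_instances <- as_volume_grid(ld_instances, mito_instances)
  nucleus_mask <- as_volume_grid(nucleus_mask, mito_instances)
  stopifnot_aligned(mito_instances, nucleus_mask)
  stopifnot_aligned(mito_instances, ld_instances)
  if (!any(nucleus_mask$data > 0)) stop("missing (empty) nucleus mask")
  dm <- dim(mito_instances$data)
  vs <- mito_instances$voxel_size
  edt_nuc <- sqrt(edt_sq_cpp(as.logical(nucleus_mask$data > 0), dm, vs))
  has_ld <- any(ld_instances$data > 0)
  edt_ld <- if (has_ld) sqrt(edt_sq_cpp(as.logical(ld_instances$data > 0), dm, vs)) else NULL
  ids <- sort(unique(mito_instances$data[mito_instances$data > 0]))
  out <- lapply(ids, function(id) {
    w <- which(mito_instances$data == id)
    dn <- min(edt_nuc[w])
    dl <- if (has_ld) min(edt_ld[w]) else Inf
    data.frame(instance_id = as.integer(id), nucleus_distance_nm = dn,
               ld_distance_nm = dl,
               nucleus_near = dn <= params$pnm_distance_max,
               ld_contact = dl <= params$ld_contact_max)
  })
  do.call(rbind, out)
}

#' Classify mitochondria into PNM / PDM / CM subpopulations
#'
#' Labels by precedence (default PDM, then PNM, then CM): LD contact makes a
#' mitochondrion peri-droplet, otherwise nucleus proximity makes it
#' perinuclear, otherwise it is cytoplasmic.  Per-cell percentages over all
#' mitochondria sum to 100.
#'
#' @param flags data.frame from [detect_contacts()].
#' @param params a [contact_params()].
#' @return list with `labels` (data.frame `instance_id`, `compartment`) and
#'   `percentages` (named vector PNM/PDM/CM, summing to 100).
#' @export
classify_compartments <- function(flags, params = contact_params()) {
  lab <- vapply(seq_len(nrow(flags)), function(i) {
    for (p in params$precedence) {
      hit <- switch(p,
                    PDM = flags$ld_contact[i],
                    PNM = flags$nucleus_near[i],
                    CM = TRUE)
      if (hit) return(p)
    }
    "CM"
  }, character(1))
  n <- length(lab)
  pct <- vapply(c(PNM = "PNM", PDM = "PDM", CM = "CM"),
                function(p) 100 * sum(lab == p) / n, numeric(1))
  list(labels = data.frame(instance_id = flags$instance_id, compartment = lab),
       percentages = pct, params = params)
}

#' Quantify lipid droplets
#'
#' Per-droplet volume (exact, voxel count x voxel volume), centroid, count
#' and total volume; optionally the ids of contacting mitochondria (within
#' `params$ld_contact_max`).  A mitochondrion touching several droplets is
#' counted once per droplet listing but classified once.
#'
#' @param ld_instances instance-labelled [volume_grid()].
#' @param mito_instances optional mitochondrial instances for contact lists.
#' @param params a [contact_params()] (used only with `mito_instances`).
#' @return list with `droplets` (data.frame), `count`, `total_volume_um3`.
#' @export
quantify_lipid_droplets <- function(ld_instances, mito_instances = NULL,
                                    params = contact_params()) {
  ld_instances <- as_volume_grid(ld_instances)
  dm <- dim(ld_instances$data)
  vs <- ld_instances$voxel_size
  ids <- sort(unique(ld_instances$data[ld_instances$data > 0]))
  if (!length(ids)) {
    return(list(droplets = data.frame(instance_id = integer(0),
                                      voxel_count = integer(0),
                                      volume_um3 = numeric(0),
                                      contacting_mitochondria = character(0)),
                count = 0L, total_volume_um3 = 0))
  }
  vv <- voxel_volume_um3(vs)
  rows <- lapply(ids, function(id) {
    w <- which(ld_instances$data == id)
    contacts <- NA_character_
    if (!is.null(mito_instances)) {
      f <- array(FALSE, dm); f[w] <- TRUE
      edt <- sqrt(edt_sq_cpp(as.logical(f), dm, vs))
      near <- unique(mito_instances$data[mito_instances$data > 0 &
                                           edt <= params$ld_contact_max])
      contacts <- paste(sort(near), collapse = ";")
    }
    data.frame(instance_id = as.integer(id), voxel_count = length(w),
               volume_um3 = length(w) * vv,
               contacting_mitochondria = contacts,
               stringsAsFactors = FALSE)
  })
  droplets <- do.call(rbind, rows)
  list(droplets = droplets, count = nrow(droplets),
       total_volume_um3 = sum(droplets$volume_um3))
}

#' Classify PET tracer uptake as HI or LO
#'
#' Uptake is percentage of injected dose per gram, normalized to the heart
#' signal; the tumour-to-heart ratio is thresholded at 0.5 for the
#' membrane-potential tracer FBnTP and 0.2 for the glucose tracer FDG, both
#' boundaries inclusive for HI.
#'
#' @param measurements data.frame with columns `tracer` ("FBnTP" or "FDG"),
#'   `tumour_uptake`, `heart_uptake` (both `> 0`); or precomputed `ratio`.
#' @return the data.frame with `ratio` and `phenotype` ("HI"/"LO") columns.
#' @export
classify_tracer_uptake <- function(measurements) {
  m <- measurements
  if (!all(m$tracer %in% c("FBnTP", "FDG"))) stop("tracer must be FBnTP or FDG")
  if (is.null(m$ratio)) {
    if (any(m$tumour_uptake <= 0) || any(m$heart_uptake <= 0))
      stop("uptake values must be > 0")
    m$ratio <- m$tumour_uptake / m$heart_uptake
  } else if (any(m$ratio <= 0)) {
    stop("uptake ratios must be > 0")
  }
  thr <- c(FBnTP = 0.5, FDG = 0.2)
  m$phenotype <- ifelse(m$ratio >= thr[m$tracer], "HI", "LO")
  m
}

#' Normalize respiratory capacity to mitochondrial content
#'
#' Maximal respiratory capacity (oxygen consumption rate) divided by the
#' mitochondrial-content signal (MitoTracker Deep Red fluorescence), giving
#' OCR per fluorescence unit.
#'
#' @param ocr_value numeric OCR/MRC values.
#' @param mito_content_signal matching content signals, all `> 0`.
#' @return elementwise quotient.
#' @export
normalize_mrc <- function(ocr_value, mito_content_signal) {
  if (any(mito_content_signal <= 0)) stop("mitochondrial content signal must be > 0")
  ocr_value / mito_content_signal
}
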