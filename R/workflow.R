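#' Pipeline configuration
#'
#' Defaults mirror the clinical protocol: six respiratory phases, an
#' isotropic 3 mm set-up margin on the BITV, 5 mm radial / 10 mm
#' craniocaudal margins on the CTV, a 0.1 cc minimum lesion volume and a
#' 15 mm lesion-matching capture radius. The reference phase — the gated
#' phase matching the planning CT's respiratory phase, on which the
#' background threshold is measured — is explicit configuration.
#'
#' @param n_phases number of respiratory bins (default 6).
#' @param reference_phase index of the phase used for threshold estimation.
#' @param ptvg_margin_mm isotropic PTVg margin (default 3).
#' @param ptv_radial_mm,ptv_cc_mm anisotropic PTV margins (default 5, 10).
#' @param min_lesion_volume_cc smallest lesion kept (default 0.1).
#' @param capture_radius_mm lesion matching capture radius (default 15).
#' @param roi_volume_cc background ROI volume in cc, in [20, 30].
#' @param roi_seed seed for background ROI placement.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_phases = 6L, reference_phase = 1L,
                            ptvg_margin_mm = 3, ptv_radial_mm = 5,
                            ptv_cc_mm = 10, min_lesion_volume_cc = 0.1,
                            capture_radius_mm = 15, roi_volume_cc = 20,
                            roi_seed = 1L) {
  if (reference_phase < 1 || reference_phase > n_phases)
    stop("reference_phase must index one of the phases")
  structure(list(n_phases = as.integer(n_phases),
                 reference_phase = as.integer(reference_phase),
                 ptvg_margin_mm = ptvg_margin_mm,
                 ptv_radial_mm = ptv_radial_mm, ptv_cc_mm = ptv_cc_mm,
                 min_lesion_volume_cc = min_lesion_volume_cc,
                 capture_radius_mm = capture_radius_mm,
                 roi_volume_cc = roi_volume_cc,
                 roi_seed = as.integer(roi_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path path to a YAML file whose keys match the arguments of
#'   \code{\link{pipeline_config}}.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x[intersect(names(x),
    names(formals(pipeline_config)))])
}

# threshold via the background protocol; draws 2 extra ROIs on demand
protocol_threshold <- function(img, healthy_mask, config) {
  first3 <- sample_background_rois(img, healthy_mask,
                                   roi_volume_cc = config$roi_volume_cc,
                                   k = 3, seed = config$roi_seed)
  background_threshold(first3, more_provider = function(n) {
    five <- sample_background_rois(img, healthy_mask,
                                   roi_volume_cc = config$roi_volume_cc,
                                   k = 5, seed = config$roi_seed)
    utils::tail(five, n)
  })
}

#' Run the gated (4D) planning workflow
#'
#' Background threshold from the reference phase, per-phase BTV threshold
#' segmentation, cross-phase lesion matching, per-lesion BITV (union over
#' phases) and PTVg (isotropic set-up margin).
#'
#' @param series a \code{gated_series} (six phases on one grid).
#' @param healthy_liver_mask \code{binary_mask} of healthy liver for the
#'   background ROIs (lesions excluded).
#' @param config a \code{pipeline_config}.
#' @param tau optional fixed threshold overriding the background protocol.
#' @return List with \code{threshold} (a \code{background_estimate} or the
#'   fixed value), \code{correspondence}, \code{bitv} and \code{ptvg} (lists
#'   of \code{binary_mask} per lesion), and \code{records} (data frame:
#'   lesion, bitv_cc, ptvg_cc, n_phases_present).
#' @export
run_gated_workflow <- function(series, healthy_liver_mask, config = pipeline_config(),
                               tau = NULL) {
  stopifnot(inherits(series, "gated_series"),
            inherits(config, "pipeline_config"))
  if (length(series) != config$n_phases)
    stop(sprintf("series has %d phases but config expects %d",
                 length(series), config$n_phases))
  threshold <- tau
  if (is.null(tau)) {
    est <- protocol_threshold(series$phases[[config$reference_phase]],
                              healthy_liver_mask, config)
    threshold <- est$threshold
  } else est <- tau
  lesion_sets <- lapply(series$phases, function(ph)
    label_lesions(threshold_segment(ph, threshold),
                  min_volume_cc = config$min_lesion_volume_cc, img = ph))
  corr <- match_lesions(lesion_sets, capture_radius_mm = config$capture_radius_mm)
  n_lesion <- nrow(corr$phase_label)
  bitv <- vector("list", n_lesion)
  ptvg <- vector("list", n_lesion)
  records <- data.frame(lesion = integer(0), bitv_cc = numeric(0),
                        ptvg_cc = numeric(0), n_phases_present = integer(0))
  for (l in seq_len(n_lesion)) {
    bitv[[l]] <- build_bitv(corr, l)
    ptvg[[l]] <- make_ptvg(bitv[[l]], config$ptvg_margin_mm)
    records <- rbind(records, data.frame(
      lesion = l, bitv_cc = volume_cc(bitv[[l]]),
      ptvg_cc = volume_cc(ptvg[[l]]),
      n_phases_present = sum(!is.na(corr$phase_label[l, ]))))
  }
  list(threshold = est, correspondence = corr, bitv = bitv, ptvg = ptvg,
       records = records)
}

#' Run the conventional (non-gated) planning workflow
#'
#' Background threshold on the non-gated image, BTV segmentation, CTV, and
#' PTV by anisotropic margin expansion. The CTV is the supplied manual mask
#' when given (the faithful clinical path: a radiation oncologist edits the
#' BTV); otherwise it is automated as BTV clipped to the liver mask, a
#' stand-in for the manual exclusion of lung, bone and other organs at risk.
#'
#' @param img the non-gated \code{suv_image}.
#' @param liver_mask \code{binary_mask} of the whole liver (for CTV
#'   clipping).
#' @param healthy_liver_mask mask for background ROIs (default:
#'   \code{liver_mask}).
#' @param ctv_override optional list of \code{binary_mask} CTVs, one per
#'   lesion, bypassing the automated CTV.
#' @param config a \code{pipeline_config}.
#' @param tau optional fixed threshold overriding the background protocol.
#' @return List with \code{threshold}, \code{lesions} (a \code{lesion_set}),
#'   \code{btv}, \code{ctv}, \code{ptv} (lists per lesion) and
#'   \code{records} (data frame: lesion, btv_cc, ctv_cc, ptv_cc).
#' @export
run_nongated_workflow <- function(img, liver_mask,
                                  healthy_liver_mask = liver_mask,
                                  ctv_override = NULL,
                                  config = pipeline_config(), tau = NULL) {
  stopifnot(inherits(img, "suv_image"), inherits(config, "pipeline_config"))
  threshold <- tau
  if (is.null(tau)) {
    est <- protocol_threshold(img, healthy_liver_mask, config)
    threshold <- est$threshold
  } else est <- tau
  lesions <- label_lesions(threshold_segment(img, threshold),
                           min_volume_cc = config$min_lesion_volume_cc,
                           img = img)
  n_lesion <- if (is.null(ctv_override)) lesions$n else length(ctv_override)
  btv <- ctv <- ptv <- vector("list", n_lesion)
  records <- data.frame(lesion = integer(0), btv_cc = numeric(0),
                        ctv_cc = numeric(0), ptv_cc = numeric(0))
  for (l in seq_len(n_lesion)) {
    btv[[l]] <- if (l <= lesions$n)
      binary_mask(lesions$labels == l, lesions$geometry)
    else empty_mask(img$geometry)
    ctv[[l]] <- if (!is.null(ctv_override)) ctv_override[[l]]
    else mask_intersect(btv[[l]], liver_mask)
    ptv[[l]] <- make_ptv(ctv[[l]], config$ptv_radial_mm, config$ptv_cc_mm)
    records <- rbind(records, data.frame(
      lesion = l, btv_cc = volume_cc(btv[[l]]),
      ctv_cc = volume_cc(ctv[[l]]), ptv_cc = volume_cc(ptv[[l]])))
  }
  list(threshold = est, lesions = lesions, btv = btv, ctv = ctv, ptv = ptv,
       records = records)
}

#' Compare gated and non-gated planning volumes
#'
#' Joins the per-lesion records of the two workflows on lesion id and builds
#' the comparison table: per-lesion PTV/PTVg and BITV/BTV percentages, the
#' cohort summary row (means, SDs, ratio-of-means) and the paired exact
#' Wilcoxon tests. Volumes are reported in cc with one decimal and ratios as
#' integer percent, the precision of a clinical volume table.
#'
#' @param gated_records records from \code{\link{run_gated_workflow}}.
#' @param nongated_records records from \code{\link{run_nongated_workflow}};
#'   the two data frames must carry identical lesion ids.
#' @return List with \code{per_lesion} (rounded comparison table),
#'   \code{summary} (means, SDs, ratio-of-means), \code{tests} (Wilcoxon
#'   \code{ptv_vs_ptvg}, \code{bitv_vs_btv}) and \code{exceptions}
#'   (number of lesions with PTVg >= PTV).
#' @export
compare_report <- function(gated_records, nongated_records) {
  if (!setequal(gated_records$lesion, nongated_records$lesion) ||
      nrow(gated_records) != nrow(nongated_records))
    stop("gated and non-gated records must carry matching lesion ids")
  gated_records <- gated_records[order(gated_records$lesion), ]
  nongated_records <- nongated_records[order(nongated_records$lesion), ]
  rec <- data.frame(lesion = gated_records$lesion,
                    ptv_cc = nongated_records$ptv_cc,
                    ptvg_cc = gated_records$ptvg_cc,
                    bitv_cc = gated_records$bitv_cc,
                    btv_cc = nongated_records$btv_cc,
                    ctv_cc = nongated_records$ctv_cc)
  s <- summarize_volumes(rec)
  per_lesion <- s$per_row
  vols <- c("ptv_cc", "ptvg_cc", "bitv_cc", "btv_cc", "ctv_cc")
  per_lesion[vols] <- lapply(per_lesion[vols], round, digits = 1)
  per_lesion$ptv_ptvg_pct <- round(per_lesion$ptv_ptvg_pct)
  per_lesion$bitv_btv_pct <- round(per_lesion$bitv_btv_pct)
  list(per_lesion = per_lesion,
       summary = list(columns = s$columns,
                      ratio_of_means_pct = round(s$ratio_of_means)),
       tests = list(ptv_vs_ptvg = wilcoxon_exact(rec$ptv_cc, rec$ptvg_cc),
                    bitv_vs_btv = wilcoxon_exact(rec$bitv_cc, rec$btv_cc)),
       exceptions = count_exceptions(rec))
}

#' Write a comparison report to JSON (and optionally CSV)
#'
#' The JSON layout follows the schema shipped at
#' \code{inst/schema/report_schema.json}.
#'
#' @param report a report from \code{\link{compare_report}}.
#' @param json_path output JSON path.
#' @param csv_path optional path for the per-lesion CSV table.
#' @return \code{json_path}, invisibly.
#' @export
write_report <- function(report, json_path, csv_path = NULL) {
  out <- list(
    per_lesion = report$per_lesion,
    summary = list(
      columns = report$summary$columns,
      ratio_of_means_pct = as.list(report$summary$ratio_of_means_pct)),
    tests = lapply(report$tests, function(t)
      list(W = t$W, p = t$p, n_pairs = t$n_pairs, n_nonzero = t$n_nonzero,
           method = t$method, degenerate = t$degenerate)),
    exceptions = report$exceptions)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csv_path))
    utils::write.csv(report$per_lesion, csv_path, row.names = FALSE)
  invisible(json_path)
}
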