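#' Pipeline run configuration
#'
#' Validates and fills a configuration for [run_pipeline()]. Unknown keys
#' are rejected so that typos never silently fall back to defaults.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param synth a [synth_config()] describing the synthetic input tissue
#'   (the pipeline currently runs on synthetic tissues or a pre-built
#'   network supplied via `network`).
#' @param network optional pre-built `tissue_network` to analyse instead of
#'   generating one.
#' @param use_images render fluorescence stacks and quantify densities from
#'   images; when `FALSE`, the generator's per-junction densities are used
#'   directly.
#' @param ablate optional junction id to ablate (`NA` = pick the retained
#'   junction with the highest true tension; `NULL` = skip the stage).
#' @param bin_size conditional-correlation bin size.
#' @param n_null local-correlation permutations.
#' @param orientation_scheme passed to [classify_orientation()].
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, synth = synth_config(seed = seed),
                       network = NULL, use_images = FALSE, ablate = NULL,
                       bin_size = 10, n_null = 200,
                       orientation_scheme = list(vertical = c(60, 90),
                                                 transverse = c(0, 30))) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

.validate_run_config <- function(config) {
  known <- names(formals(run_config))
  extra <- setdiff(names(config), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  if (!inherits(config$synth, "synth_config")) stop("synth must be a synth_config")
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Chains the stages: generate (or accept) a tissue network, restrict to
#' three-fold interior cells, infer tensions, compute shear, quantify
#' channel densities (from rendered images or directly from the generator),
#' compute polarity profiles and the conditional/local correlations, and
#' optionally simulate an ablation. All outputs (CSV + JSON sidecars, the
#' resolved configuration, and a per-stage log with junction exclusion
#' accounting) are written under `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return list with the in-memory results (`network`, `tensions`, `shear`,
#'   `densities`, `polarity`, `correlations`, `ablation`), invisibly
#'   writing files as a side effect.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("jfrun")) {
  .validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  # stage: tissue
  if (is.null(config$network)) {
    gen <- generate_equilibrium_network(config$synth)
    net <- gen$network; truth <- gen$truth
    say("synth: %d cells, %d junctions", nrow(net$cells), nrow(net$junctions))
  } else {
    net <- config$network; truth <- NULL
    say("input network: %d cells, %d junctions", nrow(net$cells), nrow(net$junctions))
  }
  net <- restrict_threefold(net)
  say("restrict: %d/%d cells retained, %d/%d junctions retained",
      sum(net$cells$retained), nrow(net$cells),
      sum(net$junctions$retained), nrow(net$junctions))
  write_network(net, file.path(out_dir, "network.json"))

  # stage: inference
  tens <- infer_tensions(net)
  write_tensions(tens, file.path(out_dir, "tensions.csv"))
  say("infer: %d tensions, lambda = %s; excluded %d (%s)",
      nrow(tens$tensions), paste(format(tens$lambda, digits = 3), collapse = ","),
      nrow(tens$excluded),
      paste(names(table(tens$excluded$reason)), table(tens$excluded$reason),
            sep = ":", collapse = " "))

  # stage: shear
  shear <- compute_shear(net, tens)
  utils::write.csv(shear, file.path(out_dir, "shear.csv"), row.names = FALSE)
  say("shear: %d eligible of %d", sum(shear$eligible), nrow(shear))

  # stage: quantification
  if (!is.null(truth)) {
    dens <- assign_intensities(net, truth, config$synth)
    if (config$use_images) {
      imgs <- render_images(net, dens, config$synth, truth)
      rois <- extract_rois(net, labels = imgs$labels)
      proc <- lapply(imgs$stacks, function(st) preprocess_stack(st, bg_radius = 20))
      for (ch in names(proc)) {
        rd <- roi_density(proc[[ch]]$image, rois)$junctions
        dens[[ch]] <- rd$density[match(dens$junction_id, rd$junction_id)]
      }
      say("quantify: densities measured from rendered stacks")
    } else {
      say("quantify: generator densities used directly")
    }
    utils::write.csv(dens, file.path(out_dir, "densities.csv"), row.names = FALSE)

    keep <- is.finite(dens$ecadherin) & dens$ecadherin > 0 & is.finite(dens$vinculin)
    ratio <- dens$vinculin[keep] / dens$ecadherin[keep]
    pol <- list(
      myosin = polarity_profile(dens$myosin[keep], dens$angle[keep], "DV/AP"),
      ecadherin = polarity_profile(dens$ecadherin[keep], dens$angle[keep], "AP/DV"),
      vinc_ecad = polarity_profile(ratio, dens$angle[keep], "DV/AP"))
    jsonlite::write_json(
      lapply(pol, function(p) list(ald = as.list(p$ald), pcp = p$pcp,
                                   mode = p$mode)),
      file.path(out_dir, "polarity.json"), auto_unbox = TRUE, digits = NA)
    say("polarity: PCP myo %.3f (DV/AP), ecad %.3f (AP/DV), vinc/ecad %.3f",
        pol$myosin$pcp, pol$ecadherin$pcp, pol$vinc_ecad$pcp)

    # stage: correlations against inferred tension
    tt <- tens$tensions
    ti <- match(tt$junction_id, dens$junction_id)
    ok <- is.finite(dens$ecadherin[ti]) & dens$ecadherin[ti] > 0
    vr <- dens$vinculin[ti] / dens$ecadherin[ti]
    cc <- conditional_correlation(vr[ok], tt$tension[ok], tt$length[ok],
                                  bin_size = config$bin_size)
    lx <- stats::setNames(tt$tension, as.character(tt$junction_id))
    ly <- stats::setNames(vr, as.character(tt$junction_id))
    lc <- local_correlation(net, lx, ly, n_null = config$n_null,
                            seed = config$seed)
    utils::write.csv(cc$bins, file.path(out_dir, "conditional_correlation.csv"),
                     row.names = FALSE)
    utils::write.csv(lc$cells, file.path(out_dir, "local_correlation.csv"),
                     row.names = FALSE)
    say("correlate: conditional median %.3f (%d bins); local median %.3f (p=%.2e)",
        cc$median, nrow(cc$bins), lc$median, lc$p_greater)
  } else {
    dens <- NULL; pol <- NULL; cc <- NULL; lc <- NULL
  }

  # stage: ablation (optional)
  abl <- NULL
  if (!is.null(config$ablate) && !is.null(truth)) {
    j <- config$ablate
    if (is.na(j)) {
      cand <- net$junctions$id[net$junctions$retained]
      tv <- truth$tensions$tension[match(cand, truth$tensions$junction_id)]
      j <- cand[which.max(tv)]
    }
    abl <- simulate_ablation(net, truth, j, config$synth)
    utils::write.csv(abl$tracks, file.path(out_dir, "ablation_tracks.csv"),
                     row.names = FALSE)
    utils::write.csv(abl$densities, file.path(out_dir, "ablation_densities.csv"),
                     row.names = FALSE)
    say("ablate: junction %d, released tension %.3f, recoil %.3f",
        j, abl$released_tension, recoil_velocity(abl))
  }

  cfg_out <- config
  cfg_out$network <- NULL
  cfg_out$synth <- unclass(cfg_out$synth)
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(log, file.path(out_dir, "log.txt"))

  invisible(list(network = net, truth = truth, tensions = tens, shear = shear,
                 densities = dens, polarity = pol,
                 correlations = list(conditional = cc, local = lc),
                 ablation = abl, out_dir = out_dir, log = log))
}
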