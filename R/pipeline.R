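# Pipeline orchestration: config validation, staged execution, manifest.

pipeline_defaults <- function() {
  list(
    mode = "with_sock",
    spatial_ica = list(order_rule = "variance:0.995", seed = 1L,
                       n_restarts = 1L),
    sock = list(z_thr = 2.3, s_min = 5L, radial_cutoff = 0.25,
                tfn_cutoff = 0.08, seed = 1L,
                floors = as.list(sock_floors())),
    eica = list(window = c(-30, 30), n_components = 10L, n_runs = 10L,
                drift_order = 1L, seed = 1L, p = 0.05, correction = "none")
  )
}

parse_order_rule <- function(s) {
  if (inherits(s, "order_rule")) return(s)
  parts <- strsplit(as.character(s), ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("fixed", "variance")) {
    stop("order_rule must look like 'fixed:20' or 'variance:0.995'",
         call. = FALSE)
  }
  if (parts[1] == "fixed") order_fixed(as.integer(parts[2])) else
    order_variance(as.numeric(parts[2]))
}

merge_defaults <- function(cfg, defaults) {
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]]) && is.list(cfg[[k]])) {
      cfg[[k]] <- merge_defaults(cfg[[k]], defaults[[k]])
    }
  }
  cfg
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML config, fills defaults, and checks every invariant it can
#' without touching the imaging data: referenced paths exist, seeds are
#' integers, the peri-event window aligns to the TR grid, and the TFN cutoff
#' is below Nyquist.  All problems are reported together.
#'
#' @param path YAML file.
#' @return A validated config list (class `pipeline_config`); errors abort
#'   with the aggregated problem list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg <- merge_defaults(cfg, pipeline_defaults())
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  is_group <- !is.null(cfg$group)
  if (is.null(cfg$paths)) cfg$paths <- list()
  need <- function(key, where = cfg$paths) {
    val <- where[[key]]
    if (is.null(val)) {
      note(sprintf("missing required path key '%s'", key))
      return(invisible(NULL))
    }
    if (!file.exists(val)) note(sprintf("path for '%s' does not exist: %s",
                                        key, val))
    val
  }
  need("brain_mask")
  if (!is_group) {
    need("fmri")
    need("events")
  } else {
    subs <- cfg$group$subjects
    if (is.null(subs) || !length(subs)) {
      note("group mode requires group.subjects")
    } else {
      for (i in seq_along(subs)) {
        for (key in c("fmri", "events")) {
          v <- subs[[i]][[key]]
          if (is.null(v)) {
            note(sprintf("subject %d: missing key '%s'", i, key))
          } else if (!file.exists(v)) {
            note(sprintf("subject %d: path for '%s' does not exist: %s",
                         i, key, v))
          }
        }
      }
    }
  }
  if (!is.null(cfg$paths$csf_mask) && !file.exists(cfg$paths$csf_mask)) {
    note(sprintf("path for 'csf_mask' does not exist: %s",
                 cfg$paths$csf_mask))
  }
  if (is.null(cfg$paths$out_dir)) note("missing required path key 'out_dir'")

  if (!cfg$mode %in% c("with_sock", "without_sock")) {
    note("mode must be 'with_sock' or 'without_sock'")
  }
  for (sk in c("spatial_ica", "sock", "eica")) {
    sd_ <- cfg[[sk]]$seed
    if (!is.numeric(sd_) || sd_ != round(sd_)) {
      note(sprintf("%s.seed must be an integer", sk))
    }
  }
  rule <- tryCatch(parse_order_rule(cfg$spatial_ica$order_rule),
                   error = function(e) {
                     note(conditionMessage(e)); NULL
                   })
  tr <- cfg$tr
  if (!is.null(tr)) {
    if (tr <= 0) note("tr must be positive")
    w <- cfg$eica$window
    span <- w[2] - w[1]
    if (tr > 0 && abs(span / tr - round(span / tr)) > 1e-9) {
      note("bin grid must align to tr: eica.window width is not a multiple of tr")
    }
    if (tr > 0 && cfg$sock$tfn_cutoff >= 1 / (2 * tr)) {
      note(sprintf("sock.tfn_cutoff %g Hz is at or above Nyquist %g Hz",
                   cfg$sock$tfn_cutoff, 1 / (2 * tr)))
    }
  }
  if (length(errors)) {
    stop("invalid pipeline config:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg$spatial_ica$order_rule_parsed <- rule
  cfg$config_path <- normalizePath(path)
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, log_con, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.null(log_con)) {
    writeLines(sprintf("[%s] stage %-12s done in %.1f s",
                       format(Sys.time(), "%H:%M:%S"), name,
                       as.numeric(difftime(Sys.time(), t0, units = "secs"))),
               log_con)
  }
  out
}

#' Run the full denoise + event-related ICA pipeline
#'
#' Stages: spatial ICA decomposition, artifact classification, aggressive
#' regression filtering (skipped in `without_sock` mode), FIR design,
#' deconvolution, event-related ICA, mixture-model z-maps and thresholding.
#' Every intermediate artifact is written under `paths$out_dir` and a
#' manifest (versions, seeds, config hash, per-stage counts) is returned and
#' saved as `manifest.json`.  Group configs run the per-subject stages for
#' each subject, then a temporally concatenated group eICA.
#'
#' @param config a validated config from [validate_config], or a path to a
#'   YAML config.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "pipeline.log"), open = "at")
  on.exit(close(log_con))

  brain <- read_mask(config$paths$brain_mask, "brain")
  csf <- if (!is.null(config$paths$csf_mask)) {
    read_mask(config$paths$csf_mask, "csf", reference = brain)
  } else NULL
  edge <- make_edge_mask(brain, 1L)

  subjects <- if (is.null(config$group)) {
    list(list(fmri = config$paths$fmri, events = config$paths$events,
              flip = FALSE))
  } else config$group$subjects

  dialect <- config$paths$events_dialect %||% "plain"
  per_subject <- list()
  manifest_subjects <- list()
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    tag <- sprintf("sub%02d", si)
    sdir <- file.path(out_dir, tag)
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    vol <- run_stage(paste0(tag, ":read"), log_con, {
      read_volume4d(sub$fmri, tr = config$tr)
    })
    events <- read_events(sub$events, dialect = dialect)

    counts <- list()
    ica <- run_stage(paste0(tag, ":decompose"), log_con, {
      decompose(vol, brain,
                order_rule = config$spatial_ica$order_rule_parsed,
                seed = config$spatial_ica$seed,
                n_restarts = config$spatial_ica$n_restarts)
    })
    write_decomposition(ica, file.path(sdir, "ica"))
    feats <- run_stage(paste0(tag, ":features"), log_con, {
      sock_features(ica, edge = edge, csf = csf,
                    z_thr = config$sock$z_thr, s_min = config$sock$s_min,
                    radial_cutoff = config$sock$radial_cutoff,
                    tfn_cutoff = config$sock$tfn_cutoff)
    })
    cls <- run_stage(paste0(tag, ":classify"), log_con, {
      sock_classify(feats, floors = unlist(config$sock$floors),
                    seed = config$sock$seed)
    })
    write_classification(cls, feats, file.path(sdir, "sock"))
    counts$n_components <- ica$n_components
    counts$n_rejected <- length(cls$rejected)
    counts$rejected_fraction <- cls$rejected_fraction
    # the regression filter is the only stage skipped without SOCK
    if (config$mode == "with_sock") {
      den <- run_stage(paste0(tag, ":filter"), log_con, {
        regression_filter(vol, ica$time_courses, cls$rejected, mask = brain)
      })
      write_volume4d(den$volume, file.path(sdir, "denoised.nii"))
      vol_for_eica <- den$volume
    } else {
      vol_for_eica <- vol
    }

    design <- run_stage(paste0(tag, ":fir"), log_con, {
      build_fir_design(events, vol_for_eica$n_volumes, vol_for_eica$tr,
                       window = config$eica$window,
                       drift_order = config$eica$drift_order)
    })
    per <- run_stage(paste0(tag, ":deconvolve"), log_con, {
      deconvolve(vol_for_eica, design, brain)
    })
    write_peri_event_response(per, file.path(sdir, "responses"))
    counts$events_used <- design$events_used
    per_subject[[si]] <- list(per = per, flip = isTRUE(sub$flip),
                              counts = counts)
    manifest_subjects[[tag]] <- counts
  }

  if (length(per_subject) == 1L && is.null(config$group)) {
    eica_in <- per_subject[[1]]$per
  } else {
    eica_in <- run_stage("group_stack", log_con, {
      group_stack(lapply(per_subject, `[[`, "per"),
                  vapply(per_subject, `[[`, logical(1), "flip"))
    })
  }
  res <- run_stage("eica", log_con, {
    eica_decompose(eica_in, n_components = config$eica$n_components,
                   seed = config$eica$seed, n_runs = config$eica$n_runs)
  })
  write_eica_result(res, file.path(out_dir, "eica"))
  thr <- t(apply(res$z_maps, 1L, threshold_zmap, p = config$eica$p,
                 correction = config$eica$correction))
  utils::write.table(
    data.frame(component = seq_len(res$n_components),
               n_voxels_surviving = rowSums(thr != 0),
               stability = res$stability_index),
    file.path(out_dir, "eica", "thresholded_counts.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)

  manifest <- list(
    package = "sockeica",
    version = as.character(utils::packageVersion("sockeica")),
    config_hash = unname(tools::md5sum(config$config_path)),
    mode = config$mode,
    seeds = list(spatial_ica = config$spatial_ica$seed,
                 sock = config$sock$seed, eica = config$eica$seed),
    subjects = manifest_subjects,
    n_eica_components = res$n_components,
    stability_index = res$stability_index
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
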