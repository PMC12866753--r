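# End-to-end pipeline orchestration: run enabled stages in dependency order
# from one config, write artifacts and a JSON run manifest.

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param session named list of [session_config()] overrides (`n_neurons`
#'   required).
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "physio", "score", "spindles", "responses", "rsa",
#'   "subspace", "decode", "gating", "event_power")`.
#' @param rsa_n_splits,decode_k,gating_n_boot stage parameters.
#' @return `sg_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, session = list(),
                            stages = c("simulate", "physio", "score",
                                       "spindles", "responses", "rsa",
                                       "subspace", "decode", "gating"),
                            rsa_n_splits = 20, decode_k = 5,
                            gating_n_boot = 1000) {
  known <- c("simulate", "physio", "score", "spindles", "responses", "rsa",
             "subspace", "decode", "gating", "event_power")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  deps <- list(physio = "simulate", score = "physio", spindles = "score",
               responses = "simulate", rsa = "responses",
               subspace = "simulate", decode = "responses",
               gating = "responses", event_power = c("gating", "spindles"))
  for (st in stages) {
    need <- deps[[st]]
    if (length(need) && !all(need %in% stages))
      stop("stage '", st, "' requires stage(s): ",
           paste(setdiff(need, stages), collapse = ", "))
  }
  structure(list(out_dir = out_dir, seed = seed, session = session,
                 stages = stages, rsa_n_splits = rsa_n_splits,
                 decode_k = decode_k, gating_n_boot = gating_n_boot),
            class = "sg_pipeline_config")
}

#' Run the pipeline
#'
#' Executes enabled stages in dependency order on a synthetic session, writes
#' all artifacts under `config$out_dir` plus a `manifest.json` with
#' parameters, seeds, QC counters and md5 digests of every artifact.
#' Identical config + seed produce identical digests.
#'
#' @param config [pipeline_config()].
#' @return manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sg_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(name) file.path(config$out_dir, name)
  qc <- list()
  stages <- config$stages

  scfg <- do.call(session_config,
                  c(config$session, list(seed = config$seed)))
  session <- NULL; physio <- NULL; scored <- NULL; resp <- NULL
  labels <- NULL; spindles <- NULL

  if ("simulate" %in% stages) {
    session <- generate_session(scfg)
    write_raster(session$raster, art("raster.f32"))
    write_trial_table(session$trials, art("trials.csv"))
  }
  if ("physio" %in% stages) {
    physio <- generate_physio(scfg, session$truth)
    for (ch in names(physio$channels))
      write_trace(physio$channels[[ch]], art(paste0(ch, ".f32")),
                  physio$rate, ch)
  }
  if ("score" %in% stages) {
    scored <- score_session(physio)
    write_hypnogram(scored$hypnogram, art("hypnogram.csv"))
    qc$separation_ok <- scored$separation_ok
  }
  if ("spindles" %in% stages) {
    spindles <- detect_spindles(physio$channels$aucx, physio$rate,
                                scored$hypnogram)
    write_spindles(spindles, art("spindles.csv"))
    qc$n_spindles <- nrow(spindles)
  }
  if ("responses" %in% stages) {
    resp <- extract_responses(session$raster, session$trials)
    qc$dropped_trials <- length(resp$dropped)
    summ <- tuning_summary(resp, states = intersect(
      c("wake", "nrem"), unique(resp$trials$state)))
    write.csv(summ$per_sound, art("per_sound_summary.csv"),
              row.names = FALSE)
    qc$state_ratio <- summ$state_ratio
  }
  if ("rsa" %in% stages) {
    states <- intersect(c("wake", "nrem"), unique(resp$trials$state))
    rsa <- rsa_summary(resp, states, n_splits = config$rsa_n_splits,
                       seed = config$seed)
    write.csv(rsa$similarity, art("rsa_matrix.csv"))
    qc$rsa_unreliable <- rsa$qc
    qc$rsa_diag_mean <- rsa$diag_mean
  }
  if ("subspace" %in% stages) {
    st <- scfg$states[1]
    act <- session_activity_matrices(session, st)
    inc <- inclusion_index(act$spont, act$evoked, seed = config$seed)
    jsonlite::write_json(inc, art("inclusion.json"), auto_unbox = TRUE,
                         digits = NA)
    qc$inclusion_index <- inc$index
  }
  if ("decode" %in% stages) {
    st <- scfg$states[1]
    folds <- prepare_balanced_folds(resp, st, k = config$decode_k,
                                    seed = config$seed)
    dec <- decode(folds, resp, seed = config$seed)
    write.csv(dec$confusion, art("confusion.csv"))
    jsonlite::write_json(list(accuracy = dec$accuracy,
                              per_fold = dec$per_fold),
                         art("decoding.json"), digits = NA)
    qc$decoding_accuracy <- dec$accuracy
  }
  if ("gating" %in% stages) {
    templates <- build_templates(resp,
                                 states = intersect(c("wake", "nrem"),
                                                    unique(resp$trials$state)))
    labels <- label_trials(resp, templates, n_boot = config$gating_n_boot,
                           seed = config$seed,
                           states = intersect(c("wake", "nrem"),
                                              unique(resp$trials$state)))
    write.csv(labels, art("gating_labels.csv"), row.names = FALSE)
    qc$fraction_nonresponsive <- as.list(
      gating_summary(labels, resp, templates,
                     seed = config$seed)$fraction_nonresponsive)
  }
  if ("event_power" %in% stages) {
    erp <- event_related_power(physio, resp$trials, labels, c(10, 15),
                               spindles = spindles)
    jsonlite::write_json(list(sigma_contrast = erp$contrast,
                              spindle_prob = erp$spindle_prob),
                         art("event_power.json"), digits = NA)
    qc$sigma_contrast <- erp$contrast
  }

  files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                   art("manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("sleepgeom")),
    seed = config$seed, stages = stages,
    parameters = config$session, qc = qc,
    artifacts = as.list(tools::md5sum(sort(files))))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
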