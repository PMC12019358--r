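#' Run the full switching pipeline on a synthetic cohort
#'
#' Orchestrates simulate, cohort filtering, switch detection, note
#' extraction, evaluation, topic modeling and subgroup enrichment as one
#' reproducible run. Each stage's artifact is written to `out_dir` as soon
#' as it is produced, so a failing stage leaves the earlier outputs on disk
#' and aborts with the stage name. Reruns with the same configuration are
#' identical: every stochastic stage is driven by `config$seed`.
#'
#' Artifacts written: `attrition.json`, `demographics_comparison.json`,
#' `switch_matrix.csv`, `eval_report.json`, `topic_assignments.csv`,
#' `topic_terms.json`, `enrichment_<axis>.csv`, `manifest.json`.
#'
#' @param config A [sim_config()]; the synthetic cohort is generated from
#'   it.
#' @param out_dir Output directory, created if needed; `NULL` skips all
#'   writing.
#' @param extractor Extraction function with the signature of
#'   [extract_switch_info()] (`text, note_id, patterns`).
#' @param patterns Modality pattern table.
#' @param min_cluster_size Topic-stage minimum cluster size.
#' @param axes Enrichment stratification axes.
#' @param followup_anchor Passed to [apply_filters()].
#' @return A list with every stage's in-memory result: `sim`, `filtered`,
#'   `switches`, `switch_matrix`, `demographics`, `extractions`, `silver`,
#'   `eval_report`, `topics`, `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         extractor = extract_switch_info,
                         patterns = read_pattern_table(),
                         min_cluster_size = 10L,
                         axes = c("race_ethnicity", "age"),
                         followup_anchor = "last") {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  emit <- function(obj, file, writer = NULL) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, file)
    if (is.null(writer)) {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    } else writer(obj, path)
    invisible(path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", generate_cohort(config))

  filtered <- stage("cohort", apply_filters(
    sim$orders, sim$notes, patterns = patterns,
    followup_anchor = followup_anchor,
    token_threshold = config$note_token_threshold))
  emit(filtered$attrition, "attrition.json")

  switches <- stage("switches", detect_switches(filtered$orders))
  sw_mat <- switch_matrix(switches)
  emit(as.data.frame(sw_mat), "switch_matrix.csv",
       function(o, p) utils::write.csv(sw_mat, p))

  dem <- sim$demographics
  sw_pat <- unique(switches$patient_id)
  cohort_pat <- unique(filtered$orders$patient_id)
  demcmp <- stage("demographics", {
    a <- dem[dem$patient_id %in% sw_pat, , drop = FALSE]
    b <- dem[dem$patient_id %in% setdiff(cohort_pat, sw_pat), , drop = FALSE]
    if (nrow(a) && nrow(b)) demographic_comparison(a, b) else NULL
  })
  emit(demcmp, "demographics_comparison.json")

  extractions <- stage("extract", extractor(
    sim$notes$text, note_id = sim$notes$note_id, patterns = patterns))
  silver <- stage("silver", derive_silver_labels(switches))

  eval_report <- stage("evaluate", {
    idx <- match(sim$gold$note_id, extractions$note_id)
    gold_ann <- data.frame(note_id = sim$gold$note_id,
                           gold_stopped = sim$gold$true_stopped,
                           gold_started = sim$gold$true_started,
                           stringsAsFactors = FALSE)
    rep <- human_eval_report(extractions, gold_ann)
    sidx <- match(silver$note_id, extractions$note_id)
    gsil <- match(silver$note_id, sim$gold$note_id)
    rep$kappa_silver_vs_gold <- list(
      started = cohens_kappa(sim$gold$true_started[gsil],
                             silver$started),
      stopped = cohens_kappa(sim$gold$true_stopped[gsil],
                             silver$stopped),
      started_relevant = cohens_kappa(sim$gold$true_started[gsil],
                                      silver$started,
                                      restrict_to_relevant = TRUE),
      stopped_relevant = cohens_kappa(sim$gold$true_stopped[gsil],
                                      silver$stopped,
                                      restrict_to_relevant = TRUE))
    rep
  })
  emit(eval_report, "eval_report.json")

  # topic-model the reasons extracted from switch-event notes
  topics <- stage("topics", {
    ev_notes <- switches$note_id[!is.na(switches$note_id)]
    reasons <- extractions$reason[match(ev_notes, extractions$note_id)]
    if (sum(!is.na(reasons)) >= 10L) {
      tm <- topic_model(reasons, min_cluster_size = min_cluster_size)
      list(model = tm, note_ids = ev_notes)
    } else NULL
  })
  if (!is.null(topics) && !is.null(out_dir)) {
    qa <- data.frame(note_id = topics$note_ids,
                     assignment = topics$model$assignments,
                     topics$model$q, check.names = FALSE)
    utils::write.csv(qa, file.path(out_dir, "topic_assignments.csv"),
                     row.names = FALSE)
    emit(topics$model$topic_terms, "topic_terms.json")
  }

  enrichment <- stage("enrich", {
    if (is.null(topics)) NULL else {
      pats <- sim$notes$patient_id[match(topics$note_ids,
                                         sim$notes$note_id)]
      out <- list()
      for (ax in axes) {
        y <- stratify(pats, dem, ax)
        out[[ax]] <- enrichment_scores(topics$model, y)
        if (!is.null(out_dir)) {
          utils::write.csv(out[[ax]]$theta_log,
                           file.path(out_dir,
                                     paste0("enrichment_", ax, ".csv")))
        }
      }
      out
    }
  })

  manifest <- list(
    package = "switchscope",
    version = as.character(utils::packageVersion("switchscope")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = config_hash(config),
    followup_anchor = followup_anchor,
    axes = axes,
    n_patients = config$n_patients)
  emit(manifest, "manifest.json")

  list(sim = sim, filtered = filtered, switches = switches,
       switch_matrix = sw_mat, demographics = demcmp,
       extractions = extractions, silver = silver,
       eval_report = eval_report, topics = topics,
       enrichment = enrichment, manifest = manifest)
}

#' Hash a configuration
#'
#' Deterministic md5 fingerprint of a configuration object (via its YAML
#' serialization); any field change changes the hash.
#'
#' @param config Any serializable list.
#' @return A 32-character hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}
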