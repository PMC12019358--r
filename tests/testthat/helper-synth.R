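# shared fixtures and small oracles used across test files

# brute-force switch oracle: compare every consecutive pair of encounter
# modality sets, independent of the implementation's grouping/sorting
brute_force_switches <- function(timeline) {
  # timeline: list of (date, modality character vector), sorted by date
  out <- list()
  for (j in seq_len(length(timeline) - 1)) {
    prev <- sort(unique(timeline[[j]]$modalities))
    cur <- sort(unique(timeline[[j + 1]]$modalities))
    if (!setequal(prev, cur)) {
      out[[length(out) + 1]] <- list(
        prev_date = timeline[[j]]$date, new_date = timeline[[j + 1]]$date,
        stopped = setdiff(prev, cur), started = setdiff(cur, prev))
    }
  }
  out
}

random_timeline <- function(n_enc, seed = NULL) {
  mods <- modality_levels()
  lapply(seq_len(n_enc), function(j) {
    list(date = j * 30L,
         modalities = sample(mods, sample(1:2, 1), replace = FALSE))
  })
}

timeline_to_orders <- function(timeline, patient = "P1") {
  do.call(rbind, lapply(timeline, function(e) {
    data.frame(patient_id = patient, encounter_date = e$date,
               start_date = e$date, modality = e$modalities,
               stringsAsFactors = FALSE)
  }))
}

# fraction of truly co-topical pairs that the model keeps together in a
# non-noise cluster
pairwise_co_membership <- function(truth, pred) {
  pr <- outer(pred, pred, "==") & pred != "0"
  tr <- outer(truth, truth, "==")
  ut <- upper.tri(tr)
  sum(pr[ut] & tr[ut]) / sum(tr[ut])
}

switcher_config <- function(n_patients, seed, topics = default_reason_topics(),
                            plan = NULL, ...) {
  sim_config(n_patients = n_patients, switch_probability = 1,
             encounters_range = c(2L, 2L), reason_topic_catalog = topics,
             subgroup_enrichment_plan = plan, seed = seed, ...)
}
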