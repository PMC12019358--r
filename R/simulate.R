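#' Default reason-topic catalog
#'
#' Six switching-rationale topics with deliberately distinct phrase
#' vocabularies, covering the themes recurrent in contraceptive care:
#' irregular bleeding, patient preference, daily-pill adherence, weight and
#' mood changes, insurance coverage, and device discomfort. Each entry has a
#' `topic` name, a `phrases` pool and an `adverse_event` flag.
#'
#' @return A list of topic entries.
#' @export
default_reason_topics <- function() {
  # each pool shares a core vocabulary (as real topic clusters do) that is
  # disjoint from every other pool's core, so the planted clusters are
  # recoverable from a term-frequency embedding
  list(
    list(topic = "irregular bleeding", adverse_event = TRUE,
         phrases = c("bothersome spotting and irregular bleeding",
                     "breakthrough spotting with irregular bleeding",
                     "heavy irregular bleeding and spotting",
                     "irregular bleeding spotting between menses")),
    list(topic = "patient preference", adverse_event = FALSE,
         phrases = c("prefers different contraceptive method overall",
                     "prefers more convenient contraceptive method",
                     "prefers trying different contraceptive method",
                     "prefers simpler contraceptive method instead")),
    list(topic = "adherence", adverse_event = FALSE,
         phrases = c("keeps forgetting daily doses",
                     "forgetting daily doses despite alarms",
                     "missed doses forgetting daily schedule",
                     "forgetting daily doses most mornings")),
    list(topic = "weight and mood", adverse_event = TRUE,
         phrases = c("weight gain and low mood",
                     "mood swings with weight gain",
                     "weight gain plus depressed mood",
                     "steady weight gain worsening mood")),
    list(topic = "insurance coverage", adverse_event = FALSE,
         phrases = c("insurance coverage ended for product",
                     "insurance denied coverage at pharmacy",
                     "insurance prior authorization coverage refused",
                     "lapsed insurance coverage since January")),
    list(topic = "device discomfort", adverse_event = TRUE,
         phrases = c("cramping since device malpositioned",
                     "device cramping on examination",
                     "cramping near device strings",
                     "ongoing cramping since device insertion"))
  )
}

# order-sheet drug name and the shorter mention used inside note text,
# per modality; Camila/Heather are the person-name-like brands eligible for
# deidentification-style redaction
.drug_catalog <- function() {
  list(
    Oral = data.frame(
      order_name = c("norethindrone 0.35 mg oral tablet",
                     "Camila 0.35 mg oral tablet",
                     "Heather 0.35 mg oral tablet",
                     "norgestimate-ethinyl estradiol oral tablet"),
      mention = c("norethindrone", "Camila", "Heather",
                  "norgestimate-ethinyl estradiol"),
      stringsAsFactors = FALSE),
    Implant = data.frame(
      order_name = "etonogestrel 68 mg subdermal implant",
      mention = "Nexplanon", stringsAsFactors = FALSE),
    IUD = data.frame(
      order_name = c("levonorgestrel 52 mg intrauterine device",
                     "copper T380A intrauterine device"),
      mention = c("Mirena", "the copper IUD"), stringsAsFactors = FALSE),
    Injectable = data.frame(
      order_name = "medroxyprogesterone 150 mg/mL intramuscular injection",
      mention = "Depo-Provera", stringsAsFactors = FALSE),
    Transdermal = data.frame(
      order_name = "norelgestromin-ethinyl estradiol transdermal patch",
      mention = "Xulane", stringsAsFactors = FALSE),
    Intravaginal = data.frame(
      order_name = "etonogestrel-ethinyl estradiol vaginal ring",
      mention = "NuvaRing", stringsAsFactors = FALSE)
  )
}

.redactable_brands <- function() c("Camila", "Heather")

# neutral clinical filler; must stay free of extractor cue words
# (start/stop/because/due/report/placed/begin/switch/discontinu/came off)
.filler_sentences <- function() {
  c("Vitals were reviewed and are within normal limits for age.",
    "No acute complaints at this visit and the remainder of the exam is unremarkable.",
    "Allergies and the current medication list were reconciled in the chart.",
    "She denies fever, chills, chest pain, shortness of breath, or urinary symptoms.",
    "Counseling was provided on routine health maintenance and safety.",
    "Follow up was arranged with the clinic in three months or sooner as needed.",
    "Immunizations are current and screening labs were reviewed together.",
    "Patient verbalized understanding of the plan and all questions were answered.")
}

#' Synthetic-cohort configuration
#'
#' Assembles and validates the configuration for [generate_cohort()]. The
#' defaults emulate the observed study conditions: a 7.6% patient-level
#' switching rate, a first-prescription modality mix dominated by oral
#' contraceptives, and all documentation-noise rates at zero.
#'
#' @param n_patients Number of patients to simulate.
#' @param switch_probability Probability that a patient experiences one
#'   contraceptive switch during follow-up.
#' @param modality_start_distribution Named probability vector over the six
#'   modalities for the first prescribed contraceptive; must sum to 1.
#' @param reason_topic_catalog Topic catalog as from
#'   [default_reason_topics()].
#' @param subgroup_enrichment_plan Data frame with columns `topic`,
#'   `subgroup`, `factor` giving multiplicative prevalence factors (>= 0) for
#'   a topic within a race/ethnicity category or age bin; `NULL` or
#'   zero rows means no planted enrichment.
#' @param noise_rates Named list of fractions in `[0, 1]`:
#'   `missing_start`, `missing_note`, `duplicate`, `short_note`,
#'   `lost_followup`, `redact_brand`, `non_contraceptive`, `emergency`.
#'   Unnamed entries default to 0.
#' @param encounters_range Integer range (min, max) of contraceptive
#'   encounters per patient.
#' @param gap_days Named list `mean`, `sd`, `min` for the normal
#'   inter-encounter gap distribution in days (the time-to-switch
#'   distribution is deliberately configurable rather than fixed).
#' @param note_token_threshold Whitespace-token count above which a note is
#'   considered informative (the short-note filter boundary).
#' @param seed Integer RNG seed; all generation is deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 300,
                       switch_probability = 0.076,
                       modality_start_distribution = NULL,
                       reason_topic_catalog = default_reason_topics(),
                       subgroup_enrichment_plan = NULL,
                       noise_rates = list(),
                       encounters_range = c(2L, 5L),
                       gap_days = list(mean = 180, sd = 60, min = 30),
                       note_token_threshold = 50L,
                       seed = 1L) {
  if (is.null(modality_start_distribution)) {
    modality_start_distribution <- c(
      Oral = 0.660, Implant = 0.050, IUD = 0.080,
      Injectable = 0.054, Transdermal = 0.035, Intravaginal = 0.122)
    modality_start_distribution <-
      modality_start_distribution / sum(modality_start_distribution)
  }
  noise_default <- list(missing_start = 0, missing_note = 0, duplicate = 0,
                        short_note = 0, lost_followup = 0, redact_brand = 0,
                        non_contraceptive = 0, emergency = 0)
  bad <- setdiff(names(noise_rates), names(noise_default))
  if (length(bad)) stop("unknown noise rates: ", paste(bad, collapse = ", "))
  noise_default[names(noise_rates)] <- noise_rates
  cfg <- list(n_patients = as.integer(n_patients),
              switch_probability = switch_probability,
              modality_start_distribution = modality_start_distribution,
              reason_topic_catalog = reason_topic_catalog,
              subgroup_enrichment_plan = subgroup_enrichment_plan,
              noise_rates = noise_default,
              encounters_range = as.integer(encounters_range),
              gap_days = gap_days,
              note_token_threshold = as.integer(note_token_threshold),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_patients < 1L) stop("n_patients must be positive")
  p <- cfg$modality_start_distribution
  if (!setequal(names(p), modality_levels())) {
    stop("modality_start_distribution must name exactly the six modalities")
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("modality_start_distribution must be non-negative and sum to 1")
  }
  fracs <- c(switch = cfg$switch_probability, unlist(cfg$noise_rates))
  if (any(fracs < 0 | fracs > 1)) {
    stop("switch_probability and all noise rates must lie in [0, 1]")
  }
  for (tp in cfg$reason_topic_catalog) {
    if (!length(tp$phrases)) stop("topic '", tp$topic, "' has an empty phrase pool")
  }
  plan <- cfg$subgroup_enrichment_plan
  if (!is.null(plan) && nrow(plan)) {
    stopifnot(all(c("topic", "subgroup", "factor") %in% names(plan)))
    if (any(plan$factor < 0)) stop("enrichment factors must be >= 0")
    known <- vapply(cfg$reason_topic_catalog, `[[`, "", "topic")
    miss <- setdiff(plan$topic, known)
    if (length(miss)) stop("enrichment plan names unknown topics: ",
                           paste(miss, collapse = ", "))
  }
  invisible(cfg)
}

#' Compose a synthetic clinical note
#'
#' Builds one note around an optional switch event (a stopped mention, a
#' started mention, a reason clause) and pads it with neutral clinical filler
#' until it exceeds the informative-note token threshold. Pure function: the
#' same arguments always return the same text.
#'
#' @param stopped_mention,started_mention In-note drug mentions for the
#'   stopped and started product, or `NULL` for a non-switch note. At most
#'   one of each is supported.
#' @param reason Reason clause inserted after the causal cue, or `NULL`.
#' @param current_mention Drug mention for a routine continuation note.
#' @param short_note If `TRUE`, return an uninformative note of at most
#'   `token_threshold` whitespace tokens instead.
#' @param redact If `TRUE`, person-name-like brand tokens (e.g. "Camila",
#'   "Heather") are replaced by the placeholder `[REDACTED]`, emulating
#'   over-eager deidentification.
#' @param token_threshold Whitespace-token threshold the note must exceed.
#' @return A single character string.
#' @export
generate_note <- function(stopped_mention = NULL, started_mention = NULL,
                          reason = NULL, current_mention = NULL,
                          short_note = FALSE, redact = FALSE,
                          token_threshold = 50L) {
  if (length(stopped_mention) > 1L || length(started_mention) > 1L) {
    stop("at most one stopped and one started mention per note")
  }
  if (short_note) {
    txt <- "Brief visit. Refill provided. No concerns voiced today."
  } else {
    body <- character(0)
    if (!is.null(stopped_mention) || !is.null(started_mention)) {
      body <- c(body, "Contraception review visit.")
      if (!is.null(stopped_mention)) {
        s <- paste0("She stopped ", stopped_mention, " at this visit")
        if (!is.null(reason)) s <- paste0(s, " because ", reason)
        body <- c(body, paste0(s, "."))
      }
      if (!is.null(started_mention)) {
        body <- c(body,
                  paste0("After counseling on the available options she is starting ",
                         started_mention, " today."))
      }
    } else if (!is.null(current_mention)) {
      body <- c(body, "Routine follow-up visit.",
                paste0("She continues ", current_mention,
                       " without new concerns."))
    } else {
      body <- c(body, "Annual wellness visit.")
    }
    filler <- .filler_sentences()
    txt <- paste(body, collapse = " ")
    i <- 0L
    while (length(strsplit(txt, "\\s+")[[1]]) <= token_threshold + 5L) {
      txt <- paste(txt, filler[(i %% length(filler)) + 1L])
      i <- i + 1L
    }
  }
  if (redact) {
    for (b in .redactable_brands()) {
      txt <- gsub(paste0("\\b", b, "\\b"), "[REDACTED]", txt)
    }
  }
  txt
}

.age_bin <- function(age) {
  ifelse(age < 21, "<21",
         ifelse(age <= 30, "21-30",
                ifelse(age <= 40, "31-40", "40+")))
}

#' Generate a synthetic EHR cohort
#'
#' Simulates a medication-order table, a demographics table, a clinical-note
#' table and per-note gold labels, with switch dynamics, reason topics,
#' subgroup topic enrichments and documentation noise planted according to
#' the configuration. A planted-truth summary records the exact counts each
#' downstream cohort filter should remove, the number of planted switches,
#' and per-(topic, subgroup) note counts, so the generator doubles as the
#' oracle for pipeline tests. Noise types are planted on disjoint record
#' sets, which is what makes the per-filter bookkeeping exact.
#'
#' Generation is fully deterministic given `config$seed`; the caller's RNG
#' state is left untouched.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `switch_sim`: a list with data frames
#'   `orders`, `demographics`, `notes`, `gold`, the planted-`truth` list and
#'   the `config`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_patients
  mods <- modality_levels()
  start_p <- config$modality_start_distribution[mods]
  catalog <- .drug_catalog()
  topics <- config$reason_topic_catalog
  topic_names <- vapply(topics, `[[`, "", "topic")
  plan <- config$subgroup_enrichment_plan
  thr <- config$note_token_threshold

  race_levels <- c("White", "Latinx", "Black or African American", "Asian",
                   "Other", "Multi-Race/Ethnicity")
  race_p <- c(0.451, 0.151, 0.082, 0.203, 0.081, 0.031)
  lang_levels <- c("English", "Spanish", "Other")
  lang_p <- c(0.969, 0.018, 0.013)

  # sample() treats a length-1 x as 1:x; this keeps draws from short vectors
  # honest
  resample <- function(x, size = 1L, ...) x[sample.int(length(x), size, ...)]

  pid <- sprintf("P%05d", seq_len(n))
  demographics <- data.frame(
    patient_id = pid,
    race_ethnicity = sample(race_levels, n, TRUE, prob = race_p / sum(race_p)),
    preferred_language = sample(lang_levels, n, TRUE,
                                prob = lang_p / sum(lang_p)),
    age_first_rx = pmin(55, pmax(15, round(rnorm(n, 29.1, 8.4)))),
    stringsAsFactors = FALSE)
  demographics$age_bin <- .age_bin(demographics$age_first_rx)

  n_enc <- resample(seq(config$encounters_range[1],
                        config$encounters_range[2]), n, replace = TRUE)
  is_switcher <- runif(n) < config$switch_probability

  topic_probs_for <- function(race, age_bin) {
    p <- rep(1, length(topics))
    if (!is.null(plan) && nrow(plan)) {
      for (r in seq_len(nrow(plan))) {
        if (plan$subgroup[r] %in% c(race, age_bin)) {
          p[match(plan$topic[r], topic_names)] <-
            p[match(plan$topic[r], topic_names)] * plan$factor[r]
        }
      }
    }
    if (sum(p) <= 0) p <- rep(1, length(topics))
    p / sum(p)
  }

  # accumulate plain vectors; data frames are assembled once at the end
  n_orders <- sum(n_enc)
  n_notes_tot <- n_orders + n
  o_pat <- character(n_orders); o_date <- integer(n_orders)
  o_drug <- character(n_orders)
  nt_id <- character(n_notes_tot); nt_pat <- character(n_notes_tot)
  nt_date <- integer(n_notes_tot); nt_text <- character(n_notes_tot)
  nt_followup <- logical(n_notes_tot)
  g_id <- character(n_orders)
  g_stop <- rep(NA_character_, n_orders); g_start <- rep(NA_character_, n_orders)
  g_topic <- rep(NA_character_, n_orders); g_text <- rep(NA_character_, n_orders)

  oi <- 0L; ni <- 0L
  routine_cache <- new.env(parent = emptyenv())
  routine_note <- function(mention) {
    if (is.null(routine_cache[[mention]])) {
      routine_cache[[mention]] <- generate_note(current_mention = mention,
                                                token_threshold = thr)
    }
    routine_cache[[mention]]
  }
  followup_text <- generate_note(token_threshold = thr)

  for (i in seq_len(n)) {
    k <- n_enc[i]
    gaps <- pmax(config$gap_days$min,
                 round(rnorm(k - 1, config$gap_days$mean, config$gap_days$sd)))
    dates <- as.integer(cumsum(c(resample(0:365), gaps)))
    m1 <- resample(mods, prob = start_p)
    switch_at <- NA_integer_
    if (is_switcher[i] && k >= 2L) {
      switch_at <- resample(2:k)
      p2 <- start_p[mods != m1]
      m2 <- resample(mods[mods != m1], prob = p2 / sum(p2))
    }
    r1 <- sample.int(nrow(catalog[[m1]]), 1L)
    d1_order <- catalog[[m1]]$order_name[r1]
    d1_mention <- catalog[[m1]]$mention[r1]
    if (!is.na(switch_at)) {
      r2 <- sample.int(nrow(catalog[[m2]]), 1L)
      d2_order <- catalog[[m2]]$order_name[r2]
      d2_mention <- catalog[[m2]]$mention[r2]
    }

    for (j in seq_len(k)) {
      oi <- oi + 1L; ni <- ni + 1L
      on_new <- !is.na(switch_at) && j >= switch_at
      o_pat[oi] <- pid[i]; o_date[oi] <- dates[j]
      o_drug[oi] <- if (on_new) d2_order else d1_order
      id <- sprintf("N%06d", ni)
      nt_id[ni] <- id; nt_pat[ni] <- pid[i]; nt_date[ni] <- dates[j]
      g_id[oi] <- id
      if (!is.na(switch_at) && j == switch_at) {
        tp <- resample(seq_along(topics),
                       prob = topic_probs_for(demographics$race_ethnicity[i],
                                              demographics$age_bin[i]))
        phrase <- resample(topics[[tp]]$phrases)
        nt_text[ni] <- generate_note(stopped_mention = d1_mention,
                                     started_mention = d2_mention,
                                     reason = phrase, token_threshold = thr)
        g_stop[oi] <- m1; g_start[oi] <- m2
        g_topic[oi] <- topic_names[tp]; g_text[oi] <- phrase
      } else {
        nt_text[ni] <- routine_note(if (on_new) d2_mention else d1_mention)
      }
    }
    ni <- ni + 1L
    nt_id[ni] <- sprintf("N%06d", ni); nt_pat[ni] <- pid[i]
    nt_date[ni] <- dates[k] + 183L + resample(14:90)
    nt_text[ni] <- followup_text; nt_followup[ni] <- TRUE
  }

  orders <- data.frame(patient_id = o_pat, encounter_date = o_date,
                       start_date = o_date, drug_name = o_drug,
                       therapeutic_class = "CONTRACEPTIVES",
                       stringsAsFactors = FALSE)
  notes <- data.frame(note_id = nt_id, patient_id = nt_pat,
                      encounter_date = nt_date, text = nt_text,
                      followup = nt_followup, stringsAsFactors = FALSE)
  gold <- data.frame(note_id = g_id, true_stopped = g_stop,
                     true_started = g_start, true_reason_topic = g_topic,
                     true_reason_text = g_text, stringsAsFactors = FALSE)
  n_clean <- nrow(orders)

  nr <- config$noise_rates

  # patient-level noise first; those patients' orders leave the order pools
  n_lost <- round(nr$lost_followup * n)
  lost_patients <- if (n_lost > 0) resample(pid, n_lost) else character(0)
  if (n_lost > 0) {
    notes <- notes[!(notes$followup & notes$patient_id %in% lost_patients), ]
  }
  n_lost_orders <- sum(orders$patient_id %in% lost_patients)

  pool <- which(!orders$patient_id %in% lost_patients)
  draw <- function(pool, size) {
    size <- min(size, length(pool))
    idx <- if (size > 0) resample(pool, size) else integer(0)
    list(idx = idx, pool = setdiff(pool, idx))
  }
  ms <- draw(pool, round(nr$missing_start * n_clean)); pool <- ms$pool
  mn <- draw(pool, round(nr$missing_note * n_clean)); pool <- mn$pool
  sn <- draw(pool, round(nr$short_note * n_clean)); pool <- sn$pool
  dp <- draw(pool, round(nr$duplicate * n_clean)); pool <- dp$pool

  orders$start_date[ms$idx] <- NA_integer_
  if (length(mn$idx)) {
    key <- paste(orders$patient_id, orders$encounter_date)[mn$idx]
    nkey <- paste(notes$patient_id, notes$encounter_date)
    notes <- notes[!(nkey %in% key & !notes$followup), ]
  }
  if (length(sn$idx)) {
    key <- paste(orders$patient_id, orders$encounter_date)[sn$idx]
    nkey <- paste(notes$patient_id, notes$encounter_date)
    hit <- nkey %in% key & !notes$followup
    notes$text[hit] <- generate_note(short_note = TRUE, token_threshold = thr)
  }
  if (length(dp$idx)) orders <- rbind(orders, orders[dp$idx, ])

  # redaction: among switch notes whose in-note mentions include a
  # person-name-like brand
  eligible_notes <- gold$note_id[!is.na(gold$true_stopped)]
  brand_re <- paste0("\\b(", paste(.redactable_brands(), collapse = "|"),
                     ")\\b")
  eligible_notes <- intersect(
    eligible_notes, notes$note_id[grepl(brand_re, notes$text)])
  n_redact <- round(nr$redact_brand * length(eligible_notes))
  redacted <- if (n_redact > 0) resample(eligible_notes, n_redact) else character(0)
  if (length(redacted)) {
    hit <- notes$note_id %in% redacted
    notes$text[hit] <- gsub(brand_re, "[REDACTED]", notes$text[hit])
  }

  # distractor rows removed by the class / exclusion-pattern filters
  n_noncon <- round(nr$non_contraceptive * n_clean)
  n_emerg <- round(nr$emergency * n_clean)
  # distractors go to retained patients only: a random late encounter date
  # on a lost-to-follow-up patient would hand them spurious follow-up
  keep_pid <- setdiff(pid, lost_patients)
  distract <- function(k, drug, class) {
    if (k <= 0) return(NULL)
    data.frame(patient_id = resample(keep_pid, k, replace = TRUE),
               encounter_date = sample(0:2000, k, TRUE),
               start_date = sample(0:2000, k, TRUE),
               drug_name = drug, therapeutic_class = class,
               stringsAsFactors = FALSE)
  }
  orders <- rbind(orders,
                  distract(n_noncon, "ibuprofen 600 mg oral tablet",
                           "ANALGESICS"),
                  distract(n_emerg, "levonorgestrel 1.5 mg tablet (emergency)",
                           "CONTRACEPTIVES"))
  rownames(orders) <- NULL

  switch_gold <- gold[!is.na(gold$true_stopped), , drop = FALSE]
  sw_pat <- notes$patient_id[match(switch_gold$note_id, notes$note_id)]
  sw_dem <- demographics[match(sw_pat, demographics$patient_id), ]
  tsc <- rbind(
    if (nrow(switch_gold)) data.frame(
      axis = "race_ethnicity", topic = switch_gold$true_reason_topic,
      subgroup = sw_dem$race_ethnicity, stringsAsFactors = FALSE),
    if (nrow(switch_gold)) data.frame(
      axis = "age", topic = switch_gold$true_reason_topic,
      subgroup = sw_dem$age_bin, stringsAsFactors = FALSE))
  topic_subgroup_counts <- if (!is.null(tsc) && nrow(tsc)) {
    ag <- aggregate(list(n = rep(1L, nrow(tsc))),
                    tsc[c("axis", "topic", "subgroup")], sum)
    ag[order(ag$axis, ag$topic, ag$subgroup), ]
  } else {
    data.frame(axis = character(0), topic = character(0),
               subgroup = character(0), n = integer(0))
  }

  truth <- list(
    n_patients = n,
    n_orders_total = nrow(orders),
    n_orders_clean = n_clean,
    n_switch_patients = sum(is_switcher & n_enc >= 2L),
    n_switch_events = nrow(switch_gold),
    switch_note_ids = switch_gold$note_id,
    lost_patients = lost_patients,
    n_redacted_notes = length(redacted),
    filter_removals = c(
      non_contraceptive = n_noncon,
      excluded_pattern = n_emerg,
      unmapped = 0L,
      missing_start = length(ms$idx),
      no_followup = n_lost_orders,
      missing_note = length(mn$idx),
      short_note = length(sn$idx),
      duplicate = length(dp$idx)),
    topic_subgroup_counts = topic_subgroup_counts)

  structure(list(orders = orders, demographics = demographics,
                 notes = notes[, c("note_id", "patient_id",
                                   "encounter_date", "text")],
                 gold = gold, truth = truth, config = config),
            class = "switch_sim")
}

#' @method print switch_sim
#' @export
print.switch_sim <- function(x, ...) {
  cat("Synthetic contraceptive-switching cohort\n")
  cat(sprintf("  patients: %d   orders: %d   notes: %d\n",
              x$truth$n_patients, nrow(x$orders), nrow(x$notes)))
  cat(sprintf("  planted switches: %d (in %d patients)\n",
              x$truth$n_switch_events, x$truth$n_switch_patients))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic cohort to disk
#'
#' Writes orders, demographics and gold labels as CSV, notes as JSONL (one
#' `{note_id, patient_id, encounter_date, text}` object per line) and the
#' planted-truth summary as JSON.
#'
#' @param sim A `switch_sim` object from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_synthetic_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "switch_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- file.path(dir, c("orders.csv", "demographics.csv", "notes.jsonl",
                        "gold.csv", "truth.json"))
  utils::write.csv(sim$orders, f[1], row.names = FALSE)
  utils::write.csv(sim$demographics, f[2], row.names = FALSE)
  write_notes_jsonl(sim$notes, f[3])
  utils::write.csv(sim$gold, f[4], row.names = FALSE)
  truth <- sim$truth
  truth$topic_subgroup_counts <- NULL
  jsonlite::write_json(c(truth, list(
    topic_subgroup_counts = sim$truth$topic_subgroup_counts)),
    f[5], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(f)
}
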