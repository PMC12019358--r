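#' Micro-averaged precision, recall and F1
#'
#' Pools true positives, false positives and false negatives over all
#' positive labels (the six modalities by default; the no-modality label is
#' not a positive class). A `NA`/none prediction against a positive gold
#' label counts one false negative; a positive prediction against a none
#' gold counts one false positive; a positive prediction against a different
#' positive gold counts one false positive and one false negative. F1 is the
#' harmonic mean of precision and recall, and 0 when there are no true
#' positives.
#'
#' @param predictions,gold Equal-length character vectors of labels
#'   (`NA` for none).
#' @param positive Character vector of positive labels.
#' @return Named numeric vector `precision`, `recall`, `f1`, plus the pooled
#'   `tp`, `fp`, `fn` counts.
#' @export
micro_f1 <- function(predictions, gold, positive = modality_levels()) {
  if (length(predictions) != length(gold)) {
    stop("predictions and gold must have equal length")
  }
  pred_pos <- !is.na(predictions) & predictions %in% positive
  gold_pos <- !is.na(gold) & gold %in% positive
  tp <- sum(pred_pos & gold_pos & predictions == gold)
  fp <- sum(pred_pos & (!gold_pos | predictions != gold), na.rm = TRUE)
  fn <- sum(gold_pos & (!pred_pos | predictions != gold), na.rm = TRUE)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (tp > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1, tp = tp, fp = fp,
    fn = fn)
}

#' Cohen's kappa agreement
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} between
#' two label sources, with expected agreement \eqn{p_e} from the product of
#' the marginal label distributions. `NA` labels are treated as an explicit
#' "none" category. With `restrict_to_relevant = TRUE`, pairs where the
#' first (human) label is none are dropped before computing kappa — the
#' restricted concordance variant used when notes without a relevant
#' contraceptive are removed.
#'
#' @param labels_a,labels_b Equal-length label vectors; `labels_a` is the
#'   human/reference source for the restriction.
#' @param restrict_to_relevant Drop pairs with a none reference label first.
#' @return Kappa in `[-1, 1]`, or `NA` when it is undefined (empty input
#'   after restriction, or \eqn{p_e = 1}).
#' @export
cohens_kappa <- function(labels_a, labels_b, restrict_to_relevant = FALSE) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length")
  }
  a <- ifelse(is.na(labels_a), ".none", as.character(labels_a))
  b <- ifelse(is.na(labels_b), ".none", as.character(labels_b))
  if (restrict_to_relevant) {
    keep <- a != ".none"
    a <- a[keep]; b <- b[keep]
  }
  n <- length(a)
  if (n == 0L) return(NA_real_)
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, levels = lev), factor(b, levels = lev))
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < .Machine$double.eps) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Summarize human annotation of extracted reasons
#'
#' Joins extraction results to annotation records on `note_id` and reports
#' reason accuracy, hallucination rate (the fraction of extractions
#' containing information not derivable from the note) and per-task
#' micro-F1 against the annotated gold modalities. Missing boolean
#' annotations are excluded from their denominators.
#'
#' @param extractions Data frame from an extractor (`note_id`, `stopped`,
#'   `started`, `reason`).
#' @param annotations Data frame with `note_id`, `gold_stopped`,
#'   `gold_started` and optional logical `reason_accurate`, `hallucination`.
#' @return A list: `n`, `accuracy`, `hallucination_rate`, and `started` /
#'   `stopped` micro-F1 vectors.
#' @export
human_eval_report <- function(extractions, annotations) {
  check_columns(extractions, c("note_id", "stopped", "started"),
                "extractions")
  check_columns(annotations, c("note_id", "gold_stopped", "gold_started"),
                "annotations")
  idx <- match(annotations$note_id, extractions$note_id)
  if (all(is.na(idx))) stop("no overlapping note ids")
  ann <- annotations[!is.na(idx), , drop = FALSE]
  ext <- extractions[idx[!is.na(idx)], , drop = FALSE]
  frac <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else mean(x)
  }
  list(n = nrow(ann),
       accuracy = frac(ann$reason_accurate),
       hallucination_rate = frac(ann$hallucination),
       started = micro_f1(ext$started, ann$gold_started),
       stopped = micro_f1(ext$stopped, ann$gold_stopped))
}

#' Document-term matrix for note text
#'
#' Lower-cases, strips punctuation, tokenizes on whitespace and counts
#' terms. With `tfidf = TRUE`, counts are weighted by
#' \eqn{\log(1 + D/df_t)} and rows L2-normalized.
#'
#' @param texts Character vector of documents.
#' @param vocabulary Optional fixed term set (columns); terms outside it are
#'   dropped. Defaults to all observed terms, sorted.
#' @param tfidf Apply inverse-document-frequency weighting.
#' @param ngram Maximum n-gram order; `2` adds word bigrams (needed when
#'   word order carries the signal, e.g. which drug follows a start cue).
#' @return A dense numeric matrix, documents by terms.
#' @export
build_dtm <- function(texts, vocabulary = NULL, tfidf = FALSE, ngram = 1L) {
  toks <- strsplit(gsub("[^a-z0-9 ]", " ", tolower(texts)), "\\s+")
  toks <- lapply(toks, function(x) x[nzchar(x)])
  if (ngram >= 2L) {
    toks <- lapply(toks, function(x) {
      if (length(x) < 2L) return(x)
      c(x, paste(x[-length(x)], x[-1L], sep = "_"))
    })
  }
  if (is.null(vocabulary)) vocabulary <- sort(unique(unlist(toks)))
  m <- matrix(0, length(texts), length(vocabulary),
              dimnames = list(NULL, vocabulary))
  for (i in seq_along(toks)) {
    tb <- table(toks[[i]])
    keep <- intersect(names(tb), vocabulary)
    m[i, keep] <- as.numeric(tb[keep])
  }
  if (tfidf) {
    df <- colSums(m > 0)
    idf <- log(1 + length(texts) / pmax(df, 1))
    m <- sweep(m, 2, idf, "*")
    nrm <- sqrt(rowSums(m^2))
    m[nrm > 0, ] <- m[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
  }
  m
}

#' Built-in learning-curve classifiers
#'
#' Classifier specifications satisfying the fit/predict contract used by
#' [learning_curve()]: a list with a `name`, `fit(x, y)` returning a model,
#' and `predict(model, x)` returning a label vector. `classifier_logreg()`
#' is a lasso-regularized multinomial logistic regression (glmnet), which
#' concentrates weight on the sparse discriminative n-grams rather than
#' their correlated co-occurring terms; `classifier_rf()` is a random
#' forest.
#'
#' @param nlambda Length of the fitted regularization path; predictions use
#'   the least-regularized end of the path.
#' @param alpha Elastic-net mixing parameter (1 = lasso).
#' @param ntree Number of trees for the forest.
#' @return A classifier specification list.
#' @export
classifier_logreg <- function(nlambda = 50L, alpha = 1) {
  list(name = "logreg",
       fit = function(x, y) {
         suppressWarnings(
           glmnet::glmnet(x, factor(y), family = "multinomial",
                          alpha = alpha, nlambda = nlambda,
                          lambda.min.ratio = 1e-4))
       },
       predict = function(model, x) {
         as.character(stats::predict(model, x, type = "class",
                                     s = min(model$lambda))[, 1])
       })
}

#' @rdname classifier_logreg
#' @export
classifier_rf <- function(ntree = 200) {
  fix_names <- function(x) {
    colnames(x) <- make.names(colnames(x), unique = TRUE)
    x
  }
  list(name = "rf",
       fit = function(x, y) {
         randomForest::randomForest(fix_names(x), factor(y), ntree = ntree)
       },
       predict = function(model, x) {
         as.character(stats::predict(model, fix_names(x)))
       })
}

#' Learning curve over silver-labeled training subsamples
#'
#' Trains a text classifier on random subsamples of the training data at the
#' given fractions and scores micro-F1 on a held-out test split, repeated
#' over `k` random 70/10/20 train/validation/test resplits. Subsampling and
#' splitting are seeded; a fold in which some training subsample loses a
#' class entirely is skipped with a warning.
#'
#' @param texts Character vector of note texts.
#' @param labels Modality labels (silver-standard) aligned with `texts`.
#' @param fractions Numeric vector of training fractions in `(0, 1]`.
#' @param classifier A specification from [classifier_logreg()] /
#'   [classifier_rf()] or any list with `name`, `fit`, `predict`.
#' @param k Number of random resplits.
#' @param tfidf Use TF-IDF weighting rather than raw bag-of-words counts.
#' @param ngram Maximum n-gram order for the text features; the default
#'   includes bigrams so that start/stop context around a drug mention is
#'   representable.
#' @param seed Base RNG seed.
#' @return Data frame `fraction`, `mean_f1`, `sd_f1`, `n_folds`.
#' @export
learning_curve <- function(texts, labels, fractions = c(1, 0.5, 0.25, 0.1),
                           classifier = classifier_logreg(), k = 5L,
                           tfidf = TRUE, ngram = 2L, seed = 1L) {
  if (!length(fractions)) {
    return(data.frame(fraction = numeric(0), mean_f1 = numeric(0),
                      sd_f1 = numeric(0), n_folds = integer(0)))
  }
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  stopifnot(length(texts) == length(labels))
  res <- matrix(NA_real_, length(fractions), k,
                dimnames = list(fractions, NULL))
  n <- length(texts)
  for (fold in seq_len(k)) {
    set.seed(seed + fold)
    idx <- sample(n)
    n_tr <- floor(0.7 * n); n_va <- floor(0.1 * n)
    tr <- idx[seq_len(n_tr)]
    te <- idx[(n_tr + n_va + 1):n]
    vocab <- colnames(build_dtm(texts[tr], ngram = ngram))
    x_tr_all <- build_dtm(texts[tr], vocabulary = vocab, tfidf = tfidf,
                          ngram = ngram)
    x_te <- build_dtm(texts[te], vocabulary = vocab, tfidf = tfidf,
                      ngram = ngram)
    for (fi in seq_along(fractions)) {
      m <- max(2L, floor(fractions[fi] * n_tr))
      sub <- sample(seq_len(n_tr), m)
      y_sub <- labels[tr][sub]
      tab <- table(y_sub)
      if (length(tab) < 2L || min(tab) < 2L ||
          !all(unique(labels[te]) %in% names(tab))) {
        warning(sprintf(
          "fold %d, fraction %.2f: class missing (or singleton) in training subsample; skipped",
          fold, fractions[fi]))
        next
      }
      model <- classifier$fit(x_tr_all[sub, , drop = FALSE], y_sub)
      pred <- classifier$predict(model, x_te)
      res[fi, fold] <- micro_f1(pred, labels[te])[["f1"]]
    }
  }
  data.frame(fraction = fractions,
             mean_f1 = rowMeans(res, na.rm = TRUE),
             sd_f1 = apply(res, 1, stats::sd, na.rm = TRUE),
             n_folds = rowSums(!is.na(res)))
}
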