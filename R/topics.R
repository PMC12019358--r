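#' Embed reason texts as term vectors
#'
#' Default embedding backend: a deterministic L2-normalized term-frequency
#' representation over the corpus vocabulary. Texts with disjoint
#' vocabularies map to orthogonal vectors. Any alternative backend (e.g. a
#' transformer sentence encoder) can be plugged in as a function
#' `texts -> numeric matrix` wherever an `embed` argument is accepted.
#'
#' @param texts Non-empty character vector.
#' @param tfidf Apply inverse-document-frequency weighting.
#' @return Numeric matrix, one row per text.
#' @export
embed_reasons <- function(texts, tfidf = FALSE) {
  if (!length(texts)) stop("texts must be a non-empty list")
  m <- build_dtm(texts, tfidf = tfidf)
  if (!tfidf) {
    nrm <- sqrt(rowSums(m^2))
    m[nrm > 0, ] <- m[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
  }
  m
}

# Nonlinear reduction by a diffusion/Laplacian eigenmap with a self-tuning
# Gaussian affinity: w_ij = exp(-d_ij^2 / (s_i s_j)) with the local scale
# s_i the Euclidean distance to the n_neighbors-th neighbor, then the
# symmetric normalized Laplacian, eigenvectors of the n_components smallest
# eigenvalues, each coordinate damped by (1 - lambda)^t (diffusion scaling)
# so that between-cluster structure (lambda ~ 0) dominates within-cluster
# variation. Deterministic: base eigen() on a symmetric matrix.
spectral_reduce <- function(x, n_components = 5L, n_neighbors = 3L,
                            diffusion_time = 8L) {
  n <- nrow(x)
  if (n <= n_components) stop("need more vectors than components")
  d <- as.matrix(stats::dist(x))
  sigma <- vapply(seq_len(n), function(i)
    sort(d[i, ])[min(n_neighbors + 1L, n)], numeric(1))
  sigma <- pmax(sigma, 1e-3 * stats::median(d[d > 0]), .Machine$double.eps)
  w <- exp(-d^2 / outer(sigma, sigma))
  diag(w) <- 0
  deg <- pmax(rowSums(w), .Machine$double.eps)
  l <- diag(n) - sweep(sweep(w, 1, sqrt(deg), "/"), 2, sqrt(deg), "/")
  eg <- eigen((l + t(l)) / 2, symmetric = TRUE)
  idx <- order(eg$values)[seq_len(n_components)]
  damp <- (pmax(1 - eg$values[idx], 0))^diffusion_time
  sweep(eg$vectors[, idx, drop = FALSE], 2, damp, "*")
}

# Density clustering with a data-chosen cluster count, in the
# shared-nearest-neighbor (Jarvis-Patrick) family: each point's
# neighborhood is the smallest distance-ordered prefix of points holding at
# least min_cluster_size + 1 total multiplicity (never fewer than
# n_neighbors + 1 points); two points are linked when their neighborhoods
# share at least two members; clusters are the connected components of that
# link graph. Components whose total multiplicity falls below
# min_cluster_size become noise (label 0). Clusters are numbered by
# decreasing size. Deterministic: distance ties resolve by index.
density_cluster <- function(x, min_cluster_size = 10L, n_neighbors = 3L,
                            mult = NULL) {
  n <- nrow(x)
  if (is.null(mult)) mult <- rep(1L, n)
  d <- as.matrix(stats::dist(x))
  nbs <- lapply(seq_len(n), function(i) {
    o <- order(d[i, ])
    j <- which(cumsum(mult[o]) >= min_cluster_size + 1L)[1L]
    if (is.na(j)) j <- n
    o[seq_len(max(j, min(n_neighbors + 1L, n)))]
  })
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && length(intersect(nbs[[i]], nbs[[j]])) >= 2L) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  lab <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (lab[i] > 0L) next
    cl <- cl + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[v] == 0L) {
        lab[v] <- cl
        stack <- c(stack, which(adj[v, ] & lab == 0L))
      }
    }
  }
  sizes <- vapply(split(mult, lab), sum, numeric(1))
  keep <- names(sizes)[sizes >= min_cluster_size]
  ord <- keep[order(-sizes[keep], as.integer(keep))]
  labels <- rep(0L, n)
  for (k in seq_along(ord)) labels[lab == as.integer(ord[k])] <- k
  labels
}

#' Cluster embedded reasons into topics
#'
#' The clustering stage. Repeated texts give exactly repeated vectors, so
#' the geometry is computed on the unique points with their multiplicities
#' carried as density weights. Clusters come from shared-nearest-neighbor
#' density clustering ([density_cluster()]) with a data-chosen cluster
#' count; points in no sufficiently heavy component get the reserved noise
#' label `"0"`. A nonlinear reduction of the same points to `n_components`
#' dimensions (Laplacian eigenmap over a `n_neighbors`-nearest-neighbor
#' Euclidean graph) is returned as low-dimensional coordinates for
#' inspection and plotting. Per-note topic weights `q` are inverse-distance
#' soft memberships to the cluster centroids in the embedding space,
#' renormalized per note; noise notes carry all weight on topic `"0"`.
#'
#' @param vectors Numeric matrix from [embed_reasons()] (>= 10 rows).
#' @param min_cluster_size Minimum total weight of a dense component.
#' @param n_components,n_neighbors Reduction / neighborhood parameters.
#' @return A `topic_model` object: `assignments` (character topic labels,
#'   `"0"` = noise), `q` (notes x topics weight matrix, rows sum to 1),
#'   `coords` (notes x n_components reduced coordinates), `topic_terms`
#'   (empty until [top_terms()] fills it), `n_topics`.
#' @export
cluster_topics <- function(vectors, min_cluster_size = 10L,
                           n_components = 5L, n_neighbors = 3L) {
  if (nrow(vectors) < 10L) stop("need at least 10 vectors to cluster")
  if (nrow(vectors) <= n_components) stop("fewer vectors than components")
  key <- apply(vectors, 1, paste, collapse = ",")
  uniq <- which(!duplicated(key))
  uidx <- match(key, key[uniq])
  mult <- tabulate(uidx, nbins = length(uniq))
  ux <- vectors[uniq, , drop = FALSE]
  if (length(uniq) == 1L) {
    # no structure: a single topic containing everything
    labels <- rep(1L, nrow(vectors))
    coords <- matrix(0, nrow(vectors), n_components)
  } else {
    labels_u <- density_cluster(ux, min_cluster_size,
                                n_neighbors = n_neighbors, mult = mult)
    coords_u <- if (nrow(ux) > n_components) {
      spectral_reduce(ux, n_components, n_neighbors)
    } else if (ncol(ux) >= n_components) {
      ux[, seq_len(n_components), drop = FALSE]
    } else {
      cbind(ux, matrix(0, nrow(ux), n_components - ncol(ux)))
    }
    labels <- labels_u[uidx]
    coords <- coords_u[uidx, , drop = FALSE]
  }
  topics <- sort(unique(labels[labels > 0L]))
  q <- matrix(0, nrow(vectors), length(topics) + 1L,
              dimnames = list(NULL, c("0", as.character(topics))))
  if (length(topics)) {
    centroids <- t(vapply(topics, function(k)
      colMeans(vectors[labels == k, , drop = FALSE]), numeric(ncol(vectors))))
    for (i in seq_len(nrow(vectors))) {
      if (labels[i] == 0L) {
        q[i, "0"] <- 1
      } else {
        dd <- sqrt(rowSums(sweep(centroids, 2, vectors[i, ])^2))
        m <- 1 / (dd + 1e-9)
        q[i, -1L] <- m / sum(m)
      }
    }
  } else {
    q[, "0"] <- 1
  }
  structure(list(assignments = as.character(labels), q = q, coords = coords,
                 topic_terms = list(), n_topics = length(topics)),
            class = "topic_model")
}

#' @method print topic_model
#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("Topic model: %d topic(s) over %d note(s); %d in noise/no-reason class\n",
              x$n_topics, nrow(x$q), sum(x$assignments == "0")))
  invisible(x)
}

#' Class-based key terms per topic
#'
#' Pools each topic's texts into one pseudo-document and weights term `t` in
#' topic `c` by `frequency(t, c) * log(1 + n_topics / topics_containing_t)`,
#' so terms shared across topics are down-weighted relative to
#' topic-specific vocabulary. The top `k` terms per topic are returned.
#'
#' @param texts Character vector of reason texts.
#' @param assignments Topic labels aligned with `texts`.
#' @param k Number of terms per topic (>= 1).
#' @return Named list (one entry per topic) of data frames `term`, `weight`,
#'   ordered by decreasing weight.
#' @export
top_terms <- function(texts, assignments, k = 10L) {
  if (k < 1L) stop("k must be >= 1")
  stopifnot(length(texts) == length(assignments))
  keep <- !is.na(texts)
  texts <- texts[keep]; assignments <- assignments[keep]
  classes <- sort(unique(assignments))
  pooled <- vapply(classes, function(cl)
    paste(texts[assignments == cl], collapse = " "), character(1))
  dtm <- build_dtm(pooled)
  n_topics <- length(classes)
  topics_with <- colSums(dtm > 0)
  weights <- sweep(dtm, 2, log(1 + n_topics / topics_with), "*")
  out <- lapply(seq_len(n_topics), function(i) {
    w <- weights[i, ]
    w <- w[w > 0]
    w <- sort(w, decreasing = TRUE)
    head_n <- utils::head(w, k)
    data.frame(term = names(head_n), weight = unname(head_n),
               stringsAsFactors = FALSE)
  })
  names(out) <- classes
  out
}

#' Merge discovered topics into grouped topics
#'
#' Applies a manual merge map (raw topic label -> merged topic label),
#' relabeling assignments and summing the corresponding `q` columns so that
#' per-note topic mass is exactly conserved. The reserved noise label `"0"`
#' maps to itself unless the map says otherwise. Key terms are recomputed on
#' the merged classes when `texts` are supplied.
#'
#' @param result A `topic_model` from [cluster_topics()].
#' @param merge_map Named character vector: names are raw topic labels,
#'   values merged labels. Must cover every discovered topic.
#' @param texts Optional reason texts for recomputing `topic_terms`.
#' @param k Terms per merged topic.
#' @return A `topic_model` with merged labels.
#' @export
merge_topics <- function(result, merge_map, texts = NULL, k = 10L) {
  stopifnot(inherits(result, "topic_model"))
  merge_map <- c(merge_map)
  raw <- setdiff(colnames(result$q), "0")
  if (!"0" %in% names(merge_map)) merge_map <- c(merge_map, "0" = "0")
  missing <- setdiff(raw, names(merge_map))
  if (length(missing)) {
    stop("merge map is missing topic(s): ", paste(missing, collapse = ", "))
  }
  merged_of <- merge_map[colnames(result$q)]
  merged_levels <- unique(c("0", unname(merge_map[raw])))
  q2 <- matrix(0, nrow(result$q), length(merged_levels),
               dimnames = list(NULL, merged_levels))
  for (j in seq_along(merged_of)) {
    q2[, merged_of[j]] <- q2[, merged_of[j]] + result$q[, j]
  }
  assignments <- unname(merge_map[result$assignments])
  terms <- if (!is.null(texts)) top_terms(texts, assignments, k) else list()
  structure(list(assignments = assignments, q = q2, coords = result$coords,
                 topic_terms = terms,
                 n_topics = length(setdiff(merged_levels, "0"))),
            class = "topic_model")
}

#' Topic-model a set of extracted reasons
#'
#' End-to-end convenience wrapper: notes whose extracted reason is `NA` are
#' assigned the reserved no-relevant-reason topic `"0"` up front (they are
#' excluded from enrichment by default downstream); the remaining reasons
#' are embedded, reduced and density-clustered, and key terms are computed.
#'
#' @param reasons Character vector of extracted reasons, `NA` allowed.
#' @param min_cluster_size,n_components,n_neighbors See [cluster_topics()].
#' @param k Terms per topic.
#' @param embed Embedding backend, a function `texts -> matrix`.
#' @return A `topic_model` whose `q` and `assignments` cover all notes.
#' @export
topic_model <- function(reasons, min_cluster_size = 10L, n_components = 5L,
                        n_neighbors = 3L, k = 10L, embed = embed_reasons) {
  has_reason <- !is.na(reasons) & nzchar(trimws(ifelse(is.na(reasons), "",
                                                       reasons)))
  if (sum(has_reason) < 10L) {
    stop("need at least 10 non-empty reasons to model topics")
  }
  sub <- cluster_topics(embed(reasons[has_reason]),
                        min_cluster_size = min_cluster_size,
                        n_components = n_components,
                        n_neighbors = n_neighbors)
  q <- matrix(0, length(reasons), ncol(sub$q),
              dimnames = list(NULL, colnames(sub$q)))
  q[has_reason, ] <- sub$q
  q[!has_reason, "0"] <- 1
  coords <- matrix(0, length(reasons), ncol(sub$coords))
  coords[has_reason, ] <- sub$coords
  assignments <- rep("0", length(reasons))
  assignments[has_reason] <- sub$assignments
  out <- structure(list(assignments = assignments, q = q, coords = coords,
                        topic_terms = list(), n_topics = sub$n_topics),
                   class = "topic_model")
  out$topic_terms <- top_terms(ifelse(has_reason, reasons, "no relevant reason"),
                               assignments, k)
  out
}
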