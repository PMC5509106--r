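#' Assemble a network-learning dataset
#'
#' Observations are the stage-to-stage fold changes of a small gene set at
#' one taxon or ancestral node: 7 transition rows for an eight-point
#' *Neurospora* series, 5 for a six-point *Fusarium* series, 4 for a
#' five-stage ancestral node.
#'
#' @param observations A numeric matrix or data frame, transitions in rows,
#'   genes in columns (named).
#' @param node_id Label of the taxon or ancestral node the data belong to.
#' @return A `network_dataset` object wrapping the validated matrix.
#' @export
network_dataset <- function(observations, node_id = NA_character_) {
  m <- as.matrix(observations)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) stop("gene columns must be named", call. = FALSE)
  if (anyNA(m)) stop("missing values in observations", call. = FALSE)
  if (nrow(m) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (ncol(m) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (ncol(m) > 15L) warning("more than 15 genes; structure learning will be slow")
  structure(list(observations = m, node_id = node_id), class = "network_dataset")
}

# Gaussian BIC local score with a small ridge penalty on the parent
# coefficients; observation counts (4-7) are tiny, so unregularized ML
# regressions would be singular for larger parent sets.
local_score <- function(y, X, lambda = 1e-3) {
  n <- length(y)
  yc <- y - mean(y)
  k <- if (is.null(X)) 0L else ncol(X)
  if (k == 0L) {
    rss <- sum(yc^2)
  } else {
    Xc <- sweep(X, 2, colMeans(X))
    beta <- solve(crossprod(Xc) + diag(lambda, k), crossprod(Xc, yc))
    rss <- sum((yc - Xc %*% beta)^2)
  }
  rss <- max(rss, 1e-12)
  -0.5 * n * log(rss / n) - 0.5 * (k + 2) * log(n)
}

subset_key <- function(parents) paste(sort(parents), collapse = ",")

# combn() treats a scalar first argument as seq_len(); always index instead
combn_safe <- function(v, sz) {
  lapply(utils::combn(seq_along(v), sz, simplify = FALSE), function(i) v[i])
}

subsets_upto <- function(v, max_size) {
  sets <- list(integer(0))
  for (sz in seq_len(min(max_size, length(v))))
    sets <- c(sets, combn_safe(v, sz))
  sets
}

# cache of local scores for every (child, parent set <= max_parents)
build_score_cache <- function(m, max_parents, lambda) {
  p <- ncol(m)
  cache <- new.env(parent = emptyenv())
  for (child in seq_len(p)) {
    others <- setdiff(seq_len(p), child)
    for (s in subsets_upto(others, max_parents)) {
      key <- paste0(child, "|", subset_key(s))
      assign(key, local_score(m[, child], if (length(s)) m[, s, drop = FALSE] else NULL,
                              lambda), envir = cache)
    }
  }
  cache
}

dag_key <- function(adj) {
  p <- ncol(adj)
  paste(vapply(seq_len(p), function(j) subset_key(which(adj[, j])), character(1)),
        collapse = ";")
}

dag_score <- function(adj, cache) {
  p <- ncol(adj)
  sum(vapply(seq_len(p), function(j)
    get(paste0(j, "|", subset_key(which(adj[, j]))), envir = cache), numeric(1)))
}

is_acyclic <- function(adj) {
  deg <- colSums(adj)
  alive <- rep(TRUE, ncol(adj))
  repeat {
    src <- which(alive & deg == 0)
    if (!length(src)) break
    for (s in src) deg <- deg - adj[s, ] * 1
    alive[src] <- FALSE
  }
  !any(alive)
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
  out
}

# enumerate every distinct DAG with in-degree <= max_parents, scoring each;
# vectorized: per topological order, the cartesian product of per-position
# parent choices is expanded at once, then deduplicated across orders
enumerate_dags <- function(cache, p, max_parents) {
  keys_all <- ls(cache)
  score_map <- stats::setNames(
    vapply(keys_all, function(k) get(k, envir = cache), numeric(1)), keys_all)
  key_parts <- vector("list", 0)
  for (ord in all_perms(p)) {
    choices <- lapply(seq_len(p), function(i)
      vapply(subsets_upto(ord[seq_len(i - 1L)], max_parents), subset_key, character(1)))
    grid <- do.call(expand.grid, c(lapply(choices, seq_along),
                                   list(KEEP.OUT.ATTRS = FALSE)))
    L <- matrix("", nrow(grid), p)
    for (i in seq_len(p)) L[, ord[i]] <- choices[[i]][grid[[i]]]
    key_parts[[length(key_parts) + 1L]] <- L
  }
  L <- do.call(rbind, key_parts)
  key <- do.call(paste, c(lapply(seq_len(p), function(j) L[, j]), list(sep = ";")))
  keep <- !duplicated(key)
  L <- L[keep, , drop = FALSE]; key <- key[keep]
  score <- rowSums(vapply(seq_len(p), function(j)
    unname(score_map[paste0(j, "|", L[, j])]), numeric(length(key))))
  tibble::tibble(key = key, score = score)
}

key_to_adj <- function(key, genes) {
  p <- length(genes)
  adj <- matrix(FALSE, p, p, dimnames = list(genes, genes))
  parts <- strsplit(key, ";", fixed = TRUE)[[1]]
  if (length(parts) < p) parts <- c(parts, rep("", p - length(parts)))
  for (j in seq_len(p)) {
    if (nzchar(parts[j]))
      adj[as.integer(strsplit(parts[j], ",", fixed = TRUE)[[1]]), j] <- TRUE
  }
  adj
}

random_dag <- function(p, max_parents, edge_prob = 0.3) {
  ord <- sample.int(p)
  adj <- matrix(FALSE, p, p)
  for (i in seq_len(p)[-1]) {
    pred <- ord[seq_len(i - 1L)]
    k <- min(stats::rbinom(1, length(pred), edge_prob), max_parents)
    if (k > 0) adj[pred[sample.int(length(pred), k)], ord[i]] <- TRUE
  }
  adj
}

hill_climb_collect <- function(m, cache, max_parents, restarts, seen) {
  p <- ncol(m)
  record <- function(adj) {
    key <- dag_key(adj)
    if (is.null(seen[[key]])) seen[[key]] <- dag_score(adj, cache)
    seen[[key]]
  }
  for (r in seq_len(restarts)) {
    adj <- if (r == 1L) matrix(FALSE, p, p) else random_dag(p, max_parents)
    cur <- record(adj)
    repeat {
      best_gain <- 1e-9; best_adj <- NULL
      for (i in seq_len(p)) for (j in seq_len(p)) {
        if (i == j) next
        if (!adj[i, j]) {
          if (sum(adj[, j]) >= max_parents) next
          cand <- adj; cand[i, j] <- TRUE
          if (!is_acyclic(cand)) next
        } else {
          # deletion always legal; reversal handled below
          cand <- adj; cand[i, j] <- FALSE
        }
        sc <- record(cand)
        if (sc - cur > best_gain) { best_gain <- sc - cur; best_adj <- cand }
        if (adj[i, j] && sum(adj[, i]) < max_parents) {   # try reversal
          rev <- adj; rev[i, j] <- FALSE; rev[j, i] <- TRUE
          if (is_acyclic(rev)) {
            sc <- record(rev)
            if (sc - cur > best_gain) { best_gain <- sc - cur; best_adj <- rev }
          }
        }
      }
      if (is.null(best_adj)) break
      adj <- best_adj; cur <- record(adj)
    }
  }
  invisible(seen)
}

#' Learn the K highest-scoring network structures
#'
#' Score-based structure learning over directed acyclic graphs with a
#' Gaussian BIC score (ridge-regularized per-node regressions). For five or
#' fewer genes every DAG under the parent cap is enumerated and scored; for
#' more genes a seeded random-restart hill climb collects the best distinct
#' structures encountered. Identical data and seed give an identical list.
#'
#' @param data A [network_dataset()], or a matrix/data frame of
#'   transitions x genes.
#' @param K Number of top structures to return (default 100).
#' @param max_parents In-degree cap (default 2; with only 4-7 observations,
#'   larger parent sets are not identifiable).
#' @param lambda Ridge penalty on parent coefficients (default `1e-3`).
#' @param restarts Hill-climb restarts when enumeration is infeasible
#'   (default 200).
#' @param seed Seed for the hill-climb restarts (ignored by enumeration).
#' @param method `"auto"` (enumeration up to five genes, hill climb above),
#'   or force `"enumeration"` / `"hill_climb"`.
#' @return A `scored_dags` object: list with `dags` (adjacency matrices),
#'   `scores`, `genes`, `method`. If fewer than `K` distinct structures
#'   exist, all are returned with a warning.
#' @export
learn_top_k <- function(data, K = 100L, max_parents = 2L, lambda = 1e-3,
                        restarts = 200L, seed = 1L,
                        method = c("auto", "enumeration", "hill_climb")) {
  method <- match.arg(method)
  if (!inherits(data, "network_dataset")) data <- network_dataset(data)
  m <- data$observations
  p <- ncol(m); genes <- colnames(m)
  stopifnot(K >= 1L)
  cache <- build_score_cache(m, max_parents, lambda)
  if (method == "enumeration" && p > 7L)
    stop("enumeration is infeasible beyond 7 genes", call. = FALSE)
  if ((method == "auto" && p <= 5L) || method == "enumeration") {
    tab <- enumerate_dags(cache, p, max_parents)
    method <- "enumeration"
  } else {
    seen <- new.env(parent = emptyenv())
    withr::local_seed(seed)
    hill_climb_collect(m, cache, max_parents, restarts, seen)
    keys <- ls(seen)
    tab <- tibble::tibble(key = keys,
                          score = vapply(keys, function(k) seen[[k]], numeric(1)))
    method <- "hill_climb"
  }
  tab <- tab[order(-tab$score, tab$key), ]
  if (nrow(tab) < K) {
    warning("only ", nrow(tab), " distinct structures reachable; returning all")
    K <- nrow(tab)
  }
  tab <- tab[seq_len(K), ]
  dags <- lapply(tab$key, key_to_adj, genes = genes)
  stopifnot(all(vapply(dags, is_acyclic, logical(1))))
  structure(list(dags = dags, scores = tab$score, genes = genes,
                 method = method, node_id = data$node_id),
            class = "scored_dags")
}

#' @export
print.scored_dags <- function(x, ...) {
  cat("<scored_dags>", length(x$dags), "structures over",
      length(x$genes), "genes (", x$method, "); best score",
      format(x$scores[1], digits = 6), "\n")
  invisible(x)
}

#' @rdname tidy_methods
#' @export
tidy.scored_dags <- function(x, ...) {
  purrr::imap_dfr(x$dags, function(adj, i) {
    idx <- which(adj, arr.ind = TRUE)
    if (!nrow(idx)) return(tibble::tibble(model = integer(), from = character(),
                                          to = character(), score = double()))
    tibble::tibble(model = i, from = x$genes[idx[, 1]], to = x$genes[idx[, 2]],
                   score = x$scores[i])
  })
}

#' Majority consensus of a set of scored networks
#'
#' Each directed edge's confidence is the fraction of models that contain
#' it; edges at or above the threshold are retained (an edge in exactly
#' half of the models survives a 0.5 threshold).
#'
#' @param dags A `scored_dags` object, or a list of adjacency matrices.
#' @param threshold Retention threshold on edge confidence (default 0.5,
#'   inclusive).
#' @return A `consensus_network`: a tibble (`from`, `to`, `confidence`)
#'   with attributes `threshold`, `n_models`, `node_id`, `genes`.
#' @export
consensus <- function(dags, threshold = 0.5) {
  node_id <- NA_character_
  if (inherits(dags, "scored_dags")) {
    node_id <- dags$node_id
    genes <- dags$genes
    dl <- dags$dags
  } else {
    dl <- dags
    genes <- colnames(dl[[1]])
  }
  stopifnot(length(dl) >= 1L)
  counts <- Reduce(`+`, lapply(dl, function(a) a * 1))
  conf <- counts / length(dl)
  idx <- which(conf >= threshold - 1e-9 & conf > 0, arr.ind = TRUE)
  out <- tibble::tibble(from = genes[idx[, 1]], to = genes[idx[, 2]],
                        confidence = conf[idx]) |>
    dplyr::arrange(.data$from, .data$to)
  attr(out, "threshold") <- threshold
  attr(out, "n_models") <- length(dl)
  attr(out, "node_id") <- node_id
  attr(out, "genes") <- genes
  class(out) <- c("consensus_network", class(out))
  out
}

#' @rdname tidy_methods
#' @export
tidy.consensus_network <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("from", "to", "confidence")])
}

#' @rdname tidy_methods
#' @export
glance.consensus_network <- function(x, ...) {
  tibble::tibble(node_id = attr(x, "node_id"), n_edges = nrow(x),
                 n_models = attr(x, "n_models"), threshold = attr(x, "threshold"))
}

#' Classify edges as conserved across all ancestral networks
#'
#' An undirected edge {A, B} is conserved when every one of the three
#' ancestral consensus networks contains A->B or B->A — orientation is
#' ignored, matching the convention used to colour conserved interactions
#' in ancestral-network figures. All other edges are labelled by the
#' network they occur in.
#'
#' @param consensus_by_node Named list of `consensus_network` objects; must
#'   contain all names in `ancestors`.
#' @param ancestors Names of the ancestral networks required for the
#'   conservation call (default `MRCA-N`, `MRCA-F`, `MRCA-NF`).
#' @return A tibble with columns `node_id`, `from`, `to`, `confidence`,
#'   `conserved`.
#' @export
conserved_edges <- function(consensus_by_node,
                            ancestors = c("MRCA-N", "MRCA-F", "MRCA-NF")) {
  miss <- setdiff(ancestors, names(consensus_by_node))
  if (length(miss)) stop("missing ancestral network(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  und <- function(f, t) paste(pmin(f, t), pmax(f, t), sep = "~")
  anc_sets <- lapply(consensus_by_node[ancestors],
                     function(cn) unique(und(cn$from, cn$to)))
  conserved_und <- Reduce(intersect, anc_sets)
  purrr::imap_dfr(consensus_by_node, function(cn, nid) {
    if (!nrow(cn)) return(tibble::tibble(node_id = character(), from = character(),
                                         to = character(), confidence = double(),
                                         conserved = logical()))
    tibble::tibble(node_id = nid, from = cn$from, to = cn$to,
                   confidence = cn$confidence,
                   conserved = und(cn$from, cn$to) %in% conserved_und)
  })
}
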