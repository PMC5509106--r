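#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Given tip values of a continuous character on a rooted tree with branch
#' lengths, returns the internal-node values that maximize the Brownian
#' motion likelihood — equivalently, that minimize the weighted sum of
#' squared changes `sum((x_child - x_parent)^2 / v_branch)`. The solution is
#' computed by a two-pass pruning scheme: an upward pass collapses each
#' subtree into an effective value and effective branch length, and a
#' downward pass solves each node given its parent's final value. The states
#' do not depend on the Brownian rate, and are invariant to rescaling all
#' branch lengths by a common factor.
#'
#' The root is treated as a free parameter (no stationary prior).
#' Zero-length internal branches are collapsed into polytomies first;
#' zero-length terminal branches are an error.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param tip_values Named numeric vector: one value per tip label.
#' @return Named numeric vector of internal-node states. Names come from
#'   `tree$node.label` where present, otherwise `Node<k>` with k the ape
#'   node number.
#' @export
ancestral_states_ml <- function(tree, tip_values) {
  prep <- prune_prep(tree)
  miss <- setdiff(prep$tree$tip.label, names(tip_values))
  if (length(miss)) stop("missing tip value(s): ", paste(miss, collapse = ", "), call. = FALSE)
  vals <- bm_solve(prep, unname(tip_values[prep$tree$tip.label]))
  stats::setNames(vals, prep$node_names)
}

# collapse zero internal branches, validate, precompute postorder edge lists
prune_prep <- function(tree) {
  validate_phylogeny(tree)
  term <- tree$edge[, 2] <= ape::Ntip(tree)
  if (any(tree$edge.length[term] == 0))
    stop("zero-length terminal branch", call. = FALSE)
  if (any(tree$edge.length == 0)) tree <- ape::di2multi(tree, tol = 0)
  if (all(tree$edge.length == 0)) stop("all branch lengths zero", call. = FALSE)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  labs <- tree$node.label
  node_names <- if (!is.null(labs) && any(nzchar(labs))) {
    ifelse(nzchar(labs), labs, paste0("Node", ntip + seq_len(nnode)))
  } else paste0("Node", ntip + seq_len(nnode))
  list(tree = tree, ntip = ntip, nnode = nnode, node_names = node_names)
}

bm_solve <- function(prep, tip_vals) {
  tree <- prep$tree
  ntip <- prep$ntip
  ntot <- ntip + prep$nnode
  e1 <- tree$edge[, 1]; e2 <- tree$edge[, 2]; el <- tree$edge.length
  u <- c(tip_vals, numeric(prep$nnode))  # effective value per collapsed subtree
  ev <- numeric(ntot)                    # effective extra branch length
  sw <- numeric(ntot); swx <- numeric(ntot)  # accumulators of 1/w and u/w
  # upward pass: edges are postordered, so a node's accumulators are complete
  # by the time it appears as a child
  for (i in seq_along(e1)) {
    ch <- e2[i]
    if (ch > ntip) { u[ch] <- swx[ch] / sw[ch]; ev[ch] <- 1 / sw[ch] }
    w <- el[i] + ev[ch]
    sw[e1[i]] <- sw[e1[i]] + 1 / w
    swx[e1[i]] <- swx[e1[i]] + u[ch] / w
  }
  root <- e1[length(e1)]
  x <- c(tip_vals, numeric(prep$nnode))
  x[root] <- swx[root] / sw[root]
  # downward pass in reverse postorder: a node's parent is finalized before
  # the edge into the node is visited
  for (i in rev(seq_along(e1))) {
    ch <- e2[i]
    if (ch > ntip) {
      w <- el[i]
      x[ch] <- (x[e1[i]] / w + swx[ch]) / (1 / w + sw[ch])
    }
  }
  x[(ntip + 1):ntot]
}

#' Linear operator mapping tip values to ancestral states
#'
#' The BM maximum-likelihood states are linear in the tip values; this
#' returns the (internal nodes x tips) matrix `A` with `states = A %*% tips`,
#' so thousands of genes can be reconstructed with one matrix product.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return A numeric matrix with internal-node row names and tip-label
#'   column names. Rows sum to one (translation equivariance).
#' @export
ancestral_operator <- function(tree) {
  prep <- prune_prep(tree)
  tips <- prep$tree$tip.label
  A <- vapply(seq_along(tips), function(i) {
    v <- numeric(length(tips)); v[i] <- 1
    bm_solve(prep, v)
  }, numeric(prep$nnode))
  dimnames(A) <- list(prep$node_names, tips)
  A
}

#' Fit the per-gene Brownian motion rate
#'
#' REML rate via standardized independent contrasts:
#' `sigma2 = sum(contrast^2) / (n - 1)`; the reported log-likelihood is the
#' Gaussian log-density of the standardized contrasts at that rate (NA when
#' the rate is exactly zero).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param tip_values Named numeric vector of tip values.
#' @return A one-row tibble with columns `sig2`, `loglik`, `n_tips`.
#' @export
fit_bm_rate <- function(tree, tip_values) {
  validate_phylogeny(tree)
  if (ape::Ntip(tree) < 2L) stop("need at least 2 tips", call. = FALSE)
  tr <- if (!ape::is.binary(tree)) ape::multi2di(tree) else tree
  contrasts <- ape::pic(tip_values[tr$tip.label], tr)
  n <- ape::Ntip(tr)
  sig2 <- sum(contrasts^2) / (n - 1)
  ll <- if (sig2 > 0) sum(stats::dnorm(contrasts, 0, sqrt(sig2), log = TRUE)) else NA_real_
  tibble::tibble(sig2 = sig2, loglik = ll, n_tips = n)
}

#' Ancestral fold-change profiles at every internal node
#'
#' Runs the BM maximum-likelihood reconstruction independently for each
#' stage transition (each of the S-1 signed fold-change characters is
#' treated as a separate character, on the raw signed scale), then
#' back-transforms each node's fold-change vector into a relative expression
#' profile with the lowest stage set to one.
#'
#' @param tree A rooted `phylo`; tip labels must match the species in
#'   `fold_changes`.
#' @param fold_changes Tibble with columns `species`, `gene`, `transition`,
#'   `d`: one complete fold-change vector of common length per species.
#' @return A list with class `ancestral_profiles`:
#'   `states` — tibble (`gene`, `node`, `transition`, `d`);
#'   `profiles` — tibble (`gene`, `node`, `stage`, `x`).
#' @export
ancestral_profiles <- function(tree, fold_changes) {
  stopifnot(all(c("species", "gene", "transition", "d") %in% names(fold_changes)))
  sp <- unique(fold_changes$species)
  miss <- setdiff(tree$tip.label, sp)
  if (length(miss)) stop("no fold changes for species: ", paste(miss, collapse = ", "), call. = FALSE)
  lens <- fold_changes |> dplyr::count(.data$species, .data$gene)
  if (dplyr::n_distinct(lens$n) != 1L)
    stop("fold-change vectors have mismatched lengths across species/genes", call. = FALSE)
  A <- ancestral_operator(tree)
  wide <- fold_changes |>
    dplyr::filter(.data$species %in% tree$tip.label) |>
    tidyr::pivot_wider(names_from = "species", values_from = "d")
  tipmat <- as.matrix(wide[, colnames(A), drop = FALSE])
  est <- tipmat %*% t(A)     # (gene x transition) rows -> nodes in columns
  states <- dplyr::bind_cols(wide[, c("gene", "transition")],
                             tibble::as_tibble(est)) |>
    tidyr::pivot_longer(-c("gene", "transition"), names_to = "node", values_to = "d") |>
    dplyr::arrange(.data$node, .data$gene, .data$transition) |>
    dplyr::select("gene", "node", "transition", "d")
  profiles <- fold_change_to_profile(states)
  structure(list(states = states, profiles = profiles), class = "ancestral_profiles")
}

#' @export
print.ancestral_profiles <- function(x, ...) {
  cat("<ancestral_profiles>", dplyr::n_distinct(x$states$gene), "genes,",
      dplyr::n_distinct(x$states$node), "internal nodes,",
      max(x$states$transition), "transitions\n")
  invisible(x)
}

#' @rdname tidy_methods
#' @export
tidy.ancestral_profiles <- function(x, ...) x$states
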