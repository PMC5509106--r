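test_that("a strong linear dependency yields a single-edge top structure", {
  set.seed(1)
  x <- stats::rnorm(7)
  y <- 5 * x + stats::rnorm(7, sd = 0.1)
  tk <- learn_top_k(network_dataset(cbind(x = x, y = y)), K = 3)
  expect_equal(tk$method, "enumeration")
  expect_equal(sum(tk$dags[[1]]), 1)            # exactly one edge, either direction
  expect_true(tk$dags[[1]]["x", "y"] || tk$dags[[1]]["y", "x"])
  expect_equal(sum(tk$dags[[3]]), 0)            # empty graph ranks last of the three
})

test_that("exactly independent genes leave the empty graph on top", {
  set.seed(6)
  m <- orthogonal_noise(4, 3)
  tk <- learn_top_k(network_dataset(m), K = 1)
  expect_equal(sum(tk$dags[[1]]), 0)
})

test_that("a three-gene chain skeleton is recovered at low noise", {
  skeleton <- function(adj) {
    und <- adj | t(adj)
    paste(sort(apply(which(und & upper.tri(und), arr.ind = TRUE), 1,
                     function(ij) paste(ij, collapse = "-"))), collapse = ";")
  }
  # 20 observations: with the 4-7 transitions of a single developmental
  # series, near-equivalent structures are not separable at this noise level
  true_skel <- "1-2;2-3"
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    x <- stats::rnorm(20)
    y <- x + stats::rnorm(20, sd = 0.1)
    z <- y + stats::rnorm(20, sd = 0.1)
    tk <- learn_top_k(network_dataset(cbind(a = x, b = y, c = z)), K = 1)
    if (skeleton(tk$dags[[1]]) == true_skel) hits <- hits + 1
  }
  expect_gte(hits, 80)
})

test_that("every emitted structure is acyclic and respects the parent cap", {
  set.seed(10)
  m <- matrix(stats::rnorm(28), 7, 4, dimnames = list(NULL, letters[1:4]))
  tk <- learn_top_k(network_dataset(m), K = 50, max_parents = 2)
  for (adj in tk$dags) {
    expect_true(all(colSums(adj) <= 2))
    g <- igraph::graph_from_adjacency_matrix(adj)
    expect_true(igraph::is_dag(g))
  }
  expect_equal(tk$scores, sort(tk$scores, decreasing = TRUE))
})

test_that("K beyond the reachable structure count returns all with a warning", {
  set.seed(2)
  m <- matrix(stats::rnorm(10), 5, 2, dimnames = list(NULL, c("x", "y")))
  expect_warning(tk <- learn_top_k(network_dataset(m), K = 10), "3 distinct")
  expect_length(tk$dags, 3)
})

test_that("consensus keeps the inclusive threshold boundary", {
  gs <- c("a", "b")
  e1 <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2, dimnames = list(gs, gs))  # a->b
  e0 <- matrix(FALSE, 2, 2, dimnames = list(gs, gs))
  cn50 <- consensus(c(replicate(50, list(e1)), replicate(50, list(e0))), 0.5)
  expect_equal(nrow(cn50), 1)
  expect_equal(cn50$confidence, 0.5)
  cn49 <- consensus(c(replicate(49, list(e1)), replicate(51, list(e0))), 0.5)
  expect_equal(nrow(cn49), 0)
  cn100 <- consensus(replicate(100, list(e1)), 0.5)
  expect_equal(cn100$confidence, 1.0)
  # confidences are multiples of 1/K
  set.seed(4)
  dl <- replicate(40, {
    a <- matrix(stats::runif(4) < 0.4, 2, dimnames = list(gs, gs))
    diag(a) <- FALSE; a[2, 1] <- a[2, 1] && !a[1, 2]; a
  }, simplify = FALSE)
  cc <- consensus(dl, threshold = 0.01)
  expect_true(all(abs(cc$confidence * 40 - round(cc$confidence * 40)) < 1e-9))
})

test_that("hill climbing is deterministic and matches enumeration on 4 genes", {
  set.seed(30)
  m6 <- matrix(stats::rnorm(42), 7, 6, dimnames = list(NULL, letters[1:6]))
  a1 <- learn_top_k(network_dataset(m6), K = 20, seed = 99, restarts = 30)
  a2 <- learn_top_k(network_dataset(m6), K = 20, seed = 99, restarts = 30)
  expect_equal(a1$method, "hill_climb")
  expect_identical(a1$dags, a2$dags)
  expect_identical(a1$scores, a2$scores)

  agree <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 6
    x <- stats::rnorm(n)
    m <- cbind(a = x, b = x + stats::rnorm(n, sd = 0.5),
               c = stats::rnorm(n), d = stats::rnorm(n))
    enum <- learn_top_k(network_dataset(m), K = 1)
    hc <- learn_top_k(network_dataset(m), K = 1, method = "hill_climb",
                      seed = s, restarts = 200)
    if (identical(enum$dags[[1]], hc$dags[[1]])) agree <- agree + 1
  }
  expect_gte(agree, 9)
})

test_that("conserved edges ignore orientation across the three ancestors", {
  cn <- function(edges, nid) {
    out <- tibble::tibble(from = edges$from, to = edges$to,
                          confidence = rep(1, nrow(edges)))
    attr(out, "threshold") <- 0.5; attr(out, "n_models") <- 100
    attr(out, "node_id") <- nid; attr(out, "genes") <- c("A", "B", "C")
    class(out) <- c("consensus_network", class(out))
    out
  }
  nets <- list(
    "MRCA-N" = cn(tibble::tibble(from = c("A", "B"), to = c("B", "C")), "MRCA-N"),
    "MRCA-F" = cn(tibble::tibble(from = "B", to = "A"), "MRCA-F"),   # flipped A-B
    "MRCA-NF" = cn(tibble::tibble(from = "A", to = "B"), "MRCA-NF"))
  ce <- conserved_edges(nets)
  ab <- dplyr::filter(ce, (from == "A" & to == "B") | (from == "B" & to == "A"))
  expect_true(all(ab$conserved))          # present in all three, orientation mixed
  bc <- dplyr::filter(ce, from == "B", to == "C")
  expect_false(any(bc$conserved))         # present in one ancestor only
  expect_error(conserved_edges(nets[1:2]), "missing ancestral network")
})
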