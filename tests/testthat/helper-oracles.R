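# Independent oracles and fixture builders shared across tests.

# Exact BM/weighted-least-squares oracle for ancestral states, solved as a
# linear system on the weighted edge-incidence matrix -- an algebraic route
# independent of the package's two-pass pruning scheme.
oracle_ancestral <- function(tree, tip_values) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  e <- tree$edge
  w <- 1 / tree$edge.length
  # unknowns: internal nodes ntip+1 .. ntip+nint
  A <- matrix(0, nrow(e), nint)
  b <- numeric(nrow(e))
  tipv <- tip_values[tree$tip.label]
  for (i in seq_len(nrow(e))) {
    pa <- e[i, 1]; ch <- e[i, 2]
    sw <- sqrt(w[i])
    A[i, pa - ntip] <- -sw
    if (ch <= ntip) b[i] <- sw * tipv[ch] else A[i, ch - ntip] <- A[i, ch - ntip] + sw
  }
  x <- -solve(crossprod(A), crossprod(A, b))
  stats::setNames(as.vector(x), paste0("Node", ntip + seq_len(nint)))
}

# Brute-force Fisher oracle: enumerate the full hypergeometric support with
# plain choose() arithmetic.
oracle_fisher <- function(a, b, cc, d, alternative = "two.sided") {
  m <- a + b; n <- cc + d; k <- a + cc
  support <- max(0, k - n):min(k, m)
  pk <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  obs <- pk[support == a]
  switch(alternative,
         greater = sum(pk[support >= a]),
         less = sum(pk[support <= a]),
         two.sided = sum(pk[pk <= obs * (1 + 1e-7)]))
}

# random rooted tree with strictly positive branch lengths
random_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, rooted = TRUE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.2, 3)
  tr
}

# centered, mutually orthogonal noise columns: exactly independent "genes",
# so any parent adds penalty but zero fit improvement
orthogonal_noise <- function(n_obs, n_genes) {
  stopifnot(n_genes <= n_obs - 1L)
  m <- matrix(stats::rnorm(n_obs * n_genes), n_obs, n_genes)
  m <- sweep(m, 2, colMeans(m))
  q <- qr.Q(qr(m))[, seq_len(n_genes), drop = FALSE]
  colnames(q) <- paste0("g", seq_len(n_genes))
  q
}

table1_path <- function() system.file("extdata", "phenotypes_table1.tsv",
                                      package = "fruitbody")

# the 23 ranked-list knockouts in F. graminearum: the fixture's 26 pairs
# minus the three genes deleted outside the ranked screen
fg_ranked23 <- function() {
  ph <- read_phenotypes(table1_path())
  setdiff(ph$gene[ph$species == "F.graminearum"],
          c("FGSG_02751", "FGSG_09475", "FGSG_13162"))
}

# knockout calls for the 196 top-ranked N. crassa genes, rebuilt from the
# published aggregate counts (synthetic per-gene labels: 16 Stage-1, 8
# Stage-3, 10 Stage-5 from the staged-phenotype prose, remainder of the 44
# hits classed other, 152 wild type)
nc_ranked196 <- function() {
  cls <- c(rep("Stage-1", 16), rep("Stage-3", 8), rep("Stage-5", 10),
           rep("other", 10), rep("WT", 152))
  tibble::tibble(species = "N.crassa",
                 gene = sprintf("NCU%05d", seq_along(cls)),
                 phenotype = cls)
}
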