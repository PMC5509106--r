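#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the statistical structure of the study system: five
#' Sordariomycete species on a calibrated chronogram with the fixed
#' topology `((F.graminearum, F.verticillioides), (N.discreta, (N.crassa,
#' N.tetrasperma)))`, a root age of 220 Myr, five canonical developmental
#' stages, lineage-specific expression shifts planted in a minority of
#' genes, and overdispersed sequencing counts (8 sample points for
#' *Neurospora* species, 6 for *Fusarium*).
#'
#' @param n_genes Number of ortholog sets to simulate.
#' @param root_age Age of the *Fusarium*/*Neurospora* split (Myr).
#' @param age_f Age of the *Fusarium* crown node MRCA-F (Myr).
#' @param age_n Age of the *Neurospora* crown node MRCA-N (Myr).
#' @param age_nn Age of the (*N. crassa*, *N. tetrasperma*) node (Myr).
#' @param stages Number of canonical stages S (fold-change vectors have
#'   length S - 1).
#' @param rate_meanlog,rate_sdlog Log-normal distribution of the per-gene
#'   Brownian rate sigma^2, in squared trait units per Myr. The default
#'   `rate_meanlog = log(1 / root_age)` gives a median accumulated
#'   root-to-tip variance of 1, matching the order of magnitude of observed
#'   stage-to-stage fold changes; set `rate_sdlog = 0` for a fixed rate.
#' @param shift_fraction Fraction of genes carrying a planted
#'   lineage-specific shift (default 0.05).
#' @param shift_clade `"Neurospora"` or `"Fusarium"`: the clade on whose
#'   stem branch the shift is added.
#' @param shift_transition Transition index carrying the shift (default 4).
#' @param shift_magnitude Shift size on the signed fold-change scale
#'   (default +4).
#' @param root_sd Standard deviation of the per-gene, per-transition root
#'   value (default 0: every gene starts its Brownian path at zero).
#' @param depth Sequencing depth per sample (default 1e6 reads).
#' @param dispersion Negative-binomial dispersion alpha with
#'   `Var = mu + alpha * mu^2` (default 0.05; 0 gives Poisson counts).
#' @param concordance_prob Probability that a planted gene's simulated
#'   knockout phenotype lands in its shift stage (default 0.5).
#' @param wt_prob Probability that a non-planted gene is phenotypically
#'   wild type (default 0.95).
#' @param seed Integer seed; fixing it makes every generator fully
#'   reproducible.
#' @return A named list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 1000L, root_age = 220, age_f = 50,
                             age_n = 30, age_nn = 15, stages = 5L,
                             rate_meanlog = NULL, rate_sdlog = 0.5,
                             shift_fraction = 0.05, shift_clade = "Neurospora",
                             shift_transition = 4L, shift_magnitude = 4,
                             root_sd = 0, depth = 1e6, dispersion = 0.05,
                             concordance_prob = 0.5, wt_prob = 0.95, seed = 1L) {
  if (is.null(rate_meanlog)) rate_meanlog <- log(1 / root_age)
  cfg <- list(n_genes = n_genes, root_age = root_age, age_f = age_f, age_n = age_n,
              age_nn = age_nn, stages = stages, rate_meanlog = rate_meanlog,
              rate_sdlog = rate_sdlog, shift_fraction = shift_fraction,
              shift_clade = shift_clade, shift_transition = shift_transition,
              shift_magnitude = shift_magnitude, root_sd = root_sd, depth = depth,
              dispersion = dispersion, concordance_prob = concordance_prob,
              wt_prob = wt_prob, seed = seed)
  if (!(cfg$root_age > cfg$age_f && cfg$root_age > cfg$age_n && cfg$age_n > cfg$age_nn))
    stop("node ages must decrease from root to tips", call. = FALSE)
  if (cfg$shift_fraction < 0 || cfg$shift_fraction > 1)
    stop("shift_fraction must be in [0, 1]", call. = FALSE)
  if (cfg$shift_transition > cfg$stages - 1L)
    stop("shift_transition exceeds S - 1", call. = FALSE)
  structure(cfg, class = "generator_config")
}

#' Species labels used by the generator
#' @export
study_species <- c(fg = "F.graminearum", fv = "F.verticillioides",
                   nd = "N.discreta", nc = "N.crassa", nt = "N.tetrasperma")

#' Build the study chronogram
#'
#' Ultrametric five-species tree with the fixed study topology and the
#' configured node ages; internal nodes are labelled `MRCA-NF` (root),
#' `MRCA-F`, `MRCA-N` and `N-core` (the *N. crassa* / *N. tetrasperma*
#' node).
#'
#' @param cfg A [generator_config()].
#' @return A `phylo` chronogram.
#' @export
make_chronogram <- function(cfg = generator_config()) {
  nwk <- sprintf(
    "((%s:%g,%s:%g)MRCA-F:%g,(%s:%g,(%s:%g,%s:%g)N-core:%g)MRCA-N:%g)MRCA-NF;",
    study_species[["fg"]], cfg$age_f, study_species[["fv"]], cfg$age_f,
    cfg$root_age - cfg$age_f,
    study_species[["nd"]], cfg$age_n,
    study_species[["nc"]], cfg$age_nn, study_species[["nt"]], cfg$age_nn,
    cfg$age_n - cfg$age_nn,
    cfg$root_age - cfg$age_n)
  read_newick(nwk)
}

#' Simulate Brownian evolution of fold-change profiles on a tree
#'
#' Each of the S - 1 signed fold-change characters evolves independently by
#' Brownian motion from a root value of zero, with a per-gene rate drawn
#' from the configured log-normal. Planted genes additionally receive a
#' deterministic offset on the stem branch of the designated clade at the
#' designated transition, so the whole clade inherits the shift. True
#' values at every node (internal and tip) are recorded as ground truth.
#'
#' @param tree A chronogram from [make_chronogram()] (any labelled rooted
#'   tree works).
#' @param cfg A [generator_config()].
#' @param seed Overrides `cfg$seed` when given.
#' @return A list of class `gene_evolution`:
#'   `fold_changes` (tibble `species`, `gene`, `transition`, `d`),
#'   `truth` (tibble `gene`, `node`, `transition`, `d` for every node),
#'   `planted` (tibble `gene`, `transition`, `clade`, `magnitude`),
#'   `rates` (tibble `gene`, `sig2`).
#' @export
simulate_gene_evolution <- function(tree, cfg = generator_config(), seed = NULL) {
  validate_phylogeny(tree)
  withr::local_seed(if (is.null(seed)) cfg$seed else seed)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree); nnode <- tree$Nnode
  labs <- c(tree$tip.label,
            if (!is.null(tree$node.label) && any(nzchar(tree$node.label)))
              ifelse(nzchar(tree$node.label), tree$node.label,
                     paste0("Node", ntip + seq_len(nnode)))
            else paste0("Node", ntip + seq_len(nnode)))
  ngen <- cfg$n_genes; ntr <- cfg$stages - 1L
  genes <- sprintf("g%04d", seq_len(ngen))
  sig2 <- stats::rlnorm(ngen, cfg$rate_meanlog, cfg$rate_sdlog)
  n_planted <- floor(cfg$shift_fraction * ngen)
  planted_idx <- if (n_planted > 0) sort(sample.int(ngen, n_planted)) else integer(0)
  # stem branch of the shifted clade = edge into the clade's crown node
  clade_tips <- grep(if (cfg$shift_clade == "Neurospora") "^N\\." else "^F\\.",
                     tree$tip.label)
  shift_node <- if (length(clade_tips) > 1L)
    ape::getMRCA(tree, clade_tips) else clade_tips
  # values: array genes x transitions x nodes, preorder fill
  e1 <- tree$edge[, 1]; e2 <- tree$edge[, 2]; el <- tree$edge.length
  ntot <- ntip + nnode
  vals <- array(0, dim = c(ngen, ntr, ntot))
  root <- e1[length(e1)]
  if (cfg$root_sd > 0)
    vals[, , root] <- matrix(stats::rnorm(ngen * ntr, 0, cfg$root_sd), ngen, ntr)
  for (i in rev(seq_along(e1))) {   # reverse postorder = parents first
    ch <- e2[i]
    inc <- matrix(stats::rnorm(ngen * ntr, 0, sqrt(sig2 * el[i])), ngen, ntr)
    vals[, , ch] <- vals[, , e1[i]] + inc
    if (ch == shift_node && length(planted_idx))
      vals[planted_idx, cfg$shift_transition, ch] <-
        vals[planted_idx, cfg$shift_transition, ch] + cfg$shift_magnitude
  }
  truth <- tidyr::expand_grid(node = labs, transition = seq_len(ntr), gene = genes)
  truth$d <- as.vector(vals)   # array strides: gene fastest, then transition, node
  truth <- truth[, c("gene", "node", "transition", "d")]
  fold_changes <- truth |>
    dplyr::filter(.data$node %in% tree$tip.label) |>
    dplyr::rename(species = "node") |>
    dplyr::select("species", "gene", "transition", "d") |>
    dplyr::arrange(.data$species, .data$gene, .data$transition)
  planted <- tibble::tibble(gene = genes[planted_idx],
                            transition = cfg$shift_transition,
                            clade = cfg$shift_clade,
                            magnitude = cfg$shift_magnitude)
  structure(list(fold_changes = fold_changes,
                 truth = dplyr::arrange(truth, .data$node, .data$gene, .data$transition),
                 planted = planted,
                 rates = tibble::tibble(gene = genes, sig2 = sig2)),
            class = "gene_evolution")
}

#' @export
print.gene_evolution <- function(x, ...) {
  cat("<gene_evolution>", nrow(x$rates), "genes,",
      dplyr::n_distinct(x$truth$node), "nodes,",
      nrow(x$planted), "planted shifts\n")
  invisible(x)
}

#' Simulate overdispersed sequencing counts from relative profiles
#'
#' Expected counts are the gene's relative expression at the sample's
#' canonical stage times one constant per-species scale chosen so the mean
#' library size equals the configured depth; realized library sizes
#' therefore track the stage's total expression, as in real sequencing.
#' Counts are drawn negative-binomially with `Var = mu + alpha*mu^2`
#' (Poisson when `dispersion = 0`). Species whose label starts with `N`
#' get 8 sample points, others 6, both mapped onto the 5 canonical stages
#' by [default_stage_mapping()].
#'
#' @param profiles Tibble (`species`, `gene`, `stage`, `x`) of positive
#'   relative expression profiles.
#' @param cfg A [generator_config()].
#' @param seed Overrides `cfg$seed` when given.
#' @return A named list of [count_table()] objects, one per species.
#' @export
simulate_counts <- function(profiles, cfg = generator_config(), seed = NULL) {
  stopifnot(all(c("species", "gene", "stage", "x") %in% names(profiles)))
  if (any(profiles$x <= 0)) stop("profiles must be positive", call. = FALSE)
  if (cfg$depth <= 0) stop("depth must be positive", call. = FALSE)
  withr::local_seed(if (is.null(seed)) cfg$seed else seed)
  sp_list <- sort(unique(profiles$species))
  out <- lapply(sp_list, function(sp) {
    prof <- dplyr::filter(profiles, .data$species == sp) |>
      dplyr::arrange(.data$gene, .data$stage)
    n_pts <- if (grepl("^N", sp)) 8L else 6L
    samples <- sprintf("%s_t%02d", gsub("[^A-Za-z]", "", sp), seq_len(n_pts))
    smap <- default_stage_mapping(samples)
    wide <- tidyr::pivot_wider(prof[, c("gene", "stage", "x")],
                               names_from = "stage", values_from = "x")
    xm <- as.matrix(wide[, -1])
    scale_c <- cfg$depth / sum(rowMeans(xm))
    cts <- lapply(seq_len(n_pts), function(i) {
      mu <- xm[, smap$stage[i]] * scale_c
      if (cfg$dispersion > 0)
        stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
      else stats::rpois(length(mu), mu)
    })
    long <- tibble::tibble(
      gene = rep(wide$gene, times = n_pts),
      sample = rep(samples, each = nrow(wide)),
      count = unlist(cts))
    count_table(long, smap, species = sp)
  })
  stats::setNames(out, sp_list)
}

#' Simulate a knockout phenotype-call table
#'
#' Planted-shift genes receive a phenotype in their shift stage (transition
#' t manifests in stage t + 1) with the configured concordance probability,
#' otherwise a uniformly chosen other stage class; non-planted genes are
#' wild type with high probability, otherwise a random stage class.
#'
#' @param evo A `gene_evolution` object (its `planted` table defines the
#'   shifted genes) or the `planted` tibble itself.
#' @param cfg A [generator_config()].
#' @param species Species label recorded in the table.
#' @param seed Overrides `cfg$seed` when given.
#' @return A phenotype tibble (`species`, `gene`, `phenotype`).
#' @export
simulate_phenotypes <- function(evo, cfg = generator_config(),
                                species = "N.crassa", seed = NULL) {
  planted <- if (inherits(evo, "gene_evolution")) evo$planted else evo
  genes <- if (inherits(evo, "gene_evolution")) evo$rates$gene else planted$gene
  withr::local_seed(if (is.null(seed)) cfg$seed else seed)
  stage_classes <- paste0("Stage-", 1:5)
  pheno <- vapply(genes, function(g) {
    i <- match(g, planted$gene)
    if (!is.na(i)) {
      true_stage <- min(planted$transition[i] + 1L, 5L)
      if (stats::runif(1) < cfg$concordance_prob) stage_classes[true_stage]
      else sample(stage_classes[-true_stage], 1)
    } else if (stats::runif(1) < cfg$wt_prob) "WT"
    else sample(stage_classes, 1)
  }, character(1))
  tibble::tibble(species = species, gene = genes, phenotype = unname(pheno))
}
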