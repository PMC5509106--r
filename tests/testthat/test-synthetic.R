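test_that("the chronogram matches its configuration", {
  chron <- make_chronogram()
  chk <- check_ultrametric(chron)
  expect_true(chk$ultrametric)
  depth <- max(ape::node.depth.edgelength(chron))
  expect_equal(depth, 220)
  expect_setequal(chron$node.label, c("MRCA-NF", "MRCA-F", "MRCA-N", "N-core"))
  expect_error(generator_config(age_n = 10, age_nn = 15), "decrease")
  expect_error(generator_config(shift_fraction = 1.2), "shift_fraction")
  expect_error(generator_config(shift_transition = 5L), "exceeds")
})

test_that("degenerate Brownian motion leaves all tips at the root value", {
  cfg <- generator_config(n_genes = 20, rate_meanlog = -Inf, rate_sdlog = 0,
                          shift_fraction = 0)
  evo <- simulate_gene_evolution(make_chronogram(cfg), cfg)
  expect_true(all(evo$fold_changes$d == 0))
  expect_true(all(evo$truth$d == 0))
})

test_that("planted stem shifts are inherited by the whole clade", {
  cfg <- generator_config(n_genes = 2000, shift_fraction = 0.1,
                          shift_magnitude = 4, seed = 13)
  evo <- simulate_gene_evolution(make_chronogram(cfg), cfg)
  d4 <- evo$fold_changes |>
    dplyr::filter(.data$transition == 4, .data$gene %in% evo$planted$gene) |>
    tidyr::pivot_wider(names_from = "species", values_from = "d")
  gaps <- rowMeans(d4[, c("N.crassa", "N.discreta", "N.tetrasperma")]) -
    rowMeans(d4[, c("F.graminearum", "F.verticillioides")])
  expect_equal(mean(gaps), 4, tolerance = 0.1)
  # the shifted clade's crown ancestor carries the offset in the ground truth
  anc4 <- evo$truth |>
    dplyr::filter(.data$node == "MRCA-N", .data$transition == 4,
                  .data$gene %in% evo$planted$gene)
  expect_gt(mean(anc4$d), 3)
})

test_that("tip variance and covariance follow the BM identities", {
  cfg <- generator_config(n_genes = 10000, rate_meanlog = log(2), rate_sdlog = 0,
                          shift_fraction = 0, seed = 17)
  chron <- make_chronogram(cfg)
  evo <- simulate_gene_evolution(chron, cfg)
  w <- function(sp, t) dplyr::filter(evo$fold_changes, .data$species == sp,
                                     .data$transition == t)$d
  expect_equal(stats::var(w("N.crassa", 1)), 2 * 220, tolerance = 0.05)
  expect_equal(stats::var(w("F.graminearum", 3)), 2 * 220, tolerance = 0.05)
  # shared path of the two closest species: root depth minus their split age
  expect_equal(stats::cov(w("N.crassa", 2), w("N.tetrasperma", 2)),
               2 * (220 - 15), tolerance = 0.05)
  expect_equal(stats::cov(w("N.crassa", 2), w("F.graminearum", 2)), 0,
               tolerance = 20)   # absolute scale ~ sd 440/sqrt(1e4) = 4.4
})

test_that("the generator is fully reproducible under a fixed seed", {
  cfg <- generator_config(n_genes = 50, seed = 123)
  chron <- make_chronogram(cfg)
  e1 <- simulate_gene_evolution(chron, cfg)
  e2 <- simulate_gene_evolution(chron, cfg)
  expect_identical(e1, e2)
  prof <- fold_change_to_profile(dplyr::rename(e1$fold_changes, node = "species")) |>
    dplyr::rename(species = "node")
  c1 <- simulate_counts(prof, cfg)
  c2 <- simulate_counts(prof, cfg)
  expect_identical(c1, c2)
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  prof <- tidyr::expand_grid(species = "N.crassa",
                             gene = sprintf("g%03d", 1:150), stage = 1:5)
  prof$x <- 2   # flat profiles: all stage means equal
  cfg0 <- generator_config(n_genes = 150, dispersion = 0, depth = 3e5, seed = 31)
  ct <- simulate_counts(prof, cfg0)[["N.crassa"]]
  # variance/mean across genes at one stage should be near 1 (Poisson)
  s1 <- ct$counts |> dplyr::filter(.data$sample == "Ncrassa_t01")
  expect_equal(stats::var(s1$count) / mean(s1$count), 1, tolerance = 0.25)
  # flat profile: per-sample totals agree across stages within sampling error
  tots <- ct$counts |> dplyr::group_by(.data$sample) |>
    dplyr::summarise(n = sum(.data$count))
  expect_lt(diff(range(tots$n)) / mean(tots$n), 0.02)

  cfg1 <- generator_config(n_genes = 150, dispersion = 0.5, depth = 3e5, seed = 31)
  ct1 <- simulate_counts(prof, cfg1)[["N.crassa"]]
  s1d <- ct1$counts |> dplyr::filter(.data$sample == "Ncrassa_t01")
  expect_gt(stats::var(s1d$count) / mean(s1d$count), 10)  # overdispersed
  # sampling design: 8 Neurospora points, 6 Fusarium points, 5 stages
  expect_equal(dplyr::n_distinct(ct$counts$sample), 8)
  proff <- dplyr::mutate(prof, species = "F.graminearum")
  ctf <- simulate_counts(proff, cfg0)[["F.graminearum"]]
  expect_equal(dplyr::n_distinct(ctf$counts$sample), 6)
  expect_equal(max(ctf$stage_map$stage), 5)
})

test_that("phenotype simulation honours the concordance probability", {
  cfg1 <- generator_config(n_genes = 200, shift_fraction = 0.2,
                           concordance_prob = 1, seed = 41)
  evo <- simulate_gene_evolution(make_chronogram(cfg1), cfg1)
  ph1 <- simulate_phenotypes(evo, cfg1)
  planted_ph <- ph1$phenotype[ph1$gene %in% evo$planted$gene]
  expect_true(all(planted_ph == "Stage-5"))   # shift at t4 manifests at stage 5

  cfg0 <- generator_config(n_genes = 200, shift_fraction = 0.2,
                           concordance_prob = 0, seed = 41)
  ph0 <- simulate_phenotypes(evo, cfg0)
  planted0 <- ph0$phenotype[ph0$gene %in% evo$planted$gene]
  expect_false(any(planted0 == "Stage-5"))    # always a different stage class
  expect_true(all(planted0 %in% paste0("Stage-", 1:4)))
})
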