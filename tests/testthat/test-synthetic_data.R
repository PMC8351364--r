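small_cfg <- function(seed = 7, ...) {
  simulation_config(seed = seed, n_loci = 40, n_genes = 12,
                    n_chromosomes = 2, ...)
}

test_that("simulation is byte-identical under the same seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(small_cfg(), out_dir = d1)
  simulate_cohort(small_cfg(), out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  d3 <- withr::local_tempdir()
  simulate_cohort(small_cfg(seed = 8), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "diagnosis.epiread")),
                         readLines(file.path(d3, "diagnosis.epiread"))))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(depth_mean = 40, min_depth = 60),
               "at least min_depth")
  expect_error(simulation_config(planted_events = data.frame(
    category = c("selection", "disorder"), fraction = c(0.6, 0.5))),
    "sum to at most 1")
  expect_error(simulation_config(planted_events = data.frame(
    category = "meltdown", fraction = 0.1)), "unknown planted event")
  expect_error(simulation_config(n_genes = 50, n_loci = 20), "cannot exceed")
})

test_that("planted stage pairs satisfy their category definitions", {
  sim <- simulate_cohort(simulation_config(seed = 21, n_loci = 300,
                                           n_genes = 30))
  tr <- sim$truth$loci
  base <- sim$truth$distributions$npc_base
  diag <- sim$truth$distributions$diagnosis
  for (cat in c("selection", "disorder", "switch", "disorder_maintenance")) {
    idx <- which(tr$category == cat)
    expect_gt(length(idx), 0)
    for (i in idx)
      expect_equal(classify_change(base[i, ], diag[i, ]), cat)
  }
  for (i in which(tr$category == "hyper_shift"))
    expect_gte(tr$meth_diagnosis[i] - tr$meth_npc[i], 0.25)
  for (i in which(tr$category == "hypo_shift"))
    expect_lte(tr$meth_diagnosis[i] - tr$meth_npc[i], -0.25)
  # null loci have identical baseline and diagnosis truth
  nulls <- which(tr$category == "null")
  expect_equal(diag[nulls, ], base[nulls, ])
})

test_that("relapse events respect their stage-1 eligibility", {
  sim <- simulate_cohort(simulation_config(seed = 22, n_loci = 300,
                                           n_genes = 30))
  tr <- sim$truth$loci
  diag <- sim$truth$distributions$diagnosis
  rel <- sim$truth$distributions$relapse
  sel <- which(tr$category_relapse == "selection")
  expect_gt(length(sel), 0)
  for (i in sel)
    expect_equal(classify_change(diag[i, ], rel[i, ]), "selection")
  nulls <- which(tr$category_relapse == "null")
  expect_equal(rel[nulls, ], diag[nulls, ])
})

test_that("empirical pattern frequencies recover the truth at high depth", {
  cfg <- simulation_config(seed = 13, n_loci = 20, n_genes = 6,
                           depth_mean = 10000, min_depth = 10000,
                           dropout_rate = 0)
  sim <- simulate_cohort(cfg)
  pat <- enumerate_loci(sim$epireads$diagnosis,
                        epishift_config(min_locus_depth = 60))
  truth <- sim$truth$loci
  m <- epishift:::.counts_matrix(pat)
  p_hat <- m / rowSums(m)
  idx <- match(pat$locus_id, truth$locus_id)
  expect_false(anyNA(idx))
  tv <- vapply(seq_len(nrow(pat)), function(i)
    sum(abs(p_hat[i, ] - sim$truth$distributions$diagnosis[idx[i], ])) / 2,
    numeric(1))
  expect_lt(max(tv), 0.02)
})

test_that("depth is clamped at the floor so no locus fails the filter", {
  sim <- simulate_cohort(small_cfg())
  for (s in names(sim$epireads)) {
    pat <- enumerate_loci(sim$epireads[[s]])
    expect_equal(nrow(pat), 40L)
    expect_true(all(pat$depth >= 60))
  }
})

test_that("the PMD set approximates the requested genome fraction", {
  sim <- simulate_cohort(simulation_config(seed = 30, n_loci = 400,
                                           n_genes = 40,
                                           pmd_genome_fraction = 0.65))
  per_chrom <- ceiling(400 / 2)
  genome <- 2 * (per_chrom * 5000 + 2000)
  cov <- region_summary(sim$regions$pmd, genome)$genome_coverage
  expect_gt(cov, 0.45)
  expect_lt(cov, 0.85)
})

test_that("coupled genes track promoter methylation; decoupled do not", {
  cfg <- simulation_config(seed = 1, n_loci = 1100, n_genes = 1000)
  sim <- simulate_cohort(cfg)
  g <- sim$truth$genes
  meth <- epishift:::.row_meth(sim$truth$distributions$diagnosis)[g$locus_index]
  lfpm <- log2(sim$expression$diagnosis)
  r_dec <- cor(meth[!g$coupled], lfpm[!g$coupled])
  expect_lt(abs(r_dec), 0.1)
  r_cpl <- cor(meth[g$coupled], lfpm[g$coupled])
  expect_lt(r_cpl, -0.5)
})

test_that("zero-noise coupled expression is exactly monotone in methylation", {
  cfg <- simulation_config(seed = 2, n_loci = 60, n_genes = 40,
                           expression_coupled_noise_sd = 0)
  sim <- simulate_cohort(cfg)
  g <- sim$truth$genes
  meth <- epishift:::.row_meth(sim$truth$distributions$diagnosis)[g$locus_index]
  lfpm <- log2(sim$expression$diagnosis)
  cp <- g$coupled
  expect_equal(lfpm[cp], 4 - 6 * meth[cp], tolerance = 1e-12)
})

test_that("dropout mode emits missing calls that loci handling tolerates", {
  cfg <- small_cfg(dropout_rate = 0.1, depth_mean = 120)
  sim <- simulate_cohort(cfg)
  calls <- sim$epireads$diagnosis$calls
  expect_true(any(grepl(".", calls, fixed = TRUE)))
  pat <- enumerate_loci(sim$epireads$diagnosis)
  expect_true(all(pat$depth >= 60))
})
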