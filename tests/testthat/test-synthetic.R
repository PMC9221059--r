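test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_proteins = 50, n_tumor = 20, n_healthy = 3,
                          n_modules = 4, module_loading = 2, noise_sd = 1,
                          de_fraction = 0.2, seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$matrix$values, d2$matrix$values)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(synthetic_config(n_proteins = 50, n_tumor = 20,
                                          n_healthy = 3, seed = 8))
  expect_false(identical(d1$matrix$values, d3$matrix$values))
})

test_that("dimensions, groups and planted-truth invariants hold", {
  cfg <- synthetic_config(n_proteins = 97, n_tumor = 31, n_healthy = 4,
                          n_modules = 5, submodules_per_module = 2,
                          de_fraction = 0.3, seed = 3)
  ds <- generate_dataset(cfg)
  expect_equal(dim(ds$matrix$values), c(97, 35))
  expect_equal(unname(table(ds$matrix$group)[c("tumor", "healthy")]),
               c(31L, 4L), ignore_attr = TRUE)
  # every protein has exactly one (module, submodule), submodule nested
  expect_equal(nrow(ds$truth), 97)
  expect_true(all(startsWith(ds$truth$submodule,
                             paste0("M", ds$truth$module, "."))))
  # de fraction realized up to rounding
  expect_equal(sum(ds$truth$de_sign != 0), round(0.3 * 97))
})

test_that("zero missing rate gives a complete matrix; rate is respected", {
  ds0 <- generate_dataset(synthetic_config(n_proteins = 100, n_tumor = 30,
                                           missing_rate = 0, seed = 1))
  expect_identical(sum(is.na(ds0$matrix$values)), 0L)
  ds <- generate_dataset(synthetic_config(n_proteins = 300, n_tumor = 50,
                                          missing_rate = 0.1, seed = 2))
  expect_equal(mean(is.na(ds$matrix$values)), 0.1, tolerance = 0.1)
})

test_that("planted correlation structure matches the factor model", {
  # flat hierarchy: within-module correlation lambda^2 / (lambda^2 + sd^2)
  cfg <- synthetic_config(n_proteins = 60, n_tumor = 200, n_healthy = 3,
                          n_modules = 3, submodules_per_module = 1,
                          module_loading = 2, noise_sd = 1,
                          de_fraction = 0, missing_rate = 0, seed = 5)
  ds <- generate_dataset(cfg)
  cors <- cor(t(ds$matrix$values))
  same <- outer(ds$truth$module, ds$truth$module, "==") & upper.tri(cors)
  expect_equal(mean(cors[same]), 4 / 5, tolerance = 0.05)
  # cross-module correlations center on zero
  expect_lt(abs(mean(cors[!same & upper.tri(cors)])), 0.05)
  # no signal at zero loading
  cfg0 <- synthetic_config(n_proteins = 60, n_tumor = 200, n_healthy = 3,
                           n_modules = 3, submodules_per_module = 1,
                           module_loading = 0, noise_sd = 5,
                           de_fraction = 0, missing_rate = 0, seed = 6)
  ds0 <- generate_dataset(cfg0)
  cors0 <- cor(t(ds0$matrix$values))
  expect_lt(abs(mean(cors0[same])), 0.05)
})

test_that("planted tumor shift moves the group means by de_effect", {
  cfg <- synthetic_config(n_proteins = 200, n_tumor = 100, n_healthy = 50,
                          n_modules = 1, submodules_per_module = 1,
                          module_loading = 0, noise_sd = 1,
                          de_fraction = 0.5, de_effect = 2,
                          missing_rate = 0, seed = 9)
  ds <- generate_dataset(cfg)
  tum <- rowMeans(ds$matrix$values[, samples_in_group(ds$matrix, "tumor")])
  hea <- rowMeans(ds$matrix$values[, samples_in_group(ds$matrix, "healthy")])
  lfc <- tum - hea
  expect_equal(mean(lfc[ds$truth$de_sign == 1]), 2, tolerance = 0.15)
  expect_equal(mean(lfc[ds$truth$de_sign == -1]), -2, tolerance = 0.15)
  expect_equal(mean(lfc[ds$truth$de_sign == 0]), 0, tolerance = 0.15)
})

test_that("module-aligned regimes plant coherent signs and chromosomes", {
  cfg <- synthetic_config(n_proteins = 80, n_tumor = 20, n_modules = 4,
                          submodules_per_module = 1, de_fraction = 1,
                          de_pattern = "module",
                          chromosome_pattern = "module", seed = 13)
  ds <- generate_dataset(cfg)
  per_mod_signs <- tapply(ds$truth$de_sign, ds$truth$module,
                          function(s) length(unique(s)))
  expect_true(all(per_mod_signs == 1))
  per_mod_chrom <- tapply(ds$truth$chromosome, ds$truth$module,
                          function(s) length(unique(s)))
  expect_true(all(per_mod_chrom == 1))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(synthetic_config(n_proteins = 0), "n_proteins")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(de_fraction = 1.2), "de_fraction")
  expect_error(synthetic_config(n_proteins = 5, n_modules = 3,
                                submodules_per_module = 2),
               "submodules_per_module")
})

test_that("written datasets round-trip through the text readers", {
  ds <- generate_dataset(synthetic_config(n_proteins = 30, n_tumor = 12,
                                          n_healthy = 3, missing_rate = 0.1,
                                          seed = 4))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  m2 <- read_expression_matrix(file.path(dir, "matrix.tsv"), metadata = md)
  expect_identical(m2$values, ds$matrix$values)
  expect_identical(m2$group, ds$matrix$group)
  cm <- read_chromosome_map(file.path(dir, "chromosomes.tsv"))
  expect_identical(unname(cm[ds$truth$protein]), ds$truth$chromosome)
})
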