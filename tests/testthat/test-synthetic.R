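test_that("generation is deterministic under a fixed seed", {
  s1 <- generate_synthetic(tiny_config())
  s2 <- generate_synthetic(tiny_config())
  expect_identical(unclass(s1$expr), unclass(s2$expr))
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$truth$true_edges, s2$truth$true_edges)
  s3 <- generate_synthetic(tiny_config(seed = 12))
  expect_false(identical(unclass(s1$expr), unclass(s3$expr)))
})

test_that("a near-noiseless conserved module is perfectly coherent", {
  cfg <- synthetic_config(
    n_clusters = 2, samples_per_cluster = c(10L, 10L),
    modules = list(module_spec(10, "conserved")),
    n_background_genes = 0, noise_sd = 1e-8, grn = NULL, seed = 5)
  sim <- generate_synthetic(cfg)
  lg <- log2(unclass(sim$expr))   # log scale recovers the linear factor model
  cc <- abs(cor(t(lg)))
  expect_gt(min(cc), 0.999999)
})

test_that("specific modules are tighter at home than across clusters", {
  sim <- generate_synthetic(tiny_config())
  truth <- sim$truth
  spec_mod <- truth$modules$module[truth$modules$kind == "specific"][1]
  home <- truth$modules$home_cluster[truth$modules$module == spec_mod]
  parent <- truth$modules$parent[truth$modules$module == spec_mod]
  genes <- names(truth$true_module)[truth$true_module == spec_mod]
  pgenes <- names(truth$true_module)[truth$true_module == parent]
  lg <- log2(unclass(sim$expr) + 1)
  home_s <- names(truth$true_cluster)[truth$true_cluster == home]
  away_s <- names(truth$true_cluster)[truth$true_cluster != home]
  mean_abs_pcc <- function(m) { cc <- abs(cor(t(m))); mean(cc[upper.tri(cc)]) }
  # rewiring: at home the private factor binds the specific genes and
  # decouples them from their parent module; away from home they follow
  # the parent factor
  expect_gt(mean_abs_pcc(lg[genes, home_s]),
            mean(abs(cor(t(lg[genes, home_s]), t(lg[pgenes, home_s])))))
  expect_gt(mean(abs(cor(t(lg[genes, away_s]), t(lg[pgenes, away_s])))),
            mean(abs(cor(t(lg[genes, home_s]), t(lg[pgenes, home_s])))))
})

test_that("background dropout calibrates the expression filter", {
  sim <- generate_synthetic(synthetic_config(seed = 77))
  truth <- sim$truth
  bg <- names(truth$true_module)[truth$true_module == "background"]
  frac_low <- mean(rowMeans(unclass(sim$expr)[bg, ]) <= 2)
  expect_lt(abs(frac_low - 0.3), 0.05)
  # module genes always pass the filter
  mod <- names(truth$true_module)[truth$true_module != "background"]
  expect_true(all(rowMeans(unclass(sim$expr)[mod, ]) > 2))
})

test_that("truth bookkeeping is consistent", {
  sim <- generate_synthetic(tiny_config())
  truth <- sim$truth
  expect_setequal(names(truth$true_module), rownames(sim$expr))
  expect_setequal(names(truth$true_cluster), colnames(sim$expr))
  spec <- truth$modules[truth$modules$kind == "specific", ]
  expect_true(all(!is.na(spec$home_cluster)))
  expect_true(all(spec$parent %in% truth$modules$module))
  # every regulator and edge gene is a gene of the GRN host module
  host_genes <- names(truth$true_module)[truth$true_module == truth$grn_module]
  expect_true(all(sim$regulators %in% host_genes))
  expect_true(all(truth$true_edges$target %in% host_genes))
  # specificity labels partition the genes
  expect_setequal(unique(truth$specificity_label),
                  c("conserved", "specific", "background"))
})

test_that("written dataset re-loads to the in-memory objects", {
  sim <- generate_synthetic(tiny_config())
  dir <- withr::local_tempdir()
  paths <- write_synthetic(sim, dir)
  e2 <- load_expression(paths[["expression"]])
  expect_equal(unclass(e2), unclass(sim$expr))
  m2 <- load_metadata(paths[["metadata"]])
  expect_equal(m2, sim$metadata)
  a2 <- load_annotation(paths[["annotation"]])
  expect_setequal(paste(a2$gene, a2$bin),
                  paste(sim$annotation$gene, sim$annotation$bin))
  expect_identical(readLines(paths[["regulators"]]), sim$regulators)
})

test_that("invalid configurations name the offending field", {
  expect_error(synthetic_config(samples_per_cluster = c(2L, 40L, 40L, 40L)),
               "samples_per_cluster")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(background_dropout = 1.5),
               "background_dropout")
  expect_error(
    synthetic_config(modules = list(module_spec(50, "specific",
                                                home_cluster = 9))),
    "modules")
  expect_error(module_spec(10, "specific"), "home_cluster")
})
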