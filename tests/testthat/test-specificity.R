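test_that("gmc is the Pearson correlation of the displayed formula", {
  e <- rnorm(50)
  expect_equal(gmc(e, e), 1)
  expect_equal(gmc(e, -e), -1)
  # hand computation: g=(1,2,3), eg=(1,2,4) -> 3/sqrt(2*42/9)
  expect_equal(gmc(c(1, 2, 3), c(1, 2, 4)), 0.981981, tolerance = 1e-6)
  expect_error(gmc(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(gmc(1:2, 1:2), "3 samples")
})

test_that("cdv attains its extremes on constructed profiles", {
  set.seed(1)
  e <- rnorm(50)
  expect_equal(cdv(e, e, -e), 2)           # printed maximum
  expect_equal(cdv(e, -e, e), -2)
  expect_equal(cdv(e, e, e), 0)            # perfectly conserved gene
})

test_that("compute_gmc_table returns one bounded row per assigned gene", {
  set.seed(2)
  f <- rnorm(30)
  m <- rbind(g1 = f, g2 = f + rnorm(30, sd = 0.2),
             g3 = rnorm(30), g4 = rnorm(30))
  colnames(m) <- paste0("s", 1:30)
  expr <- expression_matrix(m, "log2")
  part <- module_partition(c(g1 = "A", g2 = "A", g3 = "B",
                             g4 = "unassigned"), "global")
  eig <- compute_eigengenes(expr, part)
  tab <- compute_gmc_table(expr, part, eig)
  expect_setequal(tab$gene, c("g1", "g2", "g3"))
  expect_true(all(tab$gmc >= -1 & tab$gmc <= 1))
  expect_true(all(tab$n_samples == 30))
  # single-gene module: gmc exactly 1 up to sign convention
  expect_equal(tab$gmc[tab$gene == "g3"], 1, tolerance = 1e-9)
})

test_that("cdv table satisfies the defining identity and the floor gate", {
  w_small <- local({
    sim <- generate_synthetic(tiny_config())
    filt <- filter_genes(sim$expr, sim$annotation)
    lg <- log_transform(filt)
    cl <- cluster_assignment(sim$truth$true_cluster[colnames(lg)])
    gl <- build_modules(lg, network_config(min_module_size = 15), "global")
    s <- cluster_samples(cl, 1)
    sub <- cdvnet:::subset_expr(lg, samples = s)
    pc <- build_modules(sub, network_config(min_module_size = 15), "cluster_1")
    list(ct = compute_cdv_table(lg, s, 1, gl$partition, gl$eigengenes,
                                pc$partition, pc$eigengenes),
         gl = gl, pc = pc, lg = lg, s = s)
  })
  ct <- w_small$ct
  el <- ct[ct$eligible, ]
  expect_gt(nrow(el), 0)
  expect_equal(el$cdv, el$gmc_cluster - el$gmc_global_restricted)
  expect_true(all(is.na(ct$cdv[!ct$eligible])))
  expect_true(all(el$gmc_cluster >= 0.6 & el$gmc_global_full >= 0.6))
  expect_true(all(el$cdv >= -2 & el$cdv <= 2))
  expect_true(all(ct$gmc_cluster >= -1 & ct$gmc_cluster <= 1, na.rm = TRUE))
  # ineligible rows carry a reason
  expect_true(all(!is.na(ct$reason[!ct$eligible])))
  # an impossible floor empties the eligible set
  ct2 <- compute_cdv_table(w_small$lg, w_small$s, 1,
                           w_small$gl$partition, w_small$gl$eigengenes,
                           w_small$pc$partition, w_small$pc$eigengenes,
                           gmc_floor = 1.5)
  expect_true(all(!ct2$eligible))
})

test_that("fms matches hand counts and brute-force pair enumeration", {
  p <- setNames(c(1, 1, 2, 2), letters[1:4])
  q <- setNames(c(1, 2, 1, 2), letters[1:4])
  expect_equal(fms(p, p), 1)
  expect_equal(fms(p, q), 0)
  q2 <- setNames(c(1, 1, 2, 2), letters[1:4])
  p2 <- setNames(c(1, 1, 1, 2), letters[1:4])
  expect_equal(fms(p2, q2), 1 / sqrt(6), tolerance = 1e-12)
  expect_error(fms(setNames("x", "a"), setNames("y", "a")), "fewer than 2")
})

test_that("fms and amis agree with oracles on all small partitions", {
  parts <- all_partitions(5, max_blocks = 3)
  ids <- letters[1:5]
  ref <- parts[[8]]
  for (p in parts) {
    pv <- setNames(p, ids); rv <- setNames(ref, ids)
    expect_equal(fms(pv, rv), brute_fms(p, ref), tolerance = 1e-12)
    expect_equal(amis(pv, rv), brute_amis(p, ref), tolerance = 1e-10)
  }
  # a denser sweep of random pairs at n = 8
  set.seed(11)
  ids8 <- letters[1:8]
  for (i in 1:25) {
    p <- sample(1:3, 8, replace = TRUE)
    q <- sample(1:3, 8, replace = TRUE)
    expect_equal(fms(setNames(p, ids8), setNames(q, ids8)), brute_fms(p, q),
                 tolerance = 1e-12)
    expect_equal(amis(setNames(p, ids8), setNames(q, ids8)), brute_amis(p, q),
                 tolerance = 1e-10)
  }
})

test_that("expected MI matches exhaustive permutation averaging", {
  # the hypergeometric-model E[MI] is by definition the average MI over
  # all relabelings; check it exactly on tiny vectors
  p <- c(1, 1, 2, 2, 3)
  q <- c(1, 2, 1, 2, 2)
  expect_equal(brute_emi(p, q), perm_emi(p, q), tolerance = 1e-10)
  expect_equal(cdvnet:::expected_mi(as.vector(table(p)), as.vector(table(q)),
                                    5),
               perm_emi(p, q), tolerance = 1e-10)
})

test_that("amis handles its conventions", {
  ids <- letters[1:6]
  p <- setNames(c(1, 1, 2, 2, 3, 3), ids)
  expect_equal(amis(p, p), 1)
  relab <- setNames(c(7, 7, 5, 5, 9, 9), ids)   # label permutation
  expect_equal(amis(p, relab), 1)
  single <- setNames(rep(1, 6), ids)
  expect_equal(amis(single, single), 1)          # convention
})

test_that("the CDV threshold sweep retains nested gene sets", {
  set.seed(21)
  genes <- paste0("g", 1:60)
  ct <- data.frame(gene = genes, cluster = 1,
                   cluster_module = sample(c("A", "B"), 60, TRUE),
                   global_module = sample(c("A", "B"), 60, TRUE),
                   gmc_cluster = runif(60, 0.6, 1),
                   gmc_global_full = runif(60, 0.6, 1),
                   gmc_global_restricted = runif(60, -1, 1),
                   eligible = TRUE, reason = NA_character_)
  ct$cdv <- ct$gmc_cluster - ct$gmc_global_restricted
  gl <- setNames(ct$global_module, genes)
  cl <- setNames(ct$cluster_module, genes)
  sw <- cdv_threshold_sweep(ct, gl, cl, thresholds = seq(0, 2, 0.25))
  expect_false(is.unsorted(sw$n_genes))
  # at a threshold above max cdv the sweep equals the unrestricted score
  expect_equal(sw$fms[nrow(sw)], fms(gl, cl))
  expect_equal(sw$amis[nrow(sw)], amis(gl, cl))
  expect_error(cdv_threshold_sweep(ct, gl, cl, thresholds = c(0.5, 0.1)),
               "increasing")
})

test_that("function_cdv_matrix applies the strict bin-size gate", {
  genes <- paste0("g", 1:400)
  part <- module_partition(setNames(rep(c("A", "B"), each = 200), genes),
                           "cluster_1")
  # bin100 has exactly 100 genes (excluded); bin150 has 150 (kept)
  annot <- function_annotation(
    c(genes[1:100], genes[101:250]),
    c(rep("bin100", 100), rep("bin150", 150)))
  ct <- data.frame(gene = genes, cluster = 1,
                   cluster_module = part$labels, global_module = "A",
                   gmc_cluster = 0.9, gmc_global_full = 0.9,
                   gmc_global_restricted = 0.4,
                   cdv = c(rep(0.5, 200), rep(NA, 200)),
                   eligible = c(rep(TRUE, 200), rep(FALSE, 200)),
                   reason = NA_character_)
  fm <- function_cdv_matrix(ct, annot, part, min_bin_size = 100)
  expect_false("bin100" %in% fm$bin)
  expect_true("bin150" %in% fm$bin)
  # module B members in bin150 all lack a CDV: empty cell, no mean
  rowB <- fm[fm$group == "B" & fm$bin == "bin150", ]
  expect_true(rowB$empty)
  expect_true(is.na(rowB$mean_cdv))
  rowA <- fm[fm$group == "A" & fm$bin == "bin150", ]
  expect_equal(rowA$mean_cdv, 0.5)
  expect_false(rowA$empty)
})
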