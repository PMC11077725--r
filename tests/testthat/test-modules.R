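# Two noiseless planted modules driven by independent factors.
planted_two_modules <- function(n_per = 40, n_samples = 60, noise = 0.01,
                                seed = 14) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  m <- rbind(outer(rnorm(n_per, 1, 0.1), f1),
             outer(rnorm(n_per, 1, 0.1), f2)) +
    matrix(rnorm(2 * n_per * n_samples, sd = noise), 2 * n_per)
  dimnames(m) <- list(paste0("g", seq_len(2 * n_per)),
                      paste0("s", seq_len(n_samples)))
  list(expr = expression_matrix(m - min(m), "log2"),
       truth = rep(c("m1", "m2"), each = n_per), f1 = f1, f2 = f2)
}

test_that("TOM reproduces hand-computed values", {
  # three genes, all pairwise adjacencies 0.5 at beta = 1:
  # TOM_12 = (a13 a32 + a12) / (min(k1,k2) + 1 - a12) = 0.75 / 1.5
  set.seed(1)
  g1 <- rnorm(200)
  # construct exact pairwise correlations via orthogonalized noise
  orth <- function(x, y) { r <- resid(lm(y ~ x)); r / sd(r) }
  z1 <- (g1 - mean(g1)) / sd(g1)
  n2 <- orth(z1, rnorm(200)); n3a <- orth(z1, rnorm(200))
  n3 <- orth(n2, n3a)
  rho <- 0.5
  z2 <- rho * z1 + sqrt(1 - rho^2) * n2
  # want cor(z3, z1) = cor(z3, z2) = 0.5
  b <- (rho - rho^2) / sqrt(1 - rho^2)
  a <- rho
  z3 <- a * z1 + b * n2 + sqrt(1 - a^2 - b^2) * n3
  m <- rbind(g1 = z1, g2 = z2, g3 = z3)
  colnames(m) <- paste0("s", 1:200)
  expr <- expression_matrix(m, "log2")
  expect_equal(abs(cor(z1, z2)), 0.5, tolerance = 1e-10)
  expect_equal(abs(cor(z1, z3)), 0.5, tolerance = 1e-10)
  tom <- compute_tom(expr, beta = 1)
  expect_equal(tom["g1", "g2"], 0.75 / 1.5, tolerance = 1e-9)
})

test_that("TOM of duplicated and unrelated genes hits its extremes", {
  set.seed(2)
  x <- rnorm(50); y <- rnorm(50)
  m <- rbind(g1 = x, g2 = x + 1e-12 * rnorm(50))
  colnames(m) <- paste0("s", 1:50)
  tom <- compute_tom(expression_matrix(m, "log2"), 6)
  expect_equal(tom["g1", "g2"], 1, tolerance = 1e-6)
  # an uncorrelated pair with no shared neighbours: TOM == a (tiny)
  y <- resid(lm(y ~ x))
  m2 <- rbind(g1 = x, g2 = y / sd(y))
  colnames(m2) <- paste0("s", 1:50)
  tom2 <- compute_tom(expression_matrix(m2, "log2"), 6)
  a <- abs(cor(x, m2["g2", ]))^6
  expect_equal(tom2["g1", "g2"], a, tolerance = 1e-12)
})

test_that("TOM invariants hold on arbitrary data", {
  set.seed(3)
  m <- matrix(rnorm(40 * 30), 40, 30,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:30)))
  tom <- compute_tom(expression_matrix(m, "log2"), 6)
  expect_equal(tom, t(tom))
  expect_true(all(tom >= 0 & tom <= 1))
  expect_equal(unname(diag(tom)), rep(1, 40))
  m[1, ] <- 5
  expect_error(compute_tom(expression_matrix(m, "log2"), 6), "g1")
})

test_that("soft-threshold selection behaves per contract", {
  pm <- planted_two_modules(noise = 0.4)
  cfg1 <- network_config(power_grid = 2)
  expect_equal(pick_soft_threshold(pm$expr, cfg1)$power, 2)
  cfg <- network_config()
  st1 <- pick_soft_threshold(pm$expr, cfg)
  st2 <- pick_soft_threshold(pm$expr, cfg)
  expect_identical(st1, st2)
  expect_true(st1$power %in% cfg$power_grid)
  # structured data reaches the fit target at a power no higher than noise
  set.seed(4)
  noise <- matrix(rnorm(80 * 60), 80, 60,
                  dimnames = list(paste0("g", 1:80), paste0("s", 1:60)))
  st_noise <- pick_soft_threshold(expression_matrix(noise, "log2"), cfg)
  expect_lte(st1$power, st_noise$power)
})

test_that("two planted modules are detected with perfect membership", {
  pm <- planted_two_modules()
  tom <- compute_tom(pm$expr, 6)
  part <- detect_modules(tom, network_config(min_module_size = 30))
  expect_setequal(setdiff(unique(part$labels), "unassigned"), c("A", "B"))
  expect_equal(adjusted_rand_index(part$labels, pm$truth), 1)
  # permuting gene order changes nothing but labels
  perm <- sample(nrow(tom))
  part2 <- detect_modules(tom[perm, perm], network_config(min_module_size = 30))
  expect_equal(adjusted_rand_index(part2$labels[names(part$labels)],
                                   part$labels), 1)
  expect_error(detect_modules(tom, network_config(min_module_size = 1000)),
               "unassigned")
})

test_that("eigengenes satisfy their contracts", {
  pm <- planted_two_modules(noise = 1e-4)
  part <- module_partition(setNames(pm$truth, rownames(pm$expr)), "global")
  eig <- compute_eigengenes(pm$expr, part)
  expect_equal(rownames(eig), c("m1", "m2"))
  # unit variance and orientation
  expect_equal(unname(apply(eig, 1, sd)), c(1, 1), tolerance = 1e-9)
  v <- unclass(pm$expr)
  for (m in c("m1", "m2")) {
    cors <- cor(t(v[part$labels == m, ]), eig[m, ])
    expect_gte(mean(cors), 0)
  }
  # a noiseless module's eigengene recovers the latent factor
  expect_gte(abs(cor(eig["m1", ], pm$f1)), 0.999)
  # single-gene module: eigengene is the standardized gene
  single <- module_partition(c(g1 = "A"), "global")
  e1 <- compute_eigengenes(cdvnet:::subset_expr(pm$expr, genes = "g1"), single)
  expect_equal(abs(cor(e1["A", ], v["g1", ])), 1, tolerance = 1e-12)
  # duplicated gene pair
  m2 <- rbind(g1 = v[1, ], g2 = v[1, ] * 2 + 3)
  dup <- module_partition(c(g1 = "A", g2 = "A"), "global")
  e2 <- compute_eigengenes(expression_matrix(m2, "log2"), dup)
  expect_equal(abs(cor(e2["A", ], m2["g1", ])), 1, tolerance = 1e-9)
})

test_that("merging follows the eigengene-correlation threshold", {
  # two modules driven by factors with correlation ~0.8 merge at 0.25;
  # a third at correlation ~0.3 survives
  set.seed(6)
  n <- 100
  f1 <- rnorm(n)
  f2 <- 0.8 * f1 + sqrt(1 - 0.64) * rnorm(n)
  f3 <- 0.3 * f1 + sqrt(1 - 0.09) * rnorm(n)
  mk <- function(f, tag, size = 20)
    outer(rnorm(size, 1, 0.05), f) +
      matrix(rnorm(size * n, sd = 0.05), size)
  m <- rbind(mk(f1), mk(f2), mk(f3))
  dimnames(m) <- list(paste0("g", 1:60), paste0("s", 1:n))
  expr <- expression_matrix(m, "log2")
  part <- module_partition(setNames(rep(c("A", "B", "C"), each = 20),
                                    rownames(m)), "global")
  eig <- compute_eigengenes(expr, part)
  merged <- merge_modules(expr, part, eig, merge_height = 0.25)
  labs <- merged$partition$labels
  expect_equal(length(setdiff(unique(labs), "unassigned")), 2)
  # the f1/f2 modules fused, the f3 module did not
  expect_equal(length(unique(labs[1:40])), 1)
  expect_false(labs[41] %in% labs[1:40])
  # post-condition: no surviving pair at or above correlation 0.75
  cc <- cor(t(unclass(merged$eigengenes)))
  diag(cc) <- 0
  expect_lt(max(cc), 0.75)
})
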