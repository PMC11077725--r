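grn_fixture <- function(n = 40, seed = 31) {
  set.seed(seed)
  regs <- matrix(rnorm(10 * n), 10, n,
                 dimnames = list(paste0("r", 1:10), paste0("s", 1:n)))
  t1 <- 2 * regs["r1", ] + rnorm(n, sd = 0.05)
  t2 <- regs["r2", ] - regs["r3", ] + rnorm(n, sd = 0.2)
  m <- rbind(regs, t1 = t1, t2 = t2)
  expression_matrix(m - min(m) + 0.01, "tpm")
}

test_that("a dominant linear driver earns the top incoming weight", {
  expr <- grn_fixture()
  net <- infer_grn(expr, paste0("r", 1:10), targets = c("t1", "t2"),
                   n_trees = 300, seed = 5)
  e1 <- net$edges[net$edges$target == "t1", ]
  expect_equal(e1$regulator[which.max(e1$weight)], "r1")
  e2 <- net$edges[net$edges$target == "t2", ]
  top2 <- e2$regulator[order(-e2$weight)[1:2]]
  expect_setequal(top2, c("r2", "r3"))
})

test_that("incoming weights are normalized per target", {
  expr <- grn_fixture()
  net <- infer_grn(expr, paste0("r", 1:10), n_trees = 100, seed = 5)
  sums <- tapply(net$edges$weight, net$edges$target, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # a regulator never predicts itself
  expect_true(all(net$edges$regulator != net$edges$target))
})

test_that("inference is deterministic and sample-order invariant", {
  expr <- grn_fixture(seed = 7)
  a <- infer_grn(expr, paste0("r", 1:10), n_trees = 100, seed = 42)
  b <- infer_grn(expr, paste0("r", 1:10), n_trees = 100, seed = 42)
  expect_identical(a$edges, b$edges)
  set.seed(1)
  perm <- sample(ncol(expr))
  exprp <- cdvnet:::subset_expr(expr, samples = perm)
  cp <- infer_grn(exprp, paste0("r", 1:10), n_trees = 100, seed = 42)
  expect_lt(max(abs(a$edges$weight - cp$edges$weight)), 1e-12)
})

test_that("argument and degenerate-input contracts hold", {
  expr <- grn_fixture()
  small <- cdvnet:::subset_expr(expr, samples = 1:5)
  expect_error(infer_grn(small, "r1"), "10 samples")
  expect_error(infer_grn(expr, "nope"), "absent")
  expect_error(infer_grn(cdvnet:::subset_expr(expr, genes = "r1"), "r1"),
               "no candidate regulators")
})

test_that("filter_edges uses an inclusive bound", {
  net <- structure(list(
    edges = data.frame(regulator = c("r1", "r1", "r2"),
                       target = c("t1", "t2", "t1"),
                       weight = c(0.06, 0.059, 0.5)),
    nodes = data.frame(gene = c("r1", "r2", "t1", "t2"),
                       is_regulator = c(TRUE, TRUE, FALSE, FALSE))),
    class = "grn")
  f <- filter_edges(net, 0.06)
  expect_setequal(paste(f$edges$regulator, f$edges$target),
                  c("r1 t1", "r2 t1"))
  expect_warning(filter_edges(net, 0.9), "no edges")
  d <- filter_edges(net, 0.5, drop_isolated = TRUE)
  expect_setequal(d$nodes$gene, c("r2", "t1"))
})

test_that("GraphML export round-trips and omits absent attributes", {
  net <- structure(list(
    edges = data.frame(regulator = c("r1", "r2"), target = c("t1", "t1"),
                       weight = c(0.25, 0.125)),
    nodes = data.frame(gene = c("r1", "r2", "t1"),
                       is_regulator = c(TRUE, TRUE, FALSE))),
    class = "grn")
  ct <- data.frame(gene = c("r1", "t1"), cluster = 1,
                   cluster_module = "A", global_module = "A",
                   gmc_cluster = 0.9, gmc_global_full = 0.8,
                   gmc_global_restricted = 0.2, cdv = c(0.7, 0.45),
                   eligible = TRUE, reason = NA)
  annot <- function_annotation(c("r1", "r2"), c("BIN.TF", "BIN.TF"))
  path <- file.path(withr::local_tempdir(), "net.graphml")
  files <- annotate_and_export(net, ct, annot, path)
  expect_true(all(file.exists(files)))
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  edges <- xml2::xml_find_all(doc, ".//d1:edge", ns)
  expect_length(edges, 2)
  w <- as.numeric(xml2::xml_text(
    xml2::xml_find_all(doc, ".//d1:edge/d1:data[@key='weight']", ns)))
  expect_equal(sort(w), c(0.125, 0.25))
  # r2 has no CDV row: no cdv data element on its node
  nodes <- xml2::xml_find_all(doc, ".//d1:node", ns)
  ids <- xml2::xml_attr(nodes, "id")
  cdv_of <- function(i) xml2::xml_find_first(
    nodes[[i]], "./d1:data[@key='cdv']", ns)
  expect_false(inherits(cdv_of(which(ids == "r1")), "xml_missing"))
  expect_true(inherits(cdv_of(which(ids == "r2")), "xml_missing"))
  # SIF lists each edge once
  sif <- readLines(file.path(dirname(path), "net.sif"))
  expect_length(sif, 2)
})

test_that("the planted circuit is recovered from the synthetic world", {
  sim <- generate_synthetic(tiny_config())
  truth <- sim$truth
  host_genes <- names(truth$true_module)[truth$true_module == truth$grn_module]
  home <- truth$modules$home_cluster[truth$modules$module == truth$grn_module]
  home_s <- names(truth$true_cluster)[truth$true_cluster == home]
  lg <- log_transform(sim$expr)
  sub <- cdvnet:::subset_expr(lg, genes = host_genes, samples = home_s)
  net <- infer_grn(sub, sim$regulators, n_trees = 500, seed = 3)
  te <- truth$true_edges
  cand <- net$edges[net$edges$target %in% te$target, ]
  is_true <- paste(cand$regulator, cand$target) %in%
    paste(te$regulator, te$target)
  expect_gte(auroc(cand$weight, is_true), 0.8)
  # mean rank of the true regulator among candidates per target
  ranks <- vapply(unique(te$target), function(tg) {
    e <- cand[cand$target == tg, ]
    r <- rank(-e$weight)
    mean(r[paste(e$regulator, e$target) %in% paste(te$regulator, te$target)])
  }, numeric(1))
  expect_lte(mean(ranks), 2)
})
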