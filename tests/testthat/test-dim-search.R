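test_that("module activity is the column mean of the member rows", {
  ed <- make_expr(n_genes = 5, seed = 3)
  # single-gene module: identity
  expect_equal(module_activity("g1", ed), ed$values["g1", ])
  # brute-force column mean over a 3-gene module
  mem <- c("g1", "g3", "g5")
  expect_equal(module_activity(mem, ed),
               apply(ed$values[mem, ], 2, mean), tolerance = 1e-12)
  expect_error(module_activity(c("g1", "nope"), ed), "nope")
})

test_that("opposite rows cancel to zero activity", {
  rows <- list(g1 = c(1, -1, 1, -1), g2 = c(-1, 1, -1, 1), g3 = c(0, 1, 2, 3))
  ed <- make_expr_raw(rows, 2, 2)
  # after z-scoring the two rows are still exact negatives of each other
  expect_equal(unname(module_activity(c("g1", "g2"), ed)), rep(0, 4))
})

test_that("module score equals the absolute Welch t of module activity", {
  ed <- make_expr(n_genes = 6, n_tumor = 5, n_normal = 4, seed = 11)
  idx <- split(seq_along(ed$labels), ed$labels)
  for (mem in list("g2", c("g1", "g4"), c("g2", "g3", "g6"))) {
    act <- module_activity(mem, ed)
    oracle <- abs(stats::t.test(act[idx$tumor], act[idx$normal])$statistic)
    expect_equal(module_score(mem, ed), unname(oracle), tolerance = 1e-10)
  }
})

test_that("module score hits the hand-computed Welch value on 3v3 activity", {
  # single-gene module engineered so the z-scored row, split 3v3, gives
  # activities with |mean difference| = sd-scaled 1.2247 Welch statistic:
  # use the t.test oracle on the z-scored values directly
  rows <- list(g1 = c(1, 2, 3, 0, 1, 2), g2 = c(5, 3, 1, 2, 4, 6))
  ed <- make_expr_raw(rows, 3, 3)
  z <- ed$values["g1", ]
  oracle <- abs(stats::t.test(z[1:3], z[4:6])$statistic)
  expect_equal(module_score("g1", ed), unname(oracle), tolerance = 1e-10)
  # the raw activities (1,2,3) vs (0,1,2) give Welch |t| = 1.2247 by the
  # direct formula |dm| / sqrt(v1/n1 + v2/n2); z-scoring is affine so the
  # module score is identical
  expect_equal(module_score("g1", ed), 1 / sqrt(1 / 3 + 1 / 3), tolerance = 1e-6)
})

test_that("module score is scale invariant and zero for constant rows", {
  rows <- list(g1 = c(4, 5, 6, 1, 2, 3), g2 = c(1, 1, 1, 1, 1, 1))
  ed1 <- make_expr_raw(rows, 3, 3)
  ed2 <- make_expr_raw(lapply(rows, `*`, 7), 3, 3)
  expect_equal(module_score("g1", ed1), module_score("g1", ed2), tolerance = 1e-12)
  expect_identical(module_score("g2", ed1), 0)
})

test_that("a seed with no network neighbors terminates immediately", {
  ed <- make_expr(n_genes = 4, seed = 5)
  # g1's only neighbor is outside the expression data, so within the
  # search universe it is isolated and growth terminates at once
  net <- make_net(c("g1-zzz", "g2-g3"))
  res <- sample_candidate_dim("g1", net, ed)
  expect_identical(res$members[[1]], "g1")
  expect_equal(res$score, module_score("g1", ed))
  expect_error(sample_candidate_dim("absent", net, ed), "not in network")
})

test_that("star graph with one signal leaf is adopted deterministically", {
  # center g1 and leaf g2 share a strong tumor shift; leaves g3, g4 carry
  # the opposite shift so adding them always lowers the score
  ed <- make_expr(n_genes = 4, n_tumor = 6, n_normal = 6,
                  shifted = c("g1", "g2"), effect = 3, seed = 21)
  ed$values[c("g3", "g4"), 1:6] <- ed$values[c("g3", "g4"), 1:6] - 3
  ed <- expression_dataset(ed$values, ed$labels) # re-normalize after edit
  net <- make_net(c("g1-g2", "g1-g3", "g1-g4"))
  runs <- replicate(20, sort(sample_candidate_dim("g1", net, ed)$members[[1]]),
                    simplify = FALSE)
  expect_true(all(vapply(runs, identical, TRUE, y = c("g1", "g2"))))
})

test_that("returned modules are connected, contain the seed, and improve the score", {
  inst <- generate_instance(synthetic_spec(n_genes = 60, n_drivers = 6, seed = 8L))
  net <- inst$network
  ed <- inst$expression
  seed_gene <- inst$truth$planted_modules[[1]]$seed
  set.seed(99)
  for (i in 1:10) {
    res <- sample_candidate_dim(seed_gene, net, ed)
    mem <- res$members[[1]]
    expect_true(seed_gene %in% mem)
    sub <- igraph::induced_subgraph(net$graph, mem)
    expect_true(igraph::is_connected(sub))
    expect_equal(res$score, module_score(mem, ed), tolerance = 1e-10)
    if (length(mem) > 1) {
      expect_gt(res$score, module_score(seed_gene, ed))
    }
  }
})

test_that("candidate generation is reproducible and respects n_iter", {
  ed <- make_expr(n_genes = 8, shifted = c("g1", "g2"), effect = 2, seed = 13)
  net <- make_net(c("g1-g2", "g2-g3", "g3-g4", "g1-g5", "g5-g6", "g6-g7", "g7-g8"))
  cfg <- sampling_config(n_iter = 25L, seed = 7L)
  a <- generate_candidate_dims("g1", net, ed, cfg)
  b <- generate_candidate_dims("g1", net, ed, cfg)
  expect_equal(nrow(a), 25L)
  expect_identical(a$members, b$members)
  # n_iter = 1 with a fixed seed equals one sample_candidate_dim call
  # issued from the same RNG state
  one <- generate_candidate_dims("g1", net, ed, sampling_config(n_iter = 1L, seed = 3L))
  set.seed(3L)
  single <- sample_candidate_dim("g1", net, ed, sampling_config())
  expect_identical(one$members[[1]], single$members[[1]])
})

test_that("max_module_size caps growth", {
  ed <- make_expr(n_genes = 10, shifted = paste0("g", 1:10), effect = 3, seed = 17)
  net <- make_net(paste0("g", 1:9, "-g", 2:10))
  cfg <- sampling_config(n_iter = 5L, improvement_threshold = 0, max_module_size = 3L, seed = 1L)
  cands <- generate_candidate_dims("g5", net, ed, cfg)
  expect_true(all(lengths(cands$members) <= 3L))
})

test_that("permutation p-values match exhaustive 3v3 enumeration", {
  rows <- list(g1 = c(5, 6, 7, 1, 2, 3), g2 = c(1, 2, 3, 2.5, 1.5, 2),
               g3 = c(2, 2, 2, 2, 2, 2), g4 = c(0, 5, 1, 4, 2, 3))
  ed <- make_expr_raw(rows, 3, 3)
  idx <- utils::combn(6, 3)
  welch <- function(x, i) {
    a <- x[i]; b <- x[-i]
    d <- abs(mean(a) - mean(b))
    se <- sqrt(var(a) / 3 + var(b) / 3)
    if (se == 0) { if (d < 1e-12) 0 else Inf } else d / se
  }
  p_exh <- vapply(rownames(ed$values), function(g) {
    x <- ed$values[g, ]
    obs <- welch(x, 1:3)
    stats <- apply(idx, 2, function(i) welch(x, i))
    mean(stats >= obs - 1e-12)
  }, numeric(1))
  degs <- detect_degs(ed, n_perm = 4000L, alpha = 0.05, seed = 2L)
  expect_equal(unname(degs$p_value[match(names(p_exh), degs$gene)]), unname(p_exh),
               tolerance = 0.05)
  # constant gene is never differentially expressed
  expect_equal(unname(degs$p_value[degs$gene == "g3"]), 1, tolerance = 0.01)
  expect_false(degs$deg[degs$gene == "g3"])
})

test_that("module enrichment filtering matches the hypergeometric tail oracle", {
  universe <- paste0("u", 1:100)
  degs <- universe[1:10]
  cands <- tibble::tibble(seed = "u1",
                          members = list(universe[1:5],       # 5/5 DEGs
                                         universe[c(1, 2, 50, 60, 70)], # 2/5
                                         universe[50:54]),    # 0/5
                          score = c(3, 2, 1))
  dc <- filter_dims(cands, degs, universe, alpha = 0.05)
  # all-DEG candidate: p = C(10,5)/C(100,5), survives BH comfortably
  p_oracle <- choose(10, 5) / choose(100, 5)
  expect_true("u1" %in% unlist(dc$members[dc$size == 5 & dc$n_deg == 5]))
  expect_equal(dc$p_value[dc$n_deg == 5], p_oracle, tolerance = 1e-9)
  # 0-DEG candidate is never retained (enrichment p = 1)
  expect_false(any(dc$n_deg == 0))
  # enrichment p-values equal the exhaustive choose() tail on small universes
  set.seed(4)
  for (i in 1:20) {
    n_univ <- sample(20:200, 1)
    n_deg <- sample(2:10, 1)
    m <- sample(2:8, 1)
    k <- sample(0:min(m, n_deg), 1)
    got <- stats::phyper(k - 1, n_deg, n_univ - n_deg, m, lower.tail = FALSE)
    expect_equal(got, hyper_tail(k, n_deg, n_univ - n_deg, m), tolerance = 1e-9)
  }
})

test_that("duplicate candidate member sets are tested once but counted", {
  universe <- paste0("u", 1:50)
  degs <- universe[1:8]
  mem <- universe[1:4]
  cands <- tibble::tibble(seed = "u1", members = list(mem, mem, universe[1:3]),
                          score = c(1, 1, 1))
  dc <- filter_dims(cands, degs, universe, alpha = 0.05)
  expect_equal(sum(dc$size == 4), 1L)
  expect_equal(dc$count[dc$size == 4], 2L)
  expect_identical(attr(dc, "n_candidates"), 3L)
})

test_that("empty DEG set retains no candidates", {
  universe <- paste0("u", 1:30)
  cands <- tibble::tibble(seed = "u1", members = list(universe[1:3]), score = 1)
  expect_message(dc <- filter_dims(cands, character(), universe), "No differentially")
  expect_equal(nrow(dc), 0L)
})

test_that("convergence coverage is cumulative and monotone", {
  inst <- generate_instance(synthetic_spec(n_genes = 60, n_drivers = 8, seed = 15L))
  degs <- detect_degs(inst$expression, n_perm = 500L, seed = 1L)
  seed_gene <- inst$truth$planted_modules[[1]]$seed
  curve <- convergence_curve(seed_gene, inst$network, inst$expression, degs,
                             inst$drivers, sampling_config(n_iter = 60L, seed = 2L),
                             checkpoints = c(0L, 10L, 30L, 60L))
  expect_identical(curve$covered[[1]], character(0))
  for (i in 2:nrow(curve)) {
    expect_true(all(curve$covered[[i - 1]] %in% curve$covered[[i]]))
  }
})
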