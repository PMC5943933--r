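test_that("perfect co-occurrence and exclusivity hit the hypergeometric tail", {
  samples <- paste0("s", 1:20)
  # U = V, |U| = 10: enrichment tail p = 1 / C(20,10)
  mut <- make_mut(list(u = samples[1:10], v = samples[1:10]), samples)
  res <- cooccurrence_test("u", "v", mut)
  expect_equal(res$p_cooccur, 1 / choose(20, 10), tolerance = 1e-9)
  expect_identical(res$status, "co-occurring")
  # disjoint U, V of size 10: depletion tail p has the same value
  mut2 <- make_mut(list(u = samples[1:10], v = samples[11:20]), samples)
  res2 <- cooccurrence_test("u", "v", mut2)
  expect_equal(res2$p_exclusive, 1 / choose(20, 10), tolerance = 1e-9)
  expect_identical(res2$status, "mutually-exclusive")
  # one-sided tails match the exhaustive choose() oracle
  expect_equal(res$p_cooccur,
               fisher_greater_oracle(res$n_both, res$n_u_only,
                                     res$n_v_only, res$n_neither),
               tolerance = 1e-9)
})

test_that("genes without alterations are classified neither", {
  mut <- make_mut(list(u = c("s1", "s2"), v = character()), paste0("s", 1:5))
  res <- cooccurrence_test("u", "v", mut)
  expect_identical(res$status, "neither")
  expect_equal(res$p_cooccur, 1)
})

test_that("an edge is never both co-occurring and mutually exclusive", {
  set.seed(6)
  samples <- paste0("s", 1:30)
  for (i in 1:50) {
    mut <- make_mut(list(u = sample(samples, sample(1:20, 1)),
                         v = sample(samples, sample(1:20, 1))), samples)
    res <- cooccurrence_test("u", "v", mut)
    expect_false(res$p_cooccur < 0.05 && res$p_exclusive < 0.05)
  }
})

test_that("the two-sided variant uses the odds-ratio direction", {
  samples <- paste0("s", 1:20)
  mut <- make_mut(list(u = samples[1:10], v = samples[1:10]), samples)
  expect_identical(cooccurrence_test("u", "v", mut, two_sided = TRUE)$status,
                   "co-occurring")
  mut2 <- make_mut(list(u = samples[1:10], v = samples[11:20]), samples)
  expect_identical(cooccurrence_test("u", "v", mut2, two_sided = TRUE)$status,
                   "mutually-exclusive")
})

test_that("type-I error of co-occurrence calls is calibrated on independent profiles", {
  set.seed(20)
  samples <- paste0("s", 1:100)
  n_pairs <- 1000
  calls <- logical(n_pairs)
  for (i in seq_len(n_pairs)) {
    mut <- make_mut(list(u = samples[runif(100) < 0.3],
                         v = samples[runif(100) < 0.3]), samples)
    calls[i] <- cooccurrence_test("u", "v", mut)$status == "co-occurring"
  }
  expect_lte(mean(calls), 0.075)
})

test_that("edge classification fractions match a per-edge oracle loop", {
  samples <- paste0("s", 1:40)
  gamma <- list(a = samples[1:15], b = samples[1:15],       # co-occurring pair
                c = samples[1:15], d = samples[26:40],      # exclusive pair
                e = samples[c(1, 5, 30)], f = samples[c(2, 6, 31)])
  mut <- make_mut(gamma, samples)
  fn <- make_fn(c("a", "c", "e"), c("b", "d", "f"), c(0.9, 0.5, 0.2))
  res <- classify_network_edges(fn, mut, cutoffs = c(0, 0.4))
  per_edge <- vapply(seq_len(nrow(fn)), function(i)
    cooccurrence_test(fn$source[i], fn$target[i], mut)$status, character(1))
  expect_equal(res$frac_cooccur[res$cutoff == 0], mean(per_edge == "co-occurring"))
  expect_equal(res$frac_exclusive[res$cutoff == 0], mean(per_edge == "mutually-exclusive"))
  at04 <- res[res$cutoff == 0.4, ]
  expect_equal(at04$n_edges, 2L)
  expect_equal(at04$frac_cooccur, mean(per_edge[fn$weight >= 0.4] == "co-occurring"))
  # all-co-occurring network: fraction 1, false rate 0
  fn2 <- make_fn("a", "b", 0.8)
  res2 <- classify_network_edges(fn2, mut, cutoffs = 0)
  expect_equal(res2$frac_cooccur, 1)
  expect_equal(res2$frac_exclusive, 0)
  # disjointly mutated pair: false rate 1
  fn3 <- make_fn("c", "d", 0.8)
  res3 <- classify_network_edges(fn3, mut, cutoffs = 0)
  expect_equal(res3$frac_exclusive, 1)
})

test_that("signaling continuity follows directed reachability", {
  sig <- make_sig(c("d>x", "x>u", "u>y"))
  fn <- make_fn(c("d", "d", "u", "y", "q"),
                c("x", "u", "d", "x", "d"),
                c(0.5, 0.5, 0.5, 0.5, 0.5))
  res <- signaling_continuity(fn, sig)
  get <- function(s, t) res$continuity[res$source == s & res$target == t]
  expect_identical(get("d", "x"), "continuous")      # direct edge
  expect_identical(get("d", "u"), "continuous")      # via path d->x->u
  expect_identical(get("u", "d"), "discontinuous")   # direction matters
  expect_identical(get("y", "x"), "discontinuous")
  expect_identical(get("q", "d"), "unmapped")        # q not in signaling net
  # monotone: adding signaling edges never flips continuous -> discontinuous
  sig2 <- make_sig(c("d>x", "x>u", "u>y", "y>x", "u>d"))
  res2 <- signaling_continuity(fn, sig2)
  was_cont <- res$continuity == "continuous"
  expect_true(all(res2$continuity[was_cont] == "continuous"))
})

test_that("continuity enrichment reports counts and the Fisher oracle p", {
  # every fitness edge continuous; no background pair continuous
  sig <- make_sig(c("a>b", "c>d"))
  fn <- make_fn(c("a", "c"), c("b", "d"), c(0.5, 0.5))
  res <- continuity_enrichment(fn, sig)
  expect_equal(res$n_edges_mapped, 2L)
  expect_equal(res$n_continuous, 2L)
  expect_equal(res$frac_continuous, 1)
  # background: 12 ordered pairs over {a,b,c,d}, 2 are FN edges, none of
  # the remaining 10 is continuous
  expect_equal(res$p_value, fisher_greater_oracle(2, 0, 0, 10), tolerance = 1e-9)
  # no mapped edges -> not-applicable marker
  sig2 <- make_sig("x>y")
  res2 <- continuity_enrichment(fn, sig2)
  expect_equal(res2$n_edges_mapped, 0L)
  expect_true(is.na(res2$p_value))
})

test_that("continuity fractions on planted instances match a reachability oracle", {
  inst <- generate_instance(synthetic_spec(seed = 23L))
  drivers <- inst$drivers$genes
  fn <- make_fn(rep(drivers[1], 3), drivers[2:4], c(0.9, 0.5, 0.2))
  res <- continuity_enrichment(fn, inst$signaling, drivers)
  cont <- signaling_continuity(fn, inst$signaling)
  sigg <- inst$signaling$graph
  oracle <- vapply(seq_len(nrow(fn)), function(i) {
    if (!all(c(fn$source[i], fn$target[i]) %in% igraph::V(sigg)$name)) return(NA)
    is.finite(igraph::distances(sigg, fn$source[i], fn$target[i], mode = "out"))[1]
  }, logical(1))
  expect_equal(res$n_continuous, sum(oracle, na.rm = TRUE))
  expect_equal(sum(cont$continuity == "unmapped"), sum(is.na(oracle)))
})

test_that("cross-network overlap counts common edges with significance", {
  f1 <- make_fn(c("a", "a", "b"), c("b", "c", "c"), c(0.9, 0.5, 0.2))
  res_same <- cross_network_overlap(list(f1, f1), cutoffs = c(0, 0.5))
  expect_equal(res_same$n_common, c(3L, 2L))
  f2 <- make_fn(c("c", "c"), c("a", "b"), c(0.9, 0.9))
  expect_equal(cross_network_overlap(list(f1, f2), cutoffs = 0)$n_common, 0L)
  # toy 2x2 oracle: universe of ordered pairs over the filtered node union
  f3 <- make_fn(c("a", "b"), c("b", "c"), c(0.9, 0.9))
  res <- cross_network_overlap(list(f1, f3), cutoffs = 0)
  k <- 2; n1 <- 3; n2 <- 2; univ <- 3 * 2
  expect_equal(res$n_common, 2L)
  expect_equal(res$p_value,
               fisher_greater_oracle(k, n1 - k, n2 - k, univ - n1 - n2 + k),
               tolerance = 1e-9)
})

test_that("core overlap significance uses the hypergeometric tail", {
  universe <- paste0("d", 1:30)
  core <- universe[1:5]
  res <- core_overlap_significance(list(a = core, b = core), universe)
  expect_equal(res$overlap, 5L)
  expect_equal(res$p_value, 1 / choose(30, 5), tolerance = 1e-9)
  # disjoint cores: overlap 0, tail p essentially 1
  res2 <- core_overlap_significance(list(a = universe[1:5], b = universe[6:10]), universe)
  expect_equal(res2$overlap, 0L)
  expect_equal(res2$p_value, 1, tolerance = 1e-9)
  # three-way intersection is bounded by every pairwise overlap
  cores <- list(a = universe[1:6], b = universe[3:9], c = universe[5:12])
  res3 <- core_overlap_significance(cores, universe)
  expect_lte(length(attr(res3, "common")), min(res3$overlap))
  expect_error(core_overlap_significance(list(core), character()), "Empty")
})
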