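test_that("backward allocation respects the tree topology and uses every
           waiting time once", {
  tree <- mtdna_tree()
  set.seed(51)
  for (rep in 1:5) {
    ct <- allocate_waiting_times(tree, sample_waiting_times(55))
    expect_identical(nrow(ct$events), 54L)                # w_55 .. w_2
    non_root <- 2:length(ct$spans)
    for (v in non_root) {
      sp <- ct$spans[[v]]
      if (length(ct$node_sites[[v]]) > 0L)
        expect_gt(length(sp), 0L)
      if (length(sp)) {
        expect_true(all(diff(sp) == 1L))                  # contiguous
        expect_true(all(sp >= 2L & sp <= 55L))
      }
    }
    # a clade finishes coalescing strictly before it merges upward
    defined <- non_root[!is.na(ct$merge_step[non_root])]
    expect_true(all(ct$merge_step[defined] < ct$comp_step[defined]))
  }
  expect_error(allocate_waiting_times(tree, sample_waiting_times(10)),
               "does not match")
})

test_that("first-step branch choice follows leaf-count-proportional
           weights", {
  tree <- mtdna_tree()
  # identify each top-level unit by its smallest lineage
  top_ids <- vapply(tree$root$children,
                    function(ch) clade_lineages(ch)[1], character(1))
  top_of <- function(ct) {
    v <- ct$events$node[1]
    while (ct$node_parent[v] != 1L) v <- ct$node_parent[v]
    v
  }
  kids_idx <- which(coaltree:::flatten_tree(tree)$parent == 1L)
  set.seed(52)
  w <- sample_waiting_times(55)
  draws <- integer(2000)
  for (r in seq_along(draws))
    draws[r] <- top_of(allocate_waiting_times(tree, w))
  counts <- table(factor(draws, levels = kids_idx))
  # expected: multi-leaf branches (m, abef, k, cghijl, d) in proportion to
  # their leaf totals; the single-leaf branch n is never chosen first
  mult <- vapply(tree$root$children, clade_multiplicity, numeric(1))
  expected_p <- ifelse(mult >= 2, mult, 0)
  expected_p <- expected_p / sum(expected_p)
  expect_identical(sum(counts[expected_p == 0]), 0L)
  chi <- suppressWarnings(chisq.test(counts[expected_p > 0],
                                     p = expected_p[expected_p > 0]))
  expect_gt(chi$p.value, 1e-4)
})

test_that("mutation allocation conserves the segregating-site total", {
  tree <- mtdna_tree()
  set.seed(53)
  for (rep in 1:10) {
    ct <- allocate_waiting_times(tree, sample_waiting_times(55))
    k <- allocate_mutations(ct)
    expect_identical(k$s, 18L)
    expect_true(all(k$k >= 0L))
    expect_length(k$k, 54L)
  }
})

test_that("a segment spanning one interval keeps all its mutations there", {
  # two lineages, 7 sites on the singleton: its pendant edge spans every
  # interval; the x-clade labeling puts all mutations in interval 2
  aln <- toy_private_sites(3L, 1L, 7)
  trees <- enumerate_rooted_trees(label_least_shared(find_segregating_sites(aln)))
  flipped <- trees[[which(vapply(trees, function(t)
    all(t$matrix$x["x", ] == 1L), logical(1)))]]  # 1-set {x} on all 7 sites
  set.seed(54)
  ct <- allocate_waiting_times(flipped, sample_waiting_times(4))
  k <- allocate_mutations(ct)
  expect_identical(unname(k$k["2"]), 7L)
  expect_identical(k$s, 7L)
})

test_that("the conditional mean given k matches its closed forms", {
  # n = 2: Gamma conjugate posterior mean (k+1)/(1+theta)
  for (k in 0:10) for (theta in c(0.1, 1, 10))
    expect_equal(posterior_mean_given_k(k, theta, n = 2),
                 (k + 1) / (1 + theta), tolerance = 1e-12)
  # all k = 0 at theta = 0 telescopes to the predata mean
  for (n in c(2, 5, 20))
    expect_equal(posterior_mean_given_k(rep(0, n - 1), 0, n = n),
                 2 * (1 - 1 / n), tolerance = 1e-12)
  expect_equal(posterior_mean_given_k(c(0, 0), 1, n = 3), 13 / 18)
  expect_error(posterior_mean_given_k(c(1, 2), 1, n = 4), "one entry")
})

test_that("estimator is exact for s = 0, theta = 0 and errors on bad input", {
  aln <- toy_private_sites(4L, 3L, 0)
  tree <- build_rooted_tree(
    label_least_shared(find_segregating_sites(aln)))
  for (seed in c(1, 99)) {
    set.seed(seed)
    est <- estimate_tmrca(list(tree), theta = 0, M = 300)
    expect_equal(est$t_hat, 2 * (1 - 1 / 7), tolerance = 1e-12)
    expect_true(est$converged)
    expect_equal(est$mc_se, 0)
  }
  expect_error(estimate_tmrca(list(), 1), "empty")
  expect_error(estimate_tmrca(tree, -1), "non-negative")
})

test_that("compiled and reference engines sample the same law", {
  ds <- simulate_infinite_sites(7, 2, seed = 55)
  trees <- enumerate_rooted_trees(
    label_least_shared(find_segregating_sites(ds$alignment)))
  set.seed(56)
  cpp <- estimate_tmrca(trees, theta = 2, M = 6000, tol = 1e-9)
  set.seed(57)
  ref <- estimate_tmrca(trees, theta = 2, M = 800, tol = 1e-9, engine = "R")
  z <- abs(cpp$t_hat - ref$t_hat) / sqrt(cpp$mc_se^2 + ref$mc_se^2)
  expect_lt(z, 3)
})

test_that("per-tree contributions equal the average conditional mean
           (consistency of the two estimator readings)", {
  aln <- toy_two_lineages(3L, 2L)
  trees <- enumerate_rooted_trees(
    label_least_shared(find_segregating_sites(aln)))
  tree <- trees[[1]]
  set.seed(58)
  M <- 400
  vals <- numeric(M)
  for (m in seq_len(M)) {
    w <- sample_waiting_times(5)
    vals[m] <- posterior_mean_given_k(
      allocate_mutations(allocate_waiting_times(tree, w)), theta = 1)
  }
  set.seed(58)
  est <- estimate_tmrca(list(tree), theta = 1, M = M, tol = 1e-12,
                        engine = "R")
  expect_equal(mean(vals), est$per_tree_means[1], tolerance = 1e-10)
  expect_equal(est$t_hat, est$per_tree_means[1], tolerance = 1e-10)
})

test_that("estimates rise with the mutation count and fall with theta", {
  set.seed(59)
  by_s <- vapply(c(0, 2, 4, 6), function(s) {
    aln <- toy_private_sites(3L, 2L, s)
    trees <- enumerate_rooted_trees(
      label_least_shared(find_segregating_sites(aln)))
    estimate_tmrca(trees, theta = 1, M = 3000, tol = 1e-9)$t_hat
  }, numeric(1))
  expect_true(all(diff(by_s) > 0))
  by_theta <- vapply(c(0.5, 1, 2, 4), function(theta) {
    aln <- toy_private_sites(3L, 2L, 3)
    trees <- enumerate_rooted_trees(
      label_least_shared(find_segregating_sites(aln)))
    estimate_tmrca(trees, theta = theta, M = 3000, tol = 1e-9)$t_hat
  }, numeric(1))
  expect_true(all(diff(by_theta) < 0))
})

test_that("the composition-enumerated conditional mean matches its
           reductions", {
  # s = 0 reduces to the telescoped sum
  for (theta in c(0, 1, 3))
    expect_equal(posterior_mean_given_s(5, 0, theta),
                 posterior_mean_given_k(rep(0, 4), theta, n = 5),
                 tolerance = 1e-12)
  # n = 2: the single composition makes it the conditional mean given k
  for (s in 0:5)
    expect_equal(posterior_mean_given_s(2, s, 1),
                 posterior_mean_given_k(s, 1, n = 2), tolerance = 1e-12)
  # n = 3, s = 2: direct sum over the three compositions
  comps <- rbind(c(2, 0), c(1, 1), c(0, 2))
  direct <- mean(apply(comps, 1, posterior_mean_given_k, theta = 1, n = 3))
  expect_equal(posterior_mean_given_s(3, 2, 1), direct, tolerance = 1e-12)
  # at n = 3 the printed 2/(s+1) normalisation coincides
  expect_equal(posterior_mean_given_s(3, 2, 1, normalization = "printed"),
               posterior_mean_given_s(3, 2, 1), tolerance = 1e-12)
  expect_error(posterior_mean_given_s(40, 40, 1), "too large")
})
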