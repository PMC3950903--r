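test_that("the three-gamete validity test matches textbook cases", {
  expect_true(is_valid_matrix(mtdna_binary()))
  expect_true(is_valid_matrix(diag(2)))
  bad <- rbind(c(1, 0), c(0, 1), c(1, 1))
  v <- is_valid_matrix(bad)
  expect_false(isTRUE(v))
  expect_identical(attr(v, "violating_pair"), c(1L, 2L))
})

test_that("validity agrees with a brute-force laminarity check", {
  # exhaustively over all 3x3 0/1 matrices
  for (code in 0:511) {
    m <- matrix(as.integer(intToBits(code))[1:9], nrow = 3)
    expect_identical(isTRUE(is_valid_matrix(m)), brute_laminar(m),
                     info = paste("3x3 code", code))
  }
  # randomly over 4x4 matrices
  set.seed(404)
  for (rep in 1:300) {
    m <- matrix(rbinom(16, 1, 0.4), nrow = 4)
    expect_identical(isTRUE(is_valid_matrix(m)), brute_laminar(m))
  }
})

test_that("the mtDNA rooted tree has the documented branch structure", {
  tree <- mtdna_tree()
  w <- child_weights(tree$root)
  expect_setequal(names(w),
                  c("m", "a,b,e,f", "k", "c,g,h,i,j,l", "d", "n"))
  expect_identical(w[["a,b,e,f"]], 24)
  expect_identical(w[["c,g,h,i,j,l"]], 19)
  abef <- find_clade(tree, c("a", "b", "e", "f"))
  expect_identical(abef$sites, c(4L, 6L, 14L))
  cghijl <- find_clade(tree, c("c", "g", "h", "i", "j", "l"))
  expect_identical(cghijl$sites, 18L)
  ij <- find_clade(tree, c("i", "j"))
  expect_identical(ij$sites, 16L)
  expect_identical(clade_multiplicity(ij), 12)
})

test_that("degenerate matrices build the expected trees", {
  star <- build_rooted_tree(matrix(0L, nrow = 3, ncol = 0,
                                   dimnames = list(c("a", "b", "c"), NULL)))
  expect_length(star$root$children, 3L)
  expect_true(all(vapply(star$root$children,
                         function(ch) length(ch$sites) == 0L, logical(1))))

  single <- build_rooted_tree(matrix(c(1L, 0L), ncol = 1,
                                     dimnames = list(c("a", "b"), 1)))
  kids <- single$root$children
  leaf_a <- kids[[which(vapply(kids, function(k) k$lineage == "a",
                               logical(1)))]]
  expect_identical(leaf_a$sites, 1L)

  expect_error(build_rooted_tree(rbind(c(1, 0), c(0, 1), c(1, 1))),
               "three gametes")
})

test_that("tree <-> matrix round trips are exact", {
  bm <- mtdna_binary()
  expect_identical(tree_to_matrix(build_rooted_tree(bm))$x, bm$x)
  # and on random simulated truths
  for (seed in 1:8) {
    ds <- simulate_infinite_sites(10, 2.5, seed = 100 + seed)
    rt <- tree_to_matrix(build_rooted_tree(ds$true_binary))
    expect_identical(rt$x, ds$true_binary$x)
    expect_true(isTRUE(is_valid_matrix(rt)))
  }
})

test_that("the unrooted reduction contracts and straightens correctly", {
  # star with no mutations -> a single vertex holding every lineage
  star <- build_rooted_tree(matrix(0L, 3, 0,
                                   dimnames = list(c("a", "b", "c"), NULL)))
  ustar <- to_unrooted(star)
  expect_length(ustar$vertices, 1L)
  expect_length(ustar$edges, 0L)
  expect_setequal(ustar$vertices[[1]]$lineages, c("a", "b", "c"))

  # two lineages, three mutations on one pendant edge -> a path of 3
  aln <- toy_private_sites(1L, 2L, 3)
  bm <- label_least_shared(find_segregating_sites(aln))
  upath <- to_unrooted(build_rooted_tree(bm))
  expect_length(upath$vertices, 2L)
  expect_length(upath$edges, 1L)
  expect_length(upath$edges[[1]]$sites, 3L)

  # the mtDNA unrooted tree: every vertex hosts a lineage (14 vertices)
  ut <- to_unrooted(mtdna_tree())
  expect_length(ut$vertices, 14L)
  expect_length(ut$edges, 13L)
  expect_identical(sum(lengths(lapply(ut$edges, `[[`, "sites"))), 18L)
})

test_that("enumeration returns exactly s+1 distinct trees with one
           unrooted reduction", {
  trees <- mtdna_trees()
  expect_length(trees, 19L)
  keys <- vapply(trees, function(t) paste(t$matrix$x, collapse = ""),
                 character(1))
  expect_identical(anyDuplicated(keys), 0L)
  base_key <- paste(mtdna_binary()$x, collapse = "")
  expect_true(base_key %in% keys)
  sigs <- vapply(lapply(trees, to_unrooted),
                 coaltree:::unrooted_signature, character(1))
  expect_length(unique(sigs), 1L)
  for (t in trees) expect_true(isTRUE(is_valid_matrix(t$matrix)))
})

test_that("enumeration handles the boundary cases", {
  # s = 0: a single (star) tree
  star_bm <- binary_matrix(matrix(0L, 2, 0), lineage_ids = c("a", "b"),
                           multiplicities = c(2L, 3L))
  expect_length(enumerate_rooted_trees(star_bm), 1L)

  # two lineages, one segregating site: both labelings, and both are the
  # only valid ones by exhaustive check
  aln <- toy_two_lineages()
  bm <- label_least_shared(find_segregating_sites(aln))
  two <- enumerate_rooted_trees(bm)
  expect_length(two, 2L)
  all_labelings <- list(matrix(c(1L, 0L), 2), matrix(c(0L, 1L), 2))
  valid_count <- sum(vapply(all_labelings,
                            function(m) isTRUE(is_valid_matrix(m)),
                            logical(1)))
  expect_identical(valid_count, 2L)
})

test_that("enumeration on simulated data always contains the truth", {
  # When the true root falls between mutations on an unrooted edge, which
  # of the stacked mutations lies on which side of the root is a labeling
  # convention (the enumeration fixes ascending site order), so the truth
  # is recovered up to the multiset of column 1-sets.
  col_multiset <- function(m)
    paste(sort(apply(m, 2L, paste, collapse = "")), collapse = "/")
  for (seed in 1:6) {
    ds <- simulate_infinite_sites(9, 2, seed = 200 + seed)
    bm <- label_least_shared(find_segregating_sites(ds$alignment))
    trees <- enumerate_rooted_trees(bm)
    expect_length(trees, ds$s + 1L)
    expect_true(isTRUE(is_valid_matrix(ds$true_binary)))
    true_tree <- build_rooted_tree(ds$true_binary)
    sigs <- vapply(lapply(c(trees, list(true_tree)), to_unrooted),
                   coaltree:::unrooted_signature, character(1))
    expect_length(unique(sigs), 1L)       # truth reduces to the same
                                          # unrooted gene tree
    keys <- vapply(trees, function(t) col_multiset(t$matrix$x),
                   character(1))
    expect_true(col_multiset(ds$true_binary$x) %in% keys)
  }
})

test_that("annotated Newick output round-trips and is standard-parseable", {
  one <- build_rooted_tree(matrix(0L, 1, 0, dimnames = list("a", NULL)),
                           aln = seg_alignment("a", "A", 3L))
  nwk <- write_newick(one)
  expect_match(nwk, "mult=3", fixed = TRUE)
  expect_identical(read_newick(nwk)$multiplicities, 3L)

  tree <- mtdna_tree()
  f <- tempfile(fileext = ".nwk")
  write_newick(tree, f)
  back <- read_newick(path = f)
  expect_setequal(back$lineage_ids, tree$lineage_ids)
  expect_identical(back$n, tree$n)
  expect_identical(back$s, tree$s)
  # topology identity via the matrix representation
  ord <- match(tree$lineage_ids, back$lineage_ids)
  expect_identical(back$matrix$x[ord, , drop = FALSE], tree$matrix$x)
  # a standard reader recovers the leaf set once comments are stripped
  plain <- gsub("\\[[^]]*\\]", "", readLines(f))
  ape_tree <- ape::read.tree(text = plain)
  expect_setequal(ape_tree$tip.label, tree$lineage_ids)
})
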