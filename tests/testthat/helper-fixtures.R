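# Shared fixtures and independent oracles for the test suite.  The mtDNA
# objects are built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

mtdna_alignment <- function()
  memo("aln", read_lineage_table(nuu_chah_nulth_path()))

mtdna_binary <- function()
  memo("bm", label_least_shared(find_segregating_sites(mtdna_alignment())))

mtdna_tree <- function()
  memo("tree", build_rooted_tree(mtdna_binary()))

mtdna_trees <- function()
  memo("trees", enumerate_rooted_trees(mtdna_binary()))

# write a lineage table to a temp file; rows are "id base1 base2 ... freq"
write_toy_table <- function(rows, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  writeLines(vapply(rows, paste, character(1), collapse = sep), path)
  path
}

# independent laminarity check: explicit nested-or-disjoint set comparison
# (different formulation from the package's three-gamete scan)
brute_laminar <- function(m) {
  s <- ncol(m)
  if (s < 2) return(TRUE)
  onesets <- lapply(seq_len(s), function(j) which(m[, j] == 1))
  for (j in seq_len(s - 1)) {
    for (k in (j + 1):s) {
      a <- onesets[[j]]; b <- onesets[[k]]
      common <- intersect(a, b)
      nested <- all(a %in% b) || all(b %in% a)
      if (length(common) > 0 && !nested) return(FALSE)
    }
  }
  TRUE
}

# toy two-lineage dataset: x carried by `mult` copies, y distinct at one
# site; least-shared labeling puts the mutation on the minority lineage
toy_two_lineages <- function(mult_x = 2L, mult_y = 1L) {
  seg_alignment(c("x", "y"), c("A", "G"), c(mult_x, mult_y))
}

# n-sample dataset with two lineages and `s` sites private to lineage y
toy_private_sites <- function(mult_x, mult_y, s) {
  if (s == 0) {
    seqs <- c("A")
    return(seg_alignment("x", seqs, mult_x + mult_y))
  }
  seg_alignment(c("x", "y"),
                c(strrep("A", s), strrep("G", s)),
                c(mult_x, mult_y))
}

# --- independent brute-force oracles for tiny datasets --------------------
# These re-derive the estimator's expectation with hand-worked allocation
# distributions and plain rexp() draws; they share no code with the
# package's allocation engines.

# n = 3, lineages (x: 2 copies, y: 1 copy), s = 1 site on y, given theta.
# Rooted trees: mutation on y's pendant edge (spans intervals {2,3}) or on
# the x-clade edge (spans {2} only).
oracle_n3 <- function(theta, M = 2e5) {
  w2 <- rexp(M, 1)
  w3 <- rexp(M, 3)
  a <- w2 / (w2 + w3)                     # P(mutation in interval 2 | T1)
  c2 <- 1 / (2 * (2 + theta - 1))
  c3 <- 1 / (3 * (3 + theta - 1))
  v1 <- (a + 1) * c2 + ((1 - a) + 1) * c3
  v2 <- (1 + 1) * c2 + (0 + 1) * c3
  vals <- (v1 + v2) / 2
  list(mean = 2 * mean(vals), se = 2 * sd(vals) / sqrt(M))
}

# n = 4, lineages (x: 2, y: 1, z: 1), sites s1 on y and s2 on z.
# The three rooted trees and their hand-derived allocation laws:
#  T1 ({y},{z}):   at step 4 the root already holds two available
#                  singletons, so with probability 1/2 y and z merge at the
#                  root (both sites land in interval 4) and with
#                  probability 1/2 the pair within x merges first, after
#                  which step 3 joins a uniform pair of {x-ancestor, y, z};
#                  y's edge then spans intervals {merge_y..4}, z likewise.
#  T2 ({y},{x,y}): step 4 within x, step 3 joins x-ancestor and y (forced),
#                  step 2 at the root.  y-edge spans {3,4}; clade edge
#                  (site 2) spans {2}.
#  T3 ({x,z},{z}): mirror of T2 with y and z swapped.
oracle_n4 <- function(theta, M = 2e5) {
  w2 <- rexp(M, 1); w3 <- rexp(M, 3); w4 <- rexp(M, 6)
  cf <- c(NA, 1 / (2 * (1 + theta)), 1 / (3 * (2 + theta)),
          1 / (4 * (3 + theta)))
  base <- sum(cf[2:4])
  p34 <- w3 / (w3 + w4)                   # P(land in interval 3 | spans 3,4)
  seg_34 <- function(u) ifelse(u < p34, cf[3], cf[4])
  # value of a site whose edge spans {2,3,4}
  seg_234 <- function(u) {
    tot <- w2 + w3 + w4
    ifelse(u < w2 / tot, cf[2], ifelse(u < (w2 + w3) / tot, cf[3], cf[4]))
  }
  root_first <- runif(M) < 0.5            # y+z merge at the root at step 4
  pick <- sample.int(3L, M, replace = TRUE)
  y_at3 <- pick %in% c(1L, 3L)            # y merged at step 3, else step 2
  z_at3 <- pick %in% c(2L, 3L)
  uy <- runif(M); uz <- runif(M)
  v1 <- ifelse(root_first,
               base + 2 * cf[4],
               base + ifelse(y_at3, seg_34(uy), seg_234(uy)) +
                 ifelse(z_at3, seg_34(uz), seg_234(uz)))
  v2 <- base + seg_34(runif(M)) + cf[2]
  v3 <- base + seg_34(runif(M)) + cf[2]
  vals <- (v1 + v2 + v3) / 3
  list(mean = 2 * mean(vals), se = 2 * sd(vals) / sqrt(M))
}

toy_n4_alignment <- function() {
  seg_alignment(c("x", "y", "z"), c("AA", "GA", "AG"), c(2L, 1L, 1L))
}
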