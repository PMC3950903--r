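# Infinite-sites coalescent simulator with known ground truth, used for
# parameter-recovery and property testing of the whole pipeline.

#' Encode binary haplotypes as DNA sequences
#'
#' Maps a 0/1 haplotype matrix (rows = sampled sequences, columns = sites)
#' to bases: per site an ancestral base is drawn uniformly from
#' `{A,C,G,T}` and the mutant state is its transition partner (A<->G,
#' C<->T), mirroring the transition-only character of mitochondrial
#' control-region data; with `transitions_only = FALSE` the mutant base is
#' drawn uniformly from the three alternatives.  Identical rows are
#' collapsed into lineages with multiplicities.
#'
#' @param haps 0/1 matrix of haplotypes.
#' @param transitions_only Use the transition partner as mutant state
#'   (default) or an arbitrary distinct base.
#' @return A [seg_alignment()]; attributes `ancestral_base` and
#'   `mutant_base` record the per-site encoding.
#' @export
encode_as_bases <- function(haps, transitions_only = TRUE) {
  haps <- as.matrix(haps)
  s <- ncol(haps)
  anc <- sample(DNA_BASES, s, replace = TRUE)
  mut <- if (transitions_only) unname(TRANSITION[anc]) else
    vapply(anc, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
  seqs <- vapply(seq_len(nrow(haps)), function(r)
    paste(ifelse(haps[r, ] == 1L, mut, anc), collapse = ""), character(1))
  first <- !duplicated(seqs)
  mult <- as.integer(table(factor(seqs, levels = seqs[first])))
  aln <- seg_alignment(
    lineage_ids = sprintf("L%02d", seq_len(sum(first))),
    sequences = seqs[first],
    multiplicities = mult)
  attr(aln, "ancestral_base") <- anc
  attr(aln, "mutant_base") <- mut
  aln
}

#' Simulate an infinite-sites coalescent dataset with known truth
#'
#' Draws a random binary-merge coalescent genealogy with waiting times from
#' [sample_waiting_times()] (merge order uniform over active pairs), drops
#' mutations on each branch as a Poisson process of rate `theta/2` per unit
#' time (units of `N` generations), gives every mutation its own site
#' (infinite sites), encodes haplotypes as DNA via [encode_as_bases()] and
#' collapses identical sequences into lineages.  All ground truth is
#' recorded: the waiting times, the per-coalescent-interval mutation
#' counts, the true 0/1 labeling and its rooted gene tree.
#'
#' @param n Sample size, `>= 2`.
#' @param theta Scaled mutation rate, `>= 0`.
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   first and the value is recorded in the result for replay.
#' @param transitions_only Passed to [encode_as_bases()].
#' @return An object of class `synthetic_dataset`: `alignment`
#'   (a [seg_alignment()]), `true_w` (`waiting_times`), `true_k` (named
#'   per-interval mutation counts, `i = 2..n`), `true_binary` (the true
#'   [binary_matrix()] labeling, collapsed to lineages), `true_tree` (its
#'   `rooted_genetree`), `s`, `theta`, `seed`.
#' @export
simulate_infinite_sites <- function(n, theta, seed = NULL,
                                    transitions_only = TRUE) {
  if (n < 2) stop("n must be >= 2")
  if (theta < 0) stop("theta must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  w <- sample_waiting_times(n)

  # event j (j = n..2) reduces j -> j-1 lineages at depth T_j = sum_{i>=j} w_i
  depth_at <- rev(cumsum(rev(w$w)))              # T_j for j = 2..n
  n_nodes <- 2L * n - 1L
  node_time <- numeric(n_nodes)                  # tips at depth 0
  left <- integer(n_nodes); right <- integer(n_nodes)
  active <- seq_len(n)
  nxt <- n
  for (j in n:2) {
    pair <- sample(length(active), 2L)
    nxt <- nxt + 1L
    node_time[nxt] <- depth_at[j - 1L]
    left[nxt] <- active[pair[1]]
    right[nxt] <- active[pair[2]]
    active <- c(active[-pair], nxt)
  }
  root <- nxt
  parent <- integer(n_nodes)
  for (v in (n + 1L):n_nodes) { parent[left[v]] <- v; parent[right[v]] <- v }

  # tips below each node
  tips_below <- vector("list", n_nodes)
  for (v in seq_len(n)) tips_below[[v]] <- v
  for (v in (n + 1L):n_nodes)
    tips_below[[v]] <- c(tips_below[[left[v]]], tips_below[[right[v]]])

  # Poisson mutations on each branch; each creates a fresh site
  site_tips <- list()
  site_interval <- integer(0)
  upper <- depth_at                              # T_j boundary of interval j
  for (v in seq_len(n_nodes)) {
    if (v == root) next
    len <- node_time[parent[v]] - node_time[v]
    n_mut <- stats::rpois(1L, theta / 2 * len)
    if (n_mut == 0L) next
    tau <- node_time[v] + stats::runif(n_mut) * len
    for (m in seq_len(n_mut)) {
      site_tips[[length(site_tips) + 1L]] <- tips_below[[v]]
      # interval i spans depths (T_{i+1}, T_i]; find the smallest j with
      # tau <= T_j
      site_interval[length(site_interval) + 1L] <-
        (2:n)[max(which(upper >= tau[m]))]
    }
  }
  s <- length(site_tips)
  haps <- matrix(0L, nrow = n, ncol = s)
  for (j in seq_len(s)) haps[site_tips[[j]], j] <- 1L

  aln <- encode_as_bases(haps, transitions_only = transitions_only)
  # collapse the true labeling to the lineage level, matching aln's order
  seqs <- vapply(seq_len(n), function(r)
    paste(ifelse(haps[r, ] == 1L,
                 attr(aln, "mutant_base"),
                 attr(aln, "ancestral_base")), collapse = ""), character(1))
  rep_rows <- match(aln$sequences, seqs)
  true_bin <- binary_matrix(haps[rep_rows, , drop = FALSE],
                            lineage_ids = aln$lineage_ids,
                            multiplicities = aln$multiplicities,
                            site_positions = seq_len(s),
                            labeling = "truth")
  true_k <- setNames(integer(n - 1L), 2:n)
  for (iv in site_interval)
    true_k[iv - 1L] <- true_k[iv - 1L] + 1L
  structure(
    list(alignment = aln,
         true_w = w,
         true_k = true_k,
         true_binary = true_bin,
         true_tree = build_rooted_tree(true_bin),
         s = s, theta = theta, n = as.integer(n), seed = seed),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_dataset: n = %d, theta = %g, s = %d segregating sites, ",
    "%d lineages, true t_n = %.4f\n"),
    x$n, x$theta, x$s,
    length(x$alignment$lineage_ids), x$true_w$t_n))
  invisible(x)
}
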