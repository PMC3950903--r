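# The TMRCA estimator: backward allocation of coalescent waiting times
# onto a rooted gene tree, multinomial allocation of mutations across the
# coalescent intervals each branch segment spans, and the Monte-Carlo
# posterior-mean estimate averaged over the s+1 rooted trees.
#
# Two engines implement the same model: a readable recursive R reference
# (allocate_waiting_times / allocate_mutations) and an iterative C++ core
# used by estimate_tmrca() for the replicate loop.

# flatten with children lists; node 1 is the root (preorder)
tree_arrays <- function(t) {
  fl <- flatten_tree(t)
  children <- vector("list", fl$k)
  for (i in seq_len(fl$k)) children[[i]] <- integer(0)
  for (i in seq_len(fl$k)) {
    p <- fl$parent[i]
    if (p > 0L) children[[p]] <- c(children[[p]], i)
  }
  is_leaf <- !is.na(fl$lineage)
  cnt0 <- integer(fl$k)
  for (i in rev(seq_len(fl$k)))           # preorder => children after parent
    cnt0[i] <- if (is_leaf[i]) fl$mult[i] else sum(cnt0[children[[i]]])
  list(parent = fl$parent, children = children, is_leaf = is_leaf,
       mult = fl$mult, sites = fl$sites,
       nsites = lengths(fl$sites), cnt0 = cnt0, k = fl$k,
       lineage = fl$lineage)
}

#' Allocate coalescent waiting times backward onto a rooted gene tree
#'
#' Implements the backward allocation: the waiting times are assigned in
#' the order `w_n, w_{n-1}, ..., w_2`.  At each step the coalescence is
#' placed by descending from the root: a child subtree still holding `c >= 2`
#' active leaves is chosen with weight `c`, and a merge among the lineages
#' already fully coalesced at the current node (available ancestors) is
#' chosen with weight equal to their number; within a chosen unit the rule
#' is applied recursively.  Within a group of identical leaves which pair
#' merges is irrelevant: only the active count decrements.  A fully
#' coalesced clade becomes a single available lineage of its parent scope,
#' so a single-leaf top-level branch merges only at the root scope.
#'
#' @param tree A `rooted_genetree` whose total leaf multiplicity equals
#'   `w$n`.
#' @param w A `waiting_times` object for sample size `n`.
#' @return An object of class `calibrated_tree`: the `tree`, `w`, the event
#'   log (`events`: per step `i = n..2`, the node at which the merge
#'   occurred), and per non-root tree segment the coalescent intervals it
#'   spans (`spans`, a list of integer vectors of interval indices `i`,
#'   interval `i` having length `w_i`) together with `d = lengths(spans)`.
#' @export
allocate_waiting_times <- function(tree, w) {
  stopifnot(inherits(tree, "rooted_genetree"), inherits(w, "waiting_times"))
  n <- w$n
  if (tree$n != n)
    stop("total leaf multiplicity of the tree (", tree$n,
         ") does not match the waiting-times sample size (", n, ")")
  ta <- tree_arrays(tree)
  cnt <- ta$cnt0
  slots <- vector("list", ta$k)
  merge_step <- rep(NA_integer_, ta$k)
  comp_step <- rep(NA_integer_, ta$k)
  for (v in seq_len(ta$k)) {
    if (!ta$is_leaf[v]) {
      avail <- ta$children[[v]][cnt[ta$children[[v]]] == 1L]
      slots[[v]] <- avail
    }
    if (cnt[v] == 1L) comp_step[v] <- n + 1L   # coalesced from the start
  }
  decrement <- function(u) {
    while (u > 0L) { cnt[u] <<- cnt[u] - 1L; u <- ta$parent[u] }
  }
  events <- integer(n - 1L)
  for (i in n:2) {
    v <- 1L
    repeat {
      kids <- ta$children[[v]]
      big <- kids[cnt[kids] >= 2L]
      wts <- cnt[big]
      navail <- length(slots[[v]])
      if (navail >= 2L) { big <- c(big, 0L); wts <- c(wts, navail) }
      if (!length(big))
        stop("internal error: no mergeable unit at step ", i)
      pick <- big[sample.int(length(big), 1L, prob = wts)]
      if (pick == 0L) {                        # merge among available here
        sl <- slots[[v]]
        ab <- sample.int(length(sl), 2L)
        for (u in sl[ab]) if (u > 0L) merge_step[u] <- i
        slots[[v]] <- c(sl[-ab], 0L)
        decrement(v)
        if (cnt[v] == 1L) {
          comp_step[v] <- i
          if (v > 1L) slots[[ta$parent[v]]] <- c(slots[[ta$parent[v]]], v)
        }
        events[n - i + 1L] <- v
        break
      } else if (ta$is_leaf[pick]) {           # merge within identical leaves
        decrement(pick)
        if (cnt[pick] == 1L) {
          comp_step[pick] <- i
          slots[[v]] <- c(slots[[v]], pick)
        }
        events[n - i + 1L] <- pick
        break
      } else v <- pick                         # descend
    }
  }
  spans <- vector("list", ta$k)
  for (v in 2:ta$k) {
    # merge_step is NA only for the degenerate single-lineage star, whose
    # ancestor never merges upward; its (mutation-free) segment spans nothing
    spans[[v]] <- if (is.na(merge_step[v])) integer(0) else
      seq.int(merge_step[v], comp_step[v] - 1L)
  }
  structure(
    list(tree = tree, w = w, n = n,
         node_parent = ta$parent, node_sites = ta$sites,
         node_lineage = ta$lineage,
         merge_step = merge_step, comp_step = comp_step,
         spans = spans, d = lengths(spans),
         events = data.frame(step = n:2, node = events)),
    class = "calibrated_tree")
}

#' @export
print.calibrated_tree <- function(x, ...) {
  cat(sprintf(
    "calibrated_tree: n = %d, %d tree segments, t_n = %.4f\n",
    x$n, length(x$spans) - 1L, x$w$t_n))
  invisible(x)
}

#' Allocate mutations multinomially across coalescent intervals
#'
#' Each tree segment carrying `t_r > 0` mutations spans `d` coalescent
#' intervals whose lengths are the allocated waiting times; its mutations
#' are split across those intervals by a multinomial draw with cell
#' probabilities proportional to the interval lengths.  Summing over all
#' segments gives the per-interval mutation vector
#' `k = (k_2, ..., k_n)` with `sum(k)` equal to the number of segregating
#' sites.
#'
#' @param ct A `calibrated_tree` from [allocate_waiting_times()].
#' @return An object of class `mutation_counts`: `k` (named vector indexed
#'   `i = 2..n`), `s = sum(k)`, `n`.
#' @export
allocate_mutations <- function(ct) {
  stopifnot(inherits(ct, "calibrated_tree"))
  n <- ct$n
  w <- ct$w$w
  k <- setNames(integer(n - 1L), 2:n)
  for (v in seq_along(ct$spans)) {
    tr <- length(ct$node_sites[[v]])
    if (v == 1L || tr == 0L) next
    iv <- ct$spans[[v]]
    if (length(iv) == 0L)
      stop("contract violation: segment with mutations spans no interval")
    if (length(iv) == 1L) {
      k[iv - 1L] <- k[iv - 1L] + tr
    } else {
      draw <- stats::rmultinom(1L, tr, prob = w[iv - 1L])[, 1]
      k[iv - 1L] <- k[iv - 1L] + draw
    }
  }
  structure(list(k = k, s = sum(k), n = n), class = "mutation_counts")
}

#' Posterior-mean TMRCA given a per-interval mutation vector
#'
#' The conditional expectation of the TMRCA given the mutation counts
#' `k = (k_2, ..., k_n)` per coalescent interval:
#' `E(t_n | k, s, theta) = 2 * sum_{i=2}^{n} (k_i + 1) / (i (i + theta - 1))`.
#' At `n = 2` this is the Gamma conjugate posterior mean
#' `(k + 1) / (1 + theta)`; with all `k_i = 0` and `theta = 0` it
#' telescopes to the predata mean `2 (1 - 1/n)`.
#'
#' @param k A `mutation_counts` object or a numeric vector
#'   `(k_2, ..., k_n)` of length `n - 1`.
#' @param theta Scaled mutation rate, `>= 0`.
#' @param n Sample size; taken from `k` when it is a `mutation_counts`.
#' @return The conditional mean, in units of `N` generations.
#' @export
posterior_mean_given_k <- function(k, theta, n = NULL) {
  if (inherits(k, "mutation_counts")) { n <- k$n; k <- k$k }
  if (is.null(n)) n <- length(k) + 1L
  if (length(k) != n - 1L)
    stop("k must have one entry per coalescent interval i = 2..n")
  if (any(k < 0)) stop("mutation counts must be non-negative")
  if (theta < 0) stop("theta must be non-negative")
  i <- 2:n
  2 * sum((k + 1) / (i * (i + theta - 1)))
}

tree_spec_for_cpp <- function(tree) {
  ta <- tree_arrays(tree)
  list(parent = as.integer(ta$parent - 1L),   # 0-based, root = -1
       mult = as.integer(ifelse(ta$is_leaf, ta$mult, 0L)),
       nsites = as.integer(ta$nsites))
}

# one replicate batch through the R reference path (independent of C++)
r_engine_batch <- function(trees, theta, B, coef) {
  n <- trees[[1]]$n
  out <- matrix(0, nrow = B, ncol = length(trees))
  for (m in seq_len(B)) {
    w <- sample_waiting_times(n)
    for (r in seq_along(trees)) {
      ct <- allocate_waiting_times(trees[[r]], w)
      k <- allocate_mutations(ct)$k
      out[m, r] <- sum((k + 1) * coef)
    }
  }
  out
}

#' Monte-Carlo posterior-mean estimate of the TMRCA
#'
#' The package's central estimator.  For each replicate one coalescent
#' waiting-time vector is drawn and shared across all `s + 1` rooted trees;
#' on each tree the waiting times are allocated backward
#' ([allocate_waiting_times()]) and the `s` observed mutations are
#' distributed multinomially over the spanned coalescent intervals
#' ([allocate_mutations()]); the replicate's value is
#' `2/(s+1) * sum_r sum_i (k_{r,i} + 1) / (i (i + theta - 1))`,
#' and the estimate is the running mean, with each rooted tree weighted
#' uniformly (prior `1/(s+1)`).  Convergence is monitored by batch means:
#' after each batch of `max(100, M/50)` replicates the estimate is updated
#' and the run stops early once the relative change drops below `tol`.
#'
#' @param trees A list of `rooted_genetree` objects — the full `s + 1`
#'   enumeration from [enumerate_rooted_trees()] (a single tree is
#'   accepted and treated as a one-tree ensemble).
#' @param theta Scaled mutation rate, `>= 0`.
#' @param M Maximum number of Monte-Carlo replicates, `>= 1`.
#' @param tol Relative-change convergence tolerance for the batch means.
#' @param engine `"cpp"` (default, compiled replicate loop) or `"R"`
#'   (reference implementation; identical model, independent code path).
#' @return An object of class `tmrca_estimate`: `t_hat` (units of `N`
#'   generations), `mc_se` (Monte-Carlo standard error), `M_used`,
#'   `converged`, `trace` (cumulative estimate after each batch),
#'   `per_tree_means` (each tree's conditional mean
#'   `2 * mean_m sum_i (k_{r,i}+1) coef_i`), `theta`, `n`, `s`.
#' @export
estimate_tmrca <- function(trees, theta, M = 10000L, tol = 1e-3,
                           engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  if (inherits(trees, "rooted_genetree")) trees <- list(trees)
  if (!length(trees)) stop("empty tree list")
  if (!all(vapply(trees, inherits, logical(1), "rooted_genetree")))
    stop("trees must be rooted_genetree objects")
  if (theta < 0) stop("theta must be non-negative")
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1")
  if (tol <= 0) stop("tol must be positive")
  n <- trees[[1]]$n
  s <- trees[[1]]$s
  if (!all(vapply(trees, function(t) t$n == n && t$s == s, logical(1))))
    stop("all trees must share the same n and s")
  i <- 2:n
  coef <- 1 / (i * (i + theta - 1))
  specs <- lapply(trees, tree_spec_for_cpp)

  B <- max(100L, as.integer(ceiling(M / 50)))
  vals <- numeric(0)
  tree_sums <- numeric(length(trees))
  trace <- numeric(0)
  converged <- FALSE
  prev <- NA_real_
  while (length(vals) < M) {
    b <- min(B, M - length(vals))
    mat <- if (engine == "cpp")
      cpp_estimate_batch(specs, n, theta, b) else
      r_engine_batch(trees, theta, b, coef)
    tree_sums <- tree_sums + colSums(mat)
    vals <- c(vals, 2 / length(trees) * rowSums(mat))
    est <- mean(vals)
    trace <- c(trace, est)
    if (!is.na(prev) && est > 0 && abs(est - prev) / est < tol) {
      converged <- TRUE
      break
    }
    prev <- est
  }
  M_used <- length(vals)
  structure(
    list(t_hat = mean(vals),
         mc_se = stats::sd(vals) / sqrt(M_used),
         M_used = M_used,
         converged = converged || isTRUE(stats::sd(vals) == 0),
         trace = trace,
         per_tree_means = 2 * tree_sums / M_used,
         replicate_values = vals,
         theta = theta, n = n, s = s),
    class = "tmrca_estimate")
}

#' @export
print.tmrca_estimate <- function(x, ...) {
  cat(sprintf(paste0(
    "TMRCA estimate: t_hat = %.4f N generations (MC se %.4g)\n",
    "  n = %d, s = %d, theta = %g, M = %d replicates, converged: %s\n"),
    x$t_hat, x$mc_se, x$n, x$s, x$theta, x$M_used, x$converged))
  invisible(x)
}

n_compositions <- function(s, parts) choose(s + parts - 1, parts - 1)

compositions <- function(s, parts) {
  if (parts == 1L) return(matrix(s, nrow = 1L))
  out <- NULL
  for (first in 0:s) {
    rest <- compositions(s - first, parts - 1L)
    out <- rbind(out, cbind(first, rest, deparse.level = 0))
  }
  out
}

#' Conditional mean TMRCA given only the number of segregating sites
#'
#' Averages the conditional mean `2 * sum_i (E[k_i] + 1)/(i (i + theta - 1))`
#' over all compositions of `s` mutations into the `n - 1` coalescent
#' intervals (exact enumeration; small `n`, `s` only).  Two normalisations
#' are offered: `"compositions"` (default) divides by the number of
#' compositions `choose(s + n - 2, n - 2)`, i.e. a uniform prior over
#' mutation vectors, which at `n = 2` reduces to
#' [posterior_mean_given_k()]; `"printed"` uses the factor `2/(s + 1)`
#' (the two agree at `n = 3`, where the number of compositions is `s + 1`).
#'
#' @param n Sample size, `>= 2`.
#' @param s Number of segregating sites, `>= 0`.
#' @param theta Scaled mutation rate, `>= 0`.
#' @param normalization `"compositions"` or `"printed"` (see above).
#' @param expectation Function mapping a composition `(k_2, ..., k_n)` to
#'   the vector `E[k_i]` used inside the sum; the default is the identity
#'   (each composition contributes its own counts).
#' @param max_compositions Enumeration guard; exceeding it is an error
#'   advising the Monte-Carlo estimator [estimate_tmrca()] instead.
#' @return The conditional mean, in units of `N` generations.
#' @export
posterior_mean_given_s <- function(n, s, theta,
                                   normalization = c("compositions",
                                                     "printed"),
                                   expectation = identity,
                                   max_compositions = 2e5) {
  normalization <- match.arg(normalization)
  if (n < 2) stop("n must be >= 2")
  if (s < 0 || s != round(s)) stop("s must be a non-negative integer")
  if (theta < 0) stop("theta must be non-negative")
  ncomp <- n_compositions(s, n - 1L)
  if (ncomp > max_compositions)
    stop("composition enumeration too large (", format(ncomp),
         " > ", format(max_compositions),
         "); use the Monte-Carlo estimator estimate_tmrca() instead")
  comps <- compositions(as.integer(s), as.integer(n - 1L))
  i <- 2:n
  coef <- 1 / (i * (i + theta - 1))
  total <- sum(apply(comps, 1L, function(k)
    sum((expectation(k) + 1) * coef)))
  if (normalization == "compositions") 2 * total / ncomp
  else 2 * total / (s + 1)
}
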