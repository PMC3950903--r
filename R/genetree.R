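# Rooted gene trees under the infinite-sites model: validity of 0/1
# matrices (perfect phylogeny), tree construction, the unrooted reduction,
# and enumeration of all s+1 rooted trees compatible with the data.

new_tnode <- function(sites = integer(0), children = list(),
                      lineage = NA_character_, mult = NA_integer_) {
  list(sites = as.integer(sites), children = children,
       lineage = lineage, mult = as.integer(mult))
}

node_is_leaf <- function(node) !is.na(node$lineage)

#' Total leaf multiplicity of a subtree
#'
#' @param node A node of a `rooted_genetree` (e.g. the tree's `$root` or an
#'   element of a node's `$children`).
#' @return Sum of the leaf multiplicities in the clade below `node`.
#' @export
clade_multiplicity <- function(node) {
  if (node_is_leaf(node)) return(node$mult)
  sum(vapply(node$children, clade_multiplicity, numeric(1)))
}

clade_lineages <- function(node) {
  if (node_is_leaf(node)) return(node$lineage)
  unlist(lapply(node$children, clade_lineages), use.names = FALSE)
}

#' Leaf multiplicities of the units directly below a node
#'
#' Returns the total multiplicity of each child subtree of `node` (for the
#' tree root: the top-level branches).  These are the weights used by the
#' backward waiting-time allocation.
#'
#' @param node A tree node (see [clade_multiplicity()]).
#' @return Named numeric vector; names concatenate the lineage ids in each
#'   child clade.
#' @export
child_weights <- function(node) {
  if (node_is_leaf(node)) return(setNames(numeric(0), character(0)))
  w <- vapply(node$children, clade_multiplicity, numeric(1))
  names(w) <- vapply(node$children, function(ch)
    paste(clade_lineages(ch), collapse = ","), character(1))
  w
}

#' Locate the clade spanned by a set of lineages
#'
#' Finds the node of `tree` whose clade contains exactly `lineages`
#' (order-insensitive), or `NULL` if no such clade exists.
#'
#' @param tree A `rooted_genetree`.
#' @param lineages Character vector of lineage ids.
#' @return The matching node, or `NULL`.
#' @export
find_clade <- function(tree, lineages) {
  target <- sort(unique(as.character(lineages)))
  descend <- function(node) {
    if (setequal(clade_lineages(node), target)) return(node)
    for (ch in node$children) {
      got <- descend(ch)
      if (!is.null(got)) return(got)
    }
    NULL
  }
  descend(tree$root)
}

#' Test whether a 0/1 matrix represents a rooted gene tree
#'
#' A 0/1 lineage-by-site matrix corresponds to a rooted gene tree exactly
#' when its column 1-sets form a laminar family (pairwise nested or
#' disjoint), i.e. when no pair of columns exhibits all three gametes
#' (0,1), (1,0) and (1,1).  This is the classical perfect-phylogeny test
#' for binary characters.
#'
#' @param x A [binary_matrix()] or a plain 0/1 matrix.
#' @return `TRUE` or `FALSE`; when `FALSE`, the attribute
#'   `"violating_pair"` holds the (1-based column index) positions of the
#'   first column pair found to display all three gametes.
#' @export
is_valid_matrix <- function(x) {
  m <- if (inherits(x, "binary_matrix")) x$x else {
    mm <- as.matrix(x); storage.mode(mm) <- "integer"; mm
  }
  s <- ncol(m)
  if (s < 2L) return(TRUE)
  for (j in seq_len(s - 1L)) {
    a <- m[, j] == 1L
    for (k in (j + 1L):s) {
      b <- m[, k] == 1L
      if (any(a & b) && any(a & !b) && any(!a & b)) {
        out <- FALSE
        attr(out, "violating_pair") <- c(j, k)
        return(out)
      }
    }
  }
  TRUE
}

# ---- rooted tree construction -------------------------------------------

#' Build the rooted gene tree of a valid 0/1 matrix
#'
#' A valid matrix determines the genealogy uniquely: the clades of the tree
#' are the distinct column 1-sets, sites with identical 1-sets stack on the
#' same edge (kept in ascending site order), and lineages carrying no
#' mutation under the labeling attach directly beneath the root.  Children
#' of every node are ordered by the smallest lineage (row) index in their
#' clade, giving a canonical representation.
#'
#' @param x A [binary_matrix()] (carrying lineage ids and multiplicities),
#'   or a plain 0/1 matrix.
#' @param aln Optional [seg_alignment()] supplying lineage ids and
#'   multiplicities when `x` is a plain matrix.
#' @return An object of class `rooted_genetree` with fields `root` (nested
#'   node list: `sites` on the edge above the node, `children`, and for
#'   leaves `lineage`/`mult`), `lineage_ids`, `multiplicities`,
#'   `site_positions`, `n`, `s`, `matrix` (the input labeling) and
#'   `labeling`.
#' @export
build_rooted_tree <- function(x, aln = NULL) {
  if (!inherits(x, "binary_matrix")) {
    if (!is.null(aln)) {
      x <- binary_matrix(as.matrix(x),
                         lineage_ids = aln$lineage_ids,
                         multiplicities = aln$multiplicities)
    } else {
      x <- binary_matrix(as.matrix(x))
    }
  } else if (!is.null(aln)) {
    if (!identical(as.character(aln$lineage_ids), x$lineage_ids))
      stop("alignment lineage ids do not match the matrix rows")
    if (!identical(as.integer(aln$multiplicities), x$multiplicities))
      stop("alignment multiplicities do not match the matrix")
  }
  ok <- is_valid_matrix(x)
  if (!isTRUE(ok)) {
    pair <- attr(ok, "violating_pair")
    stop("matrix is not a valid rooted-tree representation: columns at ",
         "site positions ", x$site_positions[pair[1]], " and ",
         x$site_positions[pair[2]], " display all three gametes")
  }
  m <- x$x
  R <- nrow(m)
  s <- ncol(m)

  # group columns by identical 1-sets
  groups <- list()
  if (s > 0L) {
    keys <- apply(m, 2L, paste, collapse = "")
    for (key in unique(keys)) {
      cols <- which(keys == key)
      oneset <- which(m[, cols[1]] == 1L)
      if (length(oneset) == 0L) next          # all-zero column cannot occur
      groups[[length(groups) + 1L]] <- list(
        oneset = oneset,
        sites = sort(x$site_positions[cols]))
    }
  }

  make_leaf <- function(i, sites = integer(0))
    new_tnode(sites = sites, lineage = x$lineage_ids[i],
              mult = x$multiplicities[i])

  # children of the scope spanning `members`, given the groups strictly
  # inside that scope
  build_children <- function(members, groups) {
    if (length(groups)) {
      size <- vapply(groups, function(g) length(g$oneset), integer(1))
      maximal <- vapply(seq_along(groups), function(a) {
        !any(vapply(seq_along(groups), function(b) {
          b != a && size[b] > size[a] &&
            all(groups[[a]]$oneset %in% groups[[b]]$oneset)
        }, logical(1)))
      }, logical(1))
    } else maximal <- logical(0)
    kids <- list()
    covered <- integer(0)
    for (g in groups[maximal]) {
      covered <- c(covered, g$oneset)
      if (length(g$oneset) == 1L) {
        kids[[length(kids) + 1L]] <- make_leaf(g$oneset, g$sites)
      } else {
        inner <- Filter(function(h)
          length(h$oneset) < length(g$oneset) &&
            all(h$oneset %in% g$oneset), groups)
        kids[[length(kids) + 1L]] <- new_tnode(
          sites = g$sites,
          children = build_children(g$oneset, inner))
      }
    }
    for (i in setdiff(members, covered))
      kids[[length(kids) + 1L]] <- make_leaf(i)
    ord <- order(vapply(kids, function(k)
      min(match(clade_lineages(k), x$lineage_ids)), numeric(1)))
    kids[ord]
  }

  root <- new_tnode(children = build_children(seq_len(R), groups))
  structure(
    list(root = root,
         lineage_ids = x$lineage_ids,
         multiplicities = x$multiplicities,
         site_positions = x$site_positions,
         n = sum(x$multiplicities),
         s = s,
         matrix = x,
         labeling = x$labeling),
    class = "rooted_genetree")
}

#' @export
print.rooted_genetree <- function(x, ...) {
  cat(sprintf(
    "rooted_genetree (%s): %d lineages, n = %d, s = %d mutations\n",
    x$labeling, length(x$lineage_ids), x$n, x$s))
  invisible(x)
}

#' Recover the 0/1 matrix of a rooted gene tree
#'
#' `x[i, j] = 1` iff site `j` lies on the path from the root to leaf `i`.
#' Inverse of [build_rooted_tree()].
#'
#' @param t A `rooted_genetree`.
#' @return A [binary_matrix()].
#' @export
tree_to_matrix <- function(t) {
  stopifnot(inherits(t, "rooted_genetree"))
  x <- matrix(0L, nrow = length(t$lineage_ids),
              ncol = length(t$site_positions))
  walk <- function(node, path_sites) {
    path_sites <- c(path_sites, node$sites)
    if (node_is_leaf(node)) {
      i <- match(node$lineage, t$lineage_ids)
      x[i, match(path_sites, t$site_positions)] <<- 1L
    } else {
      for (ch in node$children) walk(ch, path_sites)
    }
  }
  walk(t$root, integer(0))
  meta <- t$matrix
  binary_matrix(x,
                lineage_ids = t$lineage_ids,
                multiplicities = t$multiplicities,
                site_positions = t$site_positions,
                mutant_base = if (!is.null(meta)) meta$mutant_base else
                  rep(NA_character_, ncol(x)),
                ancestral_base = if (!is.null(meta)) meta$ancestral_base else
                  rep(NA_character_, ncol(x)),
                labeling = t$labeling)
}

# ---- unrooted reduction --------------------------------------------------

# flatten a rooted tree into parallel arrays (preorder); node 1 is the root
flatten_tree <- function(t) {
  parent <- integer(0); sites <- list(); lineage <- character(0)
  mult <- integer(0)
  add <- function(node, par) {
    id <- length(parent) + 1L
    parent[id] <<- par
    sites[[id]] <<- node$sites
    lineage[id] <<- node$lineage
    mult[id] <<- node$mult
    for (ch in node$children) add(ch, id)
    id
  }
  add(t$root, 0L)
  list(parent = parent, sites = sites, lineage = lineage, mult = mult,
       k = length(parent))
}

#' Reduce a rooted gene tree to its unrooted gene tree
#'
#' Mutation-free pendant and internal edges are contracted (a lineage whose
#' edge carries no mutation is absorbed into its parent vertex), the root is
#' suppressed, and mutation-free degree-2 pass-throughs are straightened by
#' concatenating edge mutation lists in path order.  All `s + 1` rooted
#' trees of a dataset reduce to the same unrooted tree.
#'
#' @param t A `rooted_genetree`.
#' @return An object of class `unrooted_genetree`: `vertices` (per vertex,
#'   the lineage ids and multiplicities co-located there, possibly none) and
#'   `edges` (per edge, endpoints `from`/`to` and the ordered mutation site
#'   list along the edge).
#' @export
to_unrooted <- function(t) {
  stopifnot(inherits(t, "rooted_genetree"))
  fl <- flatten_tree(t)
  # union-find over mutation-free edges
  up <- seq_len(fl$k)
  find <- function(i) { while (up[i] != i) { up[i] <<- up[up[i]]; i <- up[i] }; i }
  for (i in seq_len(fl$k)) {
    if (fl$parent[i] > 0L && length(fl$sites[[i]]) == 0L)
      up[find(i)] <- find(fl$parent[i])
  }
  comp <- vapply(seq_len(fl$k), find, integer(1))
  verts <- unique(comp)
  vid <- match(comp, verts)
  vertices <- lapply(seq_along(verts), function(v) {
    at <- which(vid == v & !is.na(fl$lineage))
    list(lineages = fl$lineage[at], mult = fl$mult[at])
  })
  edges <- list()
  for (i in seq_len(fl$k)) {
    if (fl$parent[i] > 0L && length(fl$sites[[i]]) > 0L)
      edges[[length(edges) + 1L]] <- list(
        from = vid[fl$parent[i]], to = vid[i],
        sites = fl$sites[[i]])
  }
  # straighten: suppress mutation-free degree-2 vertices with no lineages
  repeat {
    deg <- integer(length(vertices))
    for (e in edges) { deg[e$from] <- deg[e$from] + 1L; deg[e$to] <- deg[e$to] + 1L }
    anon <- which(deg == 2L &
                  vapply(vertices, function(v) length(v$lineages) == 0L,
                         logical(1)))
    anon <- anon[vapply(anon, function(v)
      !isTRUE(attr(vertices[[v]], "dead")), logical(1))]
    if (!length(anon)) break
    v <- anon[1]
    at <- which(vapply(edges, function(e) e$from == v || e$to == v,
                       logical(1)))
    e1 <- edges[[at[1]]]; e2 <- edges[[at[2]]]
    if (e1$from == v) e1 <- list(from = e1$to, to = v, sites = rev(e1$sites))
    if (e2$to == v)   e2 <- list(from = v, to = e2$from, sites = rev(e2$sites))
    merged <- list(from = e1$from, to = e2$to, sites = c(e1$sites, e2$sites))
    edges <- c(edges[-at], list(merged))
    attr(vertices[[v]], "dead") <- TRUE
  }
  keep <- which(!vapply(vertices, function(v) isTRUE(attr(v, "dead")),
                        logical(1)))
  remap <- match(seq_along(vertices), keep)
  vertices <- vertices[keep]
  edges <- lapply(edges, function(e)
    list(from = remap[e$from], to = remap[e$to], sites = e$sites))
  structure(
    list(vertices = vertices, edges = edges,
         lineage_ids = t$lineage_ids,
         multiplicities = t$multiplicities,
         site_positions = t$site_positions,
         n = t$n, s = t$s),
    class = "unrooted_genetree")
}

#' @export
print.unrooted_genetree <- function(x, ...) {
  cat(sprintf("unrooted_genetree: %d vertices, %d edges, s = %d mutations\n",
              length(x$vertices), length(x$edges), x$s))
  invisible(x)
}

# vertex indices on the `from` side of each edge (list over edges)
edge_vertex_sides <- function(ut) {
  nv <- length(ut$vertices)
  adj <- vector("list", nv)
  for (ei in seq_along(ut$edges)) {
    e <- ut$edges[[ei]]
    adj[[e$from]] <- c(adj[[e$from]], ei)
    adj[[e$to]] <- c(adj[[e$to]], ei)
  }
  lapply(seq_along(ut$edges), function(ei) {
    e <- ut$edges[[ei]]
    seen <- logical(nv); seen[e$from] <- TRUE
    queue <- e$from
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (fi in adj[[v]]) {
        if (fi == ei) next
        f <- ut$edges[[fi]]
        w <- if (f$from == v) f$to else f$from
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    which(seen)
  })
}

vertices_lineages <- function(ut, vs) {
  unlist(lapply(vs, function(v) ut$vertices[[v]]$lineages),
         use.names = FALSE)
}

# lineage ids on the `from` side of each edge (list over edges)
edge_sides <- function(ut) {
  lapply(edge_vertex_sides(ut), function(vs) vertices_lineages(ut, vs))
}

# canonical, labeling-independent signature of an unrooted gene tree; two
# trees on the same lineage set are isomorphic iff signatures match
unrooted_signature <- function(ut) {
  sides <- edge_sides(ut)
  edge_desc <- vapply(seq_along(ut$edges), function(ei) {
    A <- sort(sides[[ei]])
    B <- sort(setdiff(ut$lineage_ids, A))
    # all sites on a straightened edge share one lineage bipartition, so
    # within-edge order is stacking convention, not structure
    ss <- sort(ut$edges[[ei]]$sites)
    bip <- if (paste(A, collapse = ",") <= paste(B, collapse = ","))
      c(A, "|", B) else c(B, "|", A)
    paste(paste(bip, collapse = ","), paste(ss, collapse = ","),
          sep = " :: ")
  }, character(1))
  vert_desc <- sort(vapply(ut$vertices, function(v)
    paste(sort(v$lineages), collapse = ","), character(1)))
  paste(c(sort(edge_desc), "//", vert_desc[vert_desc != ""]),
        collapse = " ; ")
}

# ---- enumeration of the s+1 rooted trees ---------------------------------

#' Enumerate all rooted gene trees compatible with the data
#'
#' For data with `s` segregating sites there are exactly `s + 1` rooted
#' trees (equivalently, `s + 1` valid labelings of the mutant base at each
#' site): one per vertex of the unrooted gene tree, plus one per gap
#' between two adjacent mutations on an unrooted edge.  Each candidate root
#' position yields the labeling in which site `j` is carried by lineage `i`
#' iff `j` lies on the path from the root position to `i`.
#'
#' @param x A valid [binary_matrix()] (e.g. from [label_least_shared()]).
#' @param aln Optional [seg_alignment()] (see [build_rooted_tree()]).
#' @return List of `s + 1` pairwise distinct `rooted_genetree` objects, the
#'   input labeling's tree among them, all reducing to the same unrooted
#'   tree.  An internal consistency error is raised if the enumeration does
#'   not produce exactly `s + 1` distinct trees.
#' @export
enumerate_rooted_trees <- function(x, aln = NULL) {
  t0 <- build_rooted_tree(x, aln)
  bm <- t0$matrix
  ut <- to_unrooted(t0)
  vsides <- edge_vertex_sides(ut)
  sides <- lapply(vsides, function(vs) vertices_lineages(ut, vs))
  R <- length(bm$lineage_ids)
  pos <- bm$site_positions

  candidates <- list()
  base <- matrix(0L, nrow = R, ncol = length(pos),
                 dimnames = list(bm$lineage_ids, pos))
  set_col <- function(m, site, lineages) {
    col <- match(site, pos)
    m[, col] <- 0L
    m[match(lineages, bm$lineage_ids), col] <- 1L
    m
  }
  # roots at vertices
  for (v in seq_along(ut$vertices)) {
    m <- base
    for (ei in seq_along(ut$edges)) {
      e <- ut$edges[[ei]]
      A <- sides[[ei]]                         # lineages on the `from` side
      B <- setdiff(bm$lineage_ids, A)
      far <- if (v %in% vsides[[ei]]) B else A
      for (sj in e$sites) m <- set_col(m, sj, far)
    }
    candidates[[length(candidates) + 1L]] <- m
  }
  # roots between adjacent mutations on an edge: relative to the rooting at
  # the edge's `from` vertex, the first `gap` mutations now separate the
  # root from the `from` side
  for (ei in seq_along(ut$edges)) {
    e <- ut$edges[[ei]]
    d <- length(e$sites)
    if (d < 2L) next
    A <- sides[[ei]]
    B <- setdiff(bm$lineage_ids, A)
    for (gap in seq_len(d - 1L)) {
      m <- candidates[[e$from]]
      for (a in seq_len(d))
        m <- set_col(m, e$sites[a], if (a <= gap) A else B)
      candidates[[length(candidates) + 1L]] <- m
    }
  }

  keys <- vapply(candidates, function(m) paste(m, collapse = ""),
                 character(1))
  if (anyDuplicated(keys) || length(candidates) != bm_s(bm) + 1L)
    stop("internal consistency error: enumeration produced ",
         length(unique(keys)), " distinct rooted trees, expected s + 1 = ",
         bm_s(bm) + 1L)

  trees <- vector("list", length(candidates))
  base_key <- paste(bm$x, collapse = "")
  for (r in seq_along(candidates)) {
    m <- candidates[[r]]
    flipped <- colSums(m != bm$x) > 0L
    mut <- ifelse(flipped, bm$ancestral_base, bm$mutant_base)
    anc <- ifelse(flipped, bm$mutant_base, bm$ancestral_base)
    tag <- if (keys[r] == base_key) bm$labeling else
      paste0("enumerated-root-", r)
    xm <- binary_matrix(m, lineage_ids = bm$lineage_ids,
                        multiplicities = bm$multiplicities,
                        site_positions = pos,
                        mutant_base = mut, ancestral_base = anc,
                        labeling = tag)
    trees[[r]] <- build_rooted_tree(xm)
  }
  if (!base_key %in% keys)
    stop("internal consistency error: input labeling not among the ",
         "enumerated rootings")
  trees
}

bm_s <- function(bm) ncol(bm$x)

# ---- Newick serialization ------------------------------------------------

#' Write a rooted gene tree in annotated Newick format
#'
#' Leaf multiplicities and per-edge mutation site lists are carried in
#' `[&mult=...,sites={...}]` comment blocks after each node; standard
#' Newick readers that skip square-bracket comments recover the topology.
#'
#' @param t A `rooted_genetree`.
#' @param path Optional output file; when `NULL` the string is returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(t, path = NULL) {
  stopifnot(inherits(t, "rooted_genetree"))
  annot <- function(node) {
    parts <- character(0)
    if (node_is_leaf(node))
      parts <- c(parts, paste0("mult=", node$mult))
    if (length(node$sites))
      parts <- c(parts, paste0("sites={", paste(node$sites, collapse = ","),
                               "}"))
    if (length(parts)) paste0("[&", paste(parts, collapse = ","), "]") else ""
  }
  render <- function(node) {
    core <- if (node_is_leaf(node)) node$lineage else
      paste0("(", paste(vapply(node$children, render, character(1)),
                        collapse = ","), ")")
    paste0(core, annot(node))
  }
  nwk <- paste0(render(t$root), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Read a rooted gene tree from annotated Newick
#'
#' Parses the dialect emitted by [write_newick()], including the
#' `[&mult=...,sites={...}]` annotations.
#'
#' @param text A Newick string, or (if `path` given) `NULL`.
#' @param path Optional path to read from.
#' @return A `rooted_genetree`.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text) || substring(text, nchar(text)) != ";")
    stop("not a Newick string (missing terminating ';')")
  chars <- strsplit(substr(text, 1L, nchar(text) - 1L), "")[[1]]
  i <- 1L
  peek <- function() if (i <= length(chars)) chars[i] else ""
  take_label <- function() {
    start <- i
    while (i <= length(chars) && !peek() %in% c("(", ")", ",", "[", ";"))
      i <<- i + 1L
    paste(chars[start:(i - 1L)], collapse = "")
  }
  take_annot <- function() {
    mult <- NA_integer_; sites <- integer(0)
    if (peek() == "[") {
      start <- i
      while (i <= length(chars) && peek() != "]") i <<- i + 1L
      if (peek() != "]") stop("unterminated [&...] comment")
      ann <- paste(chars[start:i], collapse = "")
      i <<- i + 1L
      mm <- regmatches(ann, regexec("mult=([0-9]+)", ann))[[1]]
      if (length(mm) == 2L) mult <- as.integer(mm[2])
      sm <- regmatches(ann, regexec("sites=\\{([0-9,]*)\\}", ann))[[1]]
      if (length(sm) == 2L && nzchar(sm[2]))
        sites <- as.integer(strsplit(sm[2], ",")[[1]])
    }
    list(mult = mult, sites = sites)
  }
  parse_node <- function() {
    if (peek() == "(") {
      i <<- i + 1L
      children <- list(parse_node())
      while (peek() == ",") {
        i <<- i + 1L
        children[[length(children) + 1L]] <- parse_node()
      }
      if (peek() != ")") stop("malformed Newick: expected ')'")
      i <<- i + 1L
      if (!peek() %in% c("[", ",", ")", "")) take_label()  # drop node label
      ann <- take_annot()
      new_tnode(sites = ann$sites, children = children)
    } else {
      lab <- take_label()
      if (!nzchar(lab)) stop("malformed Newick: empty leaf label")
      ann <- take_annot()
      new_tnode(sites = ann$sites, lineage = lab,
                mult = if (is.na(ann$mult)) 1L else ann$mult)
    }
  }
  root <- parse_node()
  ids <- clade_lineages(root)
  mults <- integer(length(ids))
  sites <- integer(0)
  walk <- function(node) {
    sites <<- c(sites, node$sites)
    if (node_is_leaf(node))
      mults[match(node$lineage, ids)] <<- node$mult
    else for (ch in node$children) walk(ch)
  }
  walk(root)
  t <- structure(
    list(root = root, lineage_ids = ids, multiplicities = mults,
         site_positions = sort(sites), n = sum(mults), s = length(sites),
         matrix = NULL, labeling = "newick"),
    class = "rooted_genetree")
  t$matrix <- tree_to_matrix(t)
  t
}
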