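#' Weight bonus for the number of nucleotide types at a site
#'
#' The position score rewards sites by allele diversity: a biallelic site
#' gets the full bonus of 1 (a clean binary cut), tri- and tetra-allelic
#' sites the tabulated constants 0.66 and 0.33, and an invariant site 0.
#' The constants are the printed decimals, not 2/3 and 1/3, so that score
#' ties are exact.
#'
#' @param n_types number of distinct canonical bases observed (1..4).
#' @return The weight: 0, 1, 0.66 or 0.33.
#' @export
type_weight <- function(n_types) {
  n_types <- as.integer(n_types)
  if (is.na(n_types) || n_types < 1L || n_types > 4L)
    stop("n_types must be 1, 2, 3 or 4")
  c(0, 1, 0.66, 0.33)[n_types]
}

# weight * 100 as an exact integer, for tie-proof score comparison
type_weight100 <- function(n_types) c(0L, 100L, 66L, 33L)[n_types]

#' Balance-and-diversity score of one alignment position
#'
#' For a node holding n sequences, mid = n/2 and diff is the smallest
#' |mid - f_i| over the four canonical base counts f_i: diff measures how
#' close the best single-nucleotide cut comes to splitting the node in half.
#' The score is (mid - diff)/mid + weight, where the weight is
#' [type_weight()] of the number of bases present. It ranges over [0, 2];
#' a perfectly balanced biallelic site attains 2.
#'
#' Scores are compared through an exact integer key (the score scaled by
#' 100 n), so ranking and tie detection never depend on floating point.
#'
#' @param counts counts of A, C, G, T at the site (length-4 vector, in that
#'   order, or named).
#' @param node_size number of sequences in the node; must equal sum(counts).
#' @param position optional 1-based site index carried along for reporting.
#' @return An object of class `score_breakdown`: list with `position`,
#'   `mid`, `diff`, `n_types`, `weight`, `score` and the integer comparison
#'   `key`.
#' @export
position_score <- function(counts, node_size, position = NA_integer_) {
  counts <- as.integer(counts)
  if (length(counts) != 4L || anyNA(counts) || any(counts < 0L))
    stop("counts must be 4 non-negative integers (A, C, G, T)")
  node_size <- as.integer(node_size)
  if (node_size < 2L) stop("node_size must be >= 2")
  if (sum(counts) != node_size)
    stop("counts sum to ", sum(counts), " but node_size is ", node_size)
  # diff2 = 2 * diff is integral even for odd node sizes
  diff2 <- min(abs(node_size - 2L * counts))
  n_types <- sum(counts > 0L)
  weight <- type_weight(n_types)
  structure(list(position = as.integer(position),
                 mid = node_size / 2,
                 diff = diff2 / 2,
                 n_types = n_types,
                 weight = weight,
                 score = (node_size - diff2) / node_size + weight,
                 key = 100L * (node_size - diff2) +
                       type_weight100(n_types) * node_size),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("position %s: mid=%g diff=%g types=%d weight=%g score=%g\n",
              ifelse(is.na(x$position), "?", x$position),
              x$mid, x$diff, x$n_types, x$weight, x$score))
  invisible(x)
}

# pivot = base whose count is closest to mid (argmin of |mid - f_i|),
# alphabetical tie-break. For a variable site every present base has
# 0 < f < n hence diff < mid, so the pivot is always a present base.
pivot_base <- function(counts, node_size) {
  diffs2 <- abs(node_size - 2L * counts)
  DNA_BASES[which.min(diffs2)]  # which.min takes the first, i.e. A < C < G < T
}

# candidate positions at a node: globally non-excluded AND variable within
# the subset
candidate_positions <- function(a, row_subset, global_excluded) {
  sub <- a$matrix[row_subset, , drop = FALSE]
  variable <- vapply(seq_len(ncol(sub)), function(p) {
    u <- unique(sub[, p])
    length(u) >= 2L
  }, logical(1L))
  setdiff(which(variable), global_excluded)
}

#' Best split of a node's species subset
#'
#' Scans all candidate positions (no gap or ambiguity symbol anywhere in the
#' full panel, and variable within the subset) and returns the position with
#' the maximal score; ties go to the smallest position index. The pivot is
#' the nucleotide whose subset count is closest to mid (ties broken
#' alphabetically); species carrying the pivot form the left branch.
#'
#' With `criterion = "gain"` or `"gini"` the same candidate (position,
#' pivot) scan is ranked by information gain (maximised) or by size-weighted
#' child Gini impurity (minimised) instead; see [information_gain()] and
#' [gini_index()].
#'
#' @param a an [aligned_set()].
#' @param row_subset integer row indices of the node's species (>= 2).
#' @param criterion `"dtsb"` (default), `"gain"` or `"gini"`.
#' @return List with `position`, `pivot`, and `score` (a `score_breakdown`
#'   for `"dtsb"`, the criterion value otherwise).
#' @export
best_split <- function(a, row_subset, criterion = c("dtsb", "gain", "gini")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(a, "aligned_set"))
  row_subset <- as.integer(row_subset)
  if (length(row_subset) < 2L) stop("row subset must hold >= 2 species")
  global_excluded <- nucleotide_distribution(a)$excluded
  cand <- candidate_positions(a, row_subset, global_excluded)
  if (length(cand) == 0L)
    stop("indistinguishable species: no variable non-excluded position ",
         "separates { ", paste(a$labels[row_subset], collapse = ", "), " }")
  n <- length(row_subset)
  sub <- a$matrix[row_subset, , drop = FALSE]
  if (criterion == "dtsb") {
    best <- NULL
    for (p in cand) {
      cnt <- tabulate_bases(sub[, p])
      sc <- position_score(cnt, n, position = p)
      if (is.null(best) || sc$key > best$key) best <- sc
    }
    cnt <- tabulate_bases(sub[, best$position])
    list(position = best$position, pivot = pivot_base(cnt, n), score = best)
  } else {
    best_split_impurity(sub, cand, n, criterion)
  }
}

tabulate_bases <- function(column) {
  vapply(DNA_BASES, function(b) sum(column == b), integer(1L))
}

#' Binary decision tree over SNP sites
#'
#' Greedy recursive construction: at each node the site distribution of the
#' node's species subset is scored, the node splits on [best_split()]
#' (left = species carrying the pivot nucleotide, right = the rest), and
#' recursion stops when a subset is a single species. Positions may be
#' selected repeatedly in different subtrees. The result is a strictly
#' binary tree with one leaf per species: N leaves and N - 1 decision nodes.
#'
#' @param a a trimmed [aligned_set()]; every pair of species must differ at
#'   some candidate position.
#' @param criterion split criterion, see [best_split()].
#' @return The root `decision_node`: a recursive list with fields `kind`
#'   ("decision" or "leaf"), `level` (root = 1), and either
#'   `position`/`pivot`/`left`/`right` or `species`.
#' @export
build_tree <- function(a, criterion = c("dtsb", "gain", "gini")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(a, "aligned_set"))
  root <- grow_node(a, seq_len(nrow(a$matrix)), 1L, criterion)
  structure(root, class = "decision_node",
            alignment_width = ncol(a$matrix), criterion = criterion)
}

grow_node <- function(a, rows, level, criterion) {
  if (length(rows) == 1L)
    return(list(kind = "leaf", species = a$labels[rows], level = level))
  split <- best_split(a, rows, criterion)
  carriers <- rows[a$matrix[rows, split$position] == split$pivot]
  rest <- setdiff(rows, carriers)
  # variable candidate site: both sides are non-empty by construction
  list(kind = "decision", position = split$position, pivot = split$pivot,
       level = level,
       left = grow_node(a, carriers, level + 1L, criterion),
       right = grow_node(a, rest, level + 1L, criterion))
}

#' @export
print.decision_node <- function(x, ...) {
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$kind == "leaf") {
      cat(pad, "- ", node$species, "\n", sep = "")
    } else {
      cat(pad, "p", node$position, " == ", node$pivot,
          "? (level ", node$level, ")\n", sep = "")
      show(node$left, indent + 1L)
      show(node$right, indent + 1L)
    }
  }
  show(x, 0L)
  invisible(x)
}

tree_leaves <- function(tree) {
  if (tree$kind == "leaf") return(tree$species)
  c(tree_leaves(tree$left), tree_leaves(tree$right))
}

tree_decision_count <- function(tree) {
  if (tree$kind == "leaf") return(0L)
  1L + tree_decision_count(tree$left) + tree_decision_count(tree$right)
}

#' Classify an aligned sequence by walking the tree
#'
#' From the root: go left if the sequence carries the pivot nucleotide at
#' the node's position, else right; the leaf reached names the species.
#' Valid only for sequences aligned to the same coordinate frame the tree
#' was built on (same column count).
#'
#' @param tree a `decision_node` from [build_tree()].
#' @param sequence a single aligned sequence: character string or vector of
#'   symbols, length equal to the tree's alignment width.
#' @return The species label at the leaf reached.
#' @export
classify <- function(tree, sequence) {
  stopifnot(inherits(tree, "decision_node"))
  if (is.character(sequence) && length(sequence) == 1L)
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sequence <- toupper(sequence)
  width <- attr(tree, "alignment_width")
  if (!is.null(width) && length(sequence) != width)
    stop("sequence length ", length(sequence),
         " does not match the tree's alignment width ", width)
  node <- tree
  while (node$kind != "leaf") {
    sym <- sequence[node$position]
    if (!(sym %in% DNA_BASES))
      stop("unclassifiable: symbol '", sym, "' at decision position ",
           node$position)
    node <- if (sym == node$pivot) node$left else node$right
  }
  node$species
}

#' Serialize a decision tree to JSON
#'
#' Deterministic export: each node carries `kind`, `level`, and either
#' `position`/`pivot`/`left`/`right` (children in that order) or `species`.
#' The alignment width and criterion are stored at the top level.
#'
#' @param tree a `decision_node`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "decision_node"))
  strip <- function(node) {
    if (node$kind == "leaf")
      list(kind = "leaf", species = node$species, level = node$level)
    else
      list(kind = "decision", position = node$position, pivot = node$pivot,
           level = node$level, left = strip(node$left),
           right = strip(node$right))
  }
  obj <- list(alignment_width = attr(tree, "alignment_width"),
              criterion = attr(tree, "criterion"),
              root = strip(tree))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a decision tree from JSON
#'
#' @param path a file written by [write_tree_json()].
#' @return A `decision_node`.
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path)
  rebuild <- function(node) {
    if (node$kind == "leaf")
      list(kind = "leaf", species = node$species,
           level = as.integer(node$level))
    else
      list(kind = "decision", position = as.integer(node$position),
           pivot = node$pivot, level = as.integer(node$level),
           left = rebuild(node$left), right = rebuild(node$right))
  }
  structure(rebuild(obj$root), class = "decision_node",
            alignment_width = as.integer(obj$alignment_width),
            criterion = obj$criterion)
}

#' Render a decision tree in Graphviz DOT format
#'
#' @param tree a `decision_node`.
#' @return A character string of DOT source.
#' @export
tree_to_dot <- function(tree) {
  stopifnot(inherits(tree, "decision_node"))
  lines <- c("digraph dtsb {", "  node [fontname=\"Helvetica\"];")
  counter <- new.env(); counter$i <- 0L
  emit <- function(node) {
    counter$i <- counter$i + 1L
    id <- paste0("n", counter$i)
    if (node$kind == "leaf") {
      lines <<- c(lines, sprintf("  %s [shape=box,label=\"%s\"];",
                                 id, node$species))
    } else {
      lines <<- c(lines, sprintf("  %s [shape=circle,label=\"p%d\"];",
                                 id, node$position))
      lid <- emit(node$left)
      rid <- emit(node$right)
      lines <<- c(lines,
                  sprintf("  %s -> %s [label=\"%s\"];", id, lid, node$pivot),
                  sprintf("  %s -> %s [label=\"not %s\"];", id, rid, node$pivot))
    }
    id
  }
  emit(tree)
  paste(c(lines, "}"), collapse = "\n")
}
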