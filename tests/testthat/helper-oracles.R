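# Independent brute-force oracles, kept deliberately separate from the
# package's implementation paths.

BASES <- c("A", "C", "G", "T")

# plain floating-point re-derivation of the position score
oracle_score <- function(counts, n) {
  mid <- n / 2
  diff <- min(abs(mid - counts))
  weight <- c(0, 1, 0.66, 0.33)[sum(counts > 0)]
  (mid - diff) / mid + weight
}

# scan every candidate position of a node subset: argmax score with
# smallest-index tie-break; pivot = argmin |mid - f| with alphabetical
# tie-break
oracle_best_split <- function(a, rows) {
  sub <- a$matrix[rows, , drop = FALSE]
  full_excluded <- which(apply(a$matrix, 2, function(col) any(!col %in% BASES)))
  cand <- setdiff(which(apply(sub, 2, function(col) length(unique(col)) > 1)),
                  full_excluded)
  scores <- vapply(cand, function(p) {
    cnt <- vapply(BASES, function(b) sum(sub[, p] == b), numeric(1))
    oracle_score(cnt, length(rows))
  }, numeric(1))
  p <- cand[which.max(scores)]        # first maximum = smallest index
  cnt <- vapply(BASES, function(b) sum(sub[, p] == b), numeric(1))
  pivot <- BASES[which.min(abs(length(rows) / 2 - cnt))]
  list(position = p, pivot = pivot, score = max(scores))
}

# enumerate all multisets of size k drawn from m distinct items
oracle_multiset_count <- function(m, k) {
  count <- function(m_left, k_left) {
    if (k_left == 0) return(1)
    if (m_left == 0) return(0)
    count(m_left - 1, k_left) + count(m_left, k_left - 1)
  }
  count(m, k)
}

# walk a built tree and recover every decision node's row subset
tree_node_subsets <- function(tree, a) {
  out <- list()
  walk <- function(node, rows) {
    if (node$kind == "leaf") return()
    out[[length(out) + 1]] <<- list(rows = rows, position = node$position,
                                    pivot = node$pivot)
    carriers <- rows[a$matrix[rows, node$position] == node$pivot]
    walk(node$left, carriers)
    walk(node$right, setdiff(rows, carriers))
  }
  walk(tree, seq_len(nrow(a$matrix)))
  out
}

# seeded panel family used by the property suites: alignment length scales
# with panel size so discriminability is generically attainable
draw_panel <- function(i) {
  set.seed(10000 + i)
  n <- sample(2:20, 1)
  m <- sample(max(4, 2 * n):200, 1)
  random_panel(n, m, seed = 20000 + i)
}
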