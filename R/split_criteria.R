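#' Binary entropy of a two-class sample
#'
#' Info(p, n) = -D_p log2(D_p) - D_n log2(D_n) with D_p = p/(p+n),
#' D_n = n/(p+n) and 0 log2(0) = 0. Maximal (1 bit) at p = n, zero for a
#' pure node.
#'
#' @param p count of positive-target samples (>= 0).
#' @param n count of negative-target samples (>= 0); p + n >= 1.
#' @return Entropy in bits.
#' @export
info_bits <- function(p, n) {
  if (p < 0 || n < 0) stop("counts must be non-negative")
  if (p + n < 1) stop("p + n must be >= 1")
  plogp <- function(q) if (q == 0) 0 else -q * log2(q)
  plogp(p / (p + n)) + plogp(n / (p + n))
}

#' Expected entropy of a partition
#'
#' Size-weighted mean of the children's [info_bits()]: for children with
#' counts (p_i, n_i), E = sum (p_i + n_i)/(p + n) * Info(p_i, n_i).
#'
#' @param partition list of length-2 vectors `c(p, n)` (or a 2-column
#'   matrix), one per child.
#' @return Expected entropy in bits.
#' @export
expected_entropy <- function(partition) {
  partition <- as_partition(partition)
  if (length(partition) == 0L) stop("partition must be non-empty")
  sizes <- vapply(partition, sum, numeric(1L))
  total <- sum(sizes)
  if (total < 1) stop("partition is empty overall")
  sum(vapply(partition,
             function(cell) sum(cell) / total * info_bits(cell[1L], cell[2L]),
             numeric(1L)))
}

#' Information gain of a split
#'
#' Gain = Info(parent) - expected entropy of the children; non-negative for
#' every partition whose cells sum to the parent (concavity of entropy).
#'
#' @param parent length-2 vector `c(p, n)` of parent class counts.
#' @param partition as in [expected_entropy()]; cells must sum to `parent`.
#' @return Gain in bits.
#' @export
information_gain <- function(parent, partition) {
  partition <- as_partition(partition)
  child_sum <- Reduce(`+`, partition)
  if (!isTRUE(all.equal(as.numeric(child_sum), as.numeric(parent))))
    stop("partition cells (", paste(child_sum, collapse = ","),
         ") do not sum to the parent (", paste(parent, collapse = ","), ")")
  info_bits(parent[1L], parent[2L]) - expected_entropy(partition)
}

as_partition <- function(partition) {
  if (is.matrix(partition))
    partition <- lapply(seq_len(nrow(partition)), function(i) partition[i, ])
  lapply(partition, function(cell) {
    if (length(cell) != 2L || any(cell < 0)) stop("each cell must be c(p, n) with p, n >= 0")
    as.numeric(cell)
  })
}

#' Gini impurity of a class distribution
#'
#' Gini = 1 - sum P(i|e)^2 over the classes present at the node: 0 for a
#' pure node, maximal for the uniform distribution.
#'
#' @param probs class probabilities; must sum to 1. Alternatively class
#'   counts via `counts = TRUE`.
#' @param counts if TRUE, `probs` are raw class counts and are normalised.
#' @return Gini impurity in [0, 1).
#' @export
gini_index <- function(probs, counts = FALSE) {
  probs <- as.numeric(probs)
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (counts) {
    if (sum(probs) == 0) stop("empty node")
    probs <- probs / sum(probs)
  } else if (abs(sum(probs) - 1) > 1e-9) {
    stop("probabilities must sum to 1 (got ", sum(probs), ")")
  }
  1 - sum(probs^2)
}

# --- impurity-based split selection for build_tree -----------------------
# Multi-class extension over species labels (each panel row is its own
# class): candidate splits are (position, pivot) with the pivot present in
# 0 < count < n rows; "gain" maximises the entropy drop
# H(n) - [l/n H(l) + r/n H(r)] with H(m) = log2(m) for m singleton classes;
# "gini" minimises the size-weighted child Gini. Ties: smaller position,
# then alphabetical pivot.

multiclass_entropy_bits <- function(sizes) {
  p <- sizes / sum(sizes)
  p <- p[p > 0]
  -sum(p * log2(p))
}

best_split_impurity <- function(sub, cand, n, criterion) {
  best <- NULL
  for (p in cand) {
    cnt <- tabulate_bases(sub[, p])
    for (b in DNA_BASES[cnt > 0L & cnt < n]) {
      l <- cnt[b]
      r <- n - l
      # one sequence per species: every row is a singleton class
      value <- if (criterion == "gain") {
        log2(n) - (l / n * log2(l) + r / n * log2(r))
      } else {
        -(l / n * gini_index(rep(1 / l, l)) + r / n * gini_index(rep(1 / r, r)))
      }
      if (is.null(best) || value > best$value + 1e-12) {
        best <- list(position = p, pivot = b, value = value)
      }
    }
  }
  list(position = best$position, pivot = best$pivot, score = best$value)
}
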