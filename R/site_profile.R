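#' Per-position nucleotide distribution
#'
#' Tallies the counts f_i^p of each canonical base i in {A, C, G, T} at every
#' alignment column p, over a subset of rows (a tree node's species set, or
#' the full panel). Columns in which any subset row carries a gap or an
#' ambiguity symbol are flagged as excluded: counts are defined over the four
#' canonical bases only, so such columns are never split candidates.
#'
#' @param a an [aligned_set()].
#' @param row_subset integer vector of row indices; defaults to all rows.
#' @return An object of class `site_distribution`: list with `counts` (4 x M
#'   integer matrix, rows A/C/G/T), `n_rows` (subset size), `excluded`
#'   (integer vector of excluded positions).
#' @export
nucleotide_distribution <- function(a, row_subset = seq_len(nrow(a$matrix))) {
  stopifnot(inherits(a, "aligned_set"))
  row_subset <- as.integer(row_subset)
  if (length(row_subset) == 0L) stop("empty row subset")
  if (any(row_subset < 1L | row_subset > nrow(a$matrix)))
    stop("row subset out of range")
  sub <- a$matrix[row_subset, , drop = FALSE]
  counts <- vapply(DNA_BASES, function(b) colSums(sub == b),
                   numeric(ncol(sub)))
  counts <- t(matrix(as.integer(counts), ncol = 4L,
                     dimnames = list(NULL, DNA_BASES)))
  excluded <- which(colSums(counts) < length(row_subset))
  structure(list(counts = counts, n_rows = length(row_subset),
                 excluded = as.integer(excluded)),
            class = "site_distribution")
}

#' @export
print.site_distribution <- function(x, ...) {
  cat("site_distribution:", ncol(x$counts), "positions over", x$n_rows,
      "sequences;", length(x$excluded), "excluded (gap/ambiguity)\n")
  invisible(x)
}

#' Variable (SNP) positions of an alignment
#'
#' A position is a SNP candidate when at least two canonical bases have
#' nonzero count there. Excluded positions (gap/ambiguity in any row of the
#' profiled subset) are never reported.
#'
#' @param d a `site_distribution` from [nucleotide_distribution()].
#' @return Ascending integer vector of variable positions.
#' @export
variable_positions <- function(d) {
  stopifnot(inherits(d, "site_distribution"))
  n_types <- colSums(d$counts > 0L)
  pos <- which(n_types >= 2L)
  as.integer(setdiff(pos, d$excluded))
}

#' Export a site distribution as TSV
#'
#' Columns: position, count_A, count_C, count_G, count_T, excluded (0/1).
#'
#' @param d a `site_distribution`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_site_table <- function(d, path) {
  stopifnot(inherits(d, "site_distribution"))
  tab <- data.frame(position = seq_len(ncol(d$counts)),
                    count_A = d$counts["A", ], count_C = d$counts["C", ],
                    count_G = d$counts["G", ], count_T = d$counts["T", ],
                    excluded = as.integer(seq_len(ncol(d$counts)) %in% d$excluded))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bounds on the number of SNP sites needed to separate a panel
#'
#' With four nucleotide states per site, N species need at least ceiling(N/4)
#' perfectly informative sites; in the least informative case a binary
#' decision tree needs N - 1 sites. The interval P = [p_min, p_max] brackets
#' the per-species barcode length the tree can produce.
#'
#' @param n_species panel size N (>= 2).
#' @return List with integer elements `p_min` and `p_max`.
#' @export
barcode_length_bounds <- function(n_species) {
  n_species <- as.integer(n_species)
  if (is.na(n_species) || n_species < 2L) stop("n_species must be >= 2")
  list(p_min = as.integer(ceiling(n_species / 4)),
       p_max = n_species - 1L)
}

#' Number of candidate SNP-site multisets for a panel
#'
#' In the worst case a tree over N species uses p_max = N - 1 decision sites,
#' repetition allowed; drawing N - 1 sites with repetition from M SNPs is a
#' permutation-with-repetition problem with H = C(N - 1 + M - 1, N - 1)
#' outcomes. Computed in exact arbitrary-precision integer arithmetic (the
#' panel in the worked Columbidae analysis gives C(200, 16), beyond 2^53).
#'
#' @param n_species panel size N (>= 2).
#' @param n_snps number of available SNP sites M (>= 1).
#' @return The exact count as a `bigint`: a decimal digit string with a
#'   numeric `as.numeric()` method.
#' @export
snp_combination_count <- function(n_species, n_snps) {
  n_species <- as.integer(n_species); n_snps <- as.integer(n_snps)
  if (is.na(n_species) || n_species < 2L) stop("n_species must be >= 2")
  if (is.na(n_snps) || n_snps < 1L) stop("n_snps must be >= 1")
  big_binomial(n_species - 1L + n_snps - 1L, n_species - 1L)
}

# --- exact big-integer binomial ------------------------------------------
# Little-endian base-1e4 representation; only multiply/divide by a small
# integer are needed: C(n,k) = prod_{i=1..k} (n-k+i)/i with each division
# exact (the running product after i factors is C(n-k+i, i)).

big_from_int <- function(x) {
  stopifnot(x >= 0)
  v <- integer(0)
  repeat {
    v <- c(v, x %% 10000L)
    x <- x %/% 10000L
    if (x == 0L) break
  }
  v
}

big_mul_small <- function(v, m) {
  carry <- 0
  out <- numeric(length(v))
  for (j in seq_along(v)) {
    t <- v[j] * m + carry
    out[j] <- t %% 10000
    carry <- t %/% 10000
  }
  while (carry > 0) {
    out <- c(out, carry %% 10000)
    carry <- carry %/% 10000
  }
  out
}

big_div_small <- function(v, m) {
  out <- numeric(length(v))
  rem <- 0
  for (j in rev(seq_along(v))) {
    t <- rem * 10000 + v[j]
    out[j] <- t %/% m
    rem <- t %% m
  }
  if (rem != 0) stop("internal error: inexact big-integer division")
  while (length(out) > 1L && out[length(out)] == 0) out <- out[-length(out)]
  out
}

big_to_string <- function(v) {
  digits <- c(format(v[length(v)], scientific = FALSE),
              sprintf("%04d", rev(v[-length(v)])))
  paste(digits, collapse = "")
}

big_binomial <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 0L || k > n) stop("need 0 <= k <= n")
  k <- min(k, n - k)
  v <- big_from_int(1L)
  for (i in seq_len(k)) {
    v <- big_mul_small(v, n - k + i)
    v <- big_div_small(v, i)
  }
  structure(big_to_string(v), class = "bigint")
}

#' @export
print.bigint <- function(x, ...) {
  cat(unclass(x), "\n")
  invisible(x)
}

#' @export
as.numeric.bigint <- function(x, ...) as.numeric(unclass(x))

#' @export
as.character.bigint <- function(x, ...) unclass(x)
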