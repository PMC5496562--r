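#' Worked-example 8-species panel
#'
#' A fixed 8 x 8 alignment reconstructing the published worked example of
#' the tree-induction score (the original matrix is only available as a
#' figure): position 1 has base counts (A, C, G, T) = (0, 7, 0, 1) and
#' position 6 has (0, 4, 0, 4), all rows are pairwise distinct, the root
#' split lands on position 6 with the maximal score 2, the tree uses
#' positions {1, 2, 5, 6, 7, 8}, and position 8 is selected twice (left
#' side of level 2, and the left child at level 3 under the right side of
#' level 2).
#'
#' @return An [aligned_set()] of 8 species ("S1".."S8") x 8 positions.
#' @export
figure3_fixture <- function() {
  rows <- c(S1 = "CAAAACAA",
            S2 = "CCAAACAA",
            S3 = "CAAAACAG",
            S4 = "CAAAGCAG",
            S5 = "CAAAATCA",
            S6 = "CAAAATCG",
            S7 = "CAAAATTA",
            S8 = "TAAAATTA")
  aligned_set(names(rows), unname(rows))
}

#' Staggered-ends alignment for trimming tests
#'
#' A small 4-species alignment whose records protrude unequally at the 5'
#' and 3' ends (terminal gaps), with a common region known by construction:
#' alignment columns 4..11 (8 columns, so trimming removes 3 leading and 1
#' trailing column).
#'
#' @return An untrimmed [aligned_set()] of 4 species x 12 columns.
#' @export
protruding_ends_fixture <- function() {
  rows <- c(S1 = "---CAGTACGAT",
            S2 = "TTTCAGCACGA-",
            S3 = "GGTCAGAACGTT",
            S4 = "--TCAGTTCGT-")
  aligned_set(names(rows), unname(rows))
}

#' Seeded random species panel
#'
#' Draws a root sequence uniformly over A/C/G/T and derives each species by
#' independent per-site substitution to a random different base with
#' probability `sub_rate` — a deliberately simple star-shaped divergence
#' model (no transition bias, no rate heterogeneity). Optional per-site
#' allele-count constraints pin selected columns to an exact (A, C, G, T)
#' count 4-tuple (a random permutation of the corresponding base multiset).
#' Panels are rejection-sampled until all species are pairwise distinct;
#' after `max_attempts` failures an error is raised. Output is a pure
#' function of the arguments: the same seed gives a bit-identical panel.
#'
#' @param n_species number of species (>= 2).
#' @param n_sites alignment length (>= 1).
#' @param seed integer seed; required, so panels are reproducible.
#' @param sub_rate per-site substitution probability away from the root
#'   sequence (default 0.1, of the order of congeneric COI divergence).
#' @param site_counts optional named list: position -> length-4 count vector
#'   (A, C, G, T) summing to `n_species`.
#' @param max_attempts rejection-sampling bound (default 1000).
#' @return An [aligned_set()] with species labels "S1".."Sn".
#' @export
random_panel <- function(n_species, n_sites, seed, sub_rate = 0.1,
                         site_counts = NULL, max_attempts = 1000L) {
  n_species <- as.integer(n_species); n_sites <- as.integer(n_sites)
  if (n_species < 2L) stop("n_species must be >= 2")
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (missing(seed)) stop("'seed' is required for reproducible panels")
  if (!is.null(site_counts)) {
    pos <- as.integer(names(site_counts))
    if (anyNA(pos) || any(pos < 1L | pos > n_sites))
      stop("site_counts names must be positions in 1..n_sites")
    ok <- vapply(site_counts, function(ct)
      length(ct) == 4L && all(ct >= 0) && sum(ct) == n_species, logical(1L))
    if (!all(ok))
      stop("each site_counts entry must be 4 non-negative counts summing to n_species")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  for (attempt in seq_len(max_attempts)) {
    root <- sample(DNA_BASES, n_sites, replace = TRUE)
    mat <- matrix(rep(root, each = n_species), nrow = n_species)
    mutate <- matrix(stats::runif(n_species * n_sites) < sub_rate,
                     nrow = n_species)
    if (any(mutate)) {
      idx <- which(mutate)
      mat[idx] <- vapply(mat[idx],
                         function(b) sample(setdiff(DNA_BASES, b), 1L),
                         character(1L))
    }
    if (!is.null(site_counts)) {
      for (p in names(site_counts)) {
        column <- rep(DNA_BASES, times = site_counts[[p]])
        mat[, as.integer(p)] <- sample(column)
      }
    }
    seq_strings <- apply(mat, 1L, paste, collapse = "")
    if (!anyDuplicated(seq_strings))
      return(aligned_set(paste0("S", seq_len(n_species)), mat))
  }
  stop("could not generate ", n_species, " pairwise-distinct species in ",
       max_attempts, " attempts (n_sites = ", n_sites,
       ", sub_rate = ", sub_rate, ")")
}
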