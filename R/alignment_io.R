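#' Aligned species panel
#'
#' An `aligned_set` holds one pre-aligned sequence per species: an N x M
#' character matrix over the symbols `A C G T N -` (IUPAC ambiguity codes are
#' accepted on input and treated like `N` downstream), with unique species
#' labels as row names. It is the common container consumed by the site
#' profiler, the decision-tree builder and the barcode extractor. Positions
#' are 1-based alignment columns; after [trim_common_region()] they index the
#' blunt-ended common region that serves as the coordinate frame for SNP
#' barcodes.
#'
#' @param labels character vector of unique, non-empty species labels.
#' @param matrix character matrix (N rows, M columns) of single upper-case
#'   symbols; or a character vector of N equal-length sequence strings.
#' @param origin_offset number of leading alignment columns removed by
#'   trimming (provenance only; 0 for untrimmed input).
#' @return An object of class `aligned_set` with elements `labels`, `matrix`
#'   and `origin_offset`.
#' @seealso [read_aligned_fasta()], [trim_common_region()]
#' @export
aligned_set <- function(labels, matrix, origin_offset = 0L) {
  if (is.character(matrix) && is.null(dim(matrix))) {
    lens <- nchar(matrix)
    if (length(unique(lens)) != 1L)
      stop("sequences are not aligned: record lengths differ (",
           paste(unique(lens), collapse = ", "), ")")
    matrix <- do.call(rbind, strsplit(matrix, "", fixed = TRUE))
  }
  if (!is.matrix(matrix) || !is.character(matrix))
    stop("'matrix' must be a character matrix or vector of sequence strings")
  if (nrow(matrix) < 2L)
    stop("an aligned set needs at least 2 species")
  if (ncol(matrix) < 1L)
    stop("an aligned set needs at least 1 alignment column")
  labels <- as.character(labels)
  if (length(labels) != nrow(matrix))
    stop("number of labels (", length(labels), ") does not match number of rows (",
         nrow(matrix), ")")
  if (anyDuplicated(labels))
    stop("duplicate species labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (any(!nzchar(labels)))
    stop("species labels must be non-empty")
  bad <- setdiff(unique(as.vector(matrix)), c(DNA_BASES, IUPAC_AMBIG, "N", "-"))
  if (length(bad))
    stop("unrecognized sequence symbols: ", paste(bad, collapse = ", "))
  dimnames(matrix) <- list(labels, NULL)
  structure(list(labels = labels, matrix = matrix,
                 origin_offset = as.integer(origin_offset)),
            class = "aligned_set")
}

DNA_BASES <- c("A", "C", "G", "T")
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' @export
print.aligned_set <- function(x, ...) {
  cat("aligned_set:", nrow(x$matrix), "species x", ncol(x$matrix),
      "alignment columns")
  if (x$origin_offset > 0L)
    cat(" (trimmed; ", x$origin_offset, " leading columns removed)", sep = "")
  cat("\n")
  show <- utils::head(x$labels, 6L)
  for (l in show) {
    s <- paste(x$matrix[l, seq_len(min(60L, ncol(x$matrix)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", l, s, if (ncol(x$matrix) > 60L) "..." else ""))
  }
  if (length(x$labels) > 6L) cat("  ... and", length(x$labels) - 6L, "more\n")
  invisible(x)
}

#' @export
dim.aligned_set <- function(x) dim(x$matrix)

#' Read a species-labelled aligned FASTA file
#'
#' Ingests a pre-aligned multi-FASTA (one record per species; the alignment
#' itself is an external step, e.g. ClustalW/MAFFT/MEGA). Symbols are
#' upper-cased and `U` is mapped to `T`. The species label is the header up
#' to the first whitespace.
#'
#' @param path path to an aligned multi-FASTA file.
#' @return An [aligned_set()].
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  labels <- sub("\\s.*$", "", names(seqs))
  chars <- toupper(as.character(seqs))
  chars <- gsub("U", "T", chars, fixed = TRUE)
  lens <- nchar(chars)
  if (length(unique(lens)) != 1L)
    stop("records are not aligned: lengths ", paste(unique(lens), collapse = ", "),
         " found in ", path)
  aligned_set(labels, unname(chars))
}

#' Write an aligned set as multi-FASTA
#'
#' One record per species, species label as header, 60-column line wrap.
#' Round-trips through [read_aligned_fasta()].
#'
#' @param a an [aligned_set()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_aligned_fasta <- function(a, path) {
  stopifnot(inherits(a, "aligned_set"))
  seqs <- Biostrings::BStringSet(apply(a$matrix, 1L, paste, collapse = ""))
  names(seqs) <- a$labels
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Trim an alignment to its blunt-ended common region
#'
#' Aligned barcode sequences of unequal raw length protrude at the 5' and/or
#' 3' ends; the overhangs are terminal gaps in the shorter records. Trimming
#' removes every leading column up to the last column in which any row still
#' has a terminal 5' gap, and symmetrically at the 3' end, keeping exactly
#' the columns covered by all sequences. The trimmed block is renumbered
#' 1..M' and is the reference frame for all downstream position numbering.
#' Internal gaps are untouched here (such columns are excluded from split
#' candidacy downstream).
#'
#' @param a an [aligned_set()].
#' @return A trimmed [aligned_set()] with `origin_offset` set to the number
#'   of leading columns removed. Idempotent.
#' @export
trim_common_region <- function(a) {
  stopifnot(inherits(a, "aligned_set"))
  is_gap <- a$matrix == "-"
  first_base <- apply(is_gap, 1L, function(g) {
    i <- which(!g)
    if (length(i)) i[1L] else NA_integer_
  })
  last_base <- apply(is_gap, 1L, function(g) {
    i <- which(!g)
    if (length(i)) i[length(i)] else NA_integer_
  })
  if (anyNA(first_base))
    stop("no common region: all-gap row(s): ",
         paste(a$labels[is.na(first_base)], collapse = ", "))
  start <- max(first_base)
  end <- min(last_base)
  if (start > end)
    stop("no common region: no alignment column is covered by all sequences")
  aligned_set(a$labels, a$matrix[, start:end, drop = FALSE],
              origin_offset = a$origin_offset + start - 1L)
}
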