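#' Extract per-species SNP barcodes from a decision tree
#'
#' Each species' barcode is the sequence of decision sites on its
#' root-to-leaf path, recorded with the species' OWN nucleotide at each site
#' (not the pivot); the branch taken is recoverable by comparing to the
#' pivot. Entries are in decision-level order; a position revisited deeper
#' in the path is retained in `entries` and collapsed (it necessarily
#' carries the same nucleotide) in `sorted_entries`, which is position-
#' sorted — the form rendered as the printable species tag.
#'
#' @param tree a `decision_node` from [build_tree()].
#' @param a the [aligned_set()] the tree was built from.
#' @return Named list of `snp_barcode` objects, in the panel's species
#'   order. Each has `species`, `entries` (data.frame level/position/
#'   nucleotide) and `sorted_entries` (data.frame position/nucleotide).
#' @export
extract_barcodes <- function(tree, a) {
  stopifnot(inherits(tree, "decision_node"), inherits(a, "aligned_set"))
  in_tree <- tree_leaves(tree)
  missing <- setdiff(a$labels, in_tree)
  if (length(missing))
    stop("species missing from tree: ", paste(missing, collapse = ", "))
  barcodes <- lapply(a$labels, function(sp) {
    row <- a$matrix[sp, ]
    entries <- data.frame(level = integer(0), position = integer(0),
                          nucleotide = character(0))
    node <- tree
    while (node$kind != "leaf") {
      entries <- rbind(entries,
                       data.frame(level = node$level, position = node$position,
                                  nucleotide = row[node$position]))
      node <- if (row[node$position] == node$pivot) node$left else node$right
    }
    if (node$species != sp)
      stop("tree walk for '", sp, "' reached leaf '", node$species,
           "': tree was not built from this alignment")
    rownames(entries) <- NULL
    sort_and_dedup(structure(list(species = sp, entries = entries,
                                  sorted_entries = NULL),
                             class = "snp_barcode"))
  })
  names(barcodes) <- a$labels
  barcodes
}

#' Sort a barcode by position and collapse duplicates
#'
#' Populates `sorted_entries`: ascending by position, one entry per
#' position. Revisited positions on a root-to-leaf path always carry the
#' same nucleotide for a given species; a conflict means the barcode was
#' corrupted and is an error. `entries` is left untouched. Idempotent.
#'
#' @param b an `snp_barcode`.
#' @return The barcode with `sorted_entries` filled in.
#' @export
sort_and_dedup <- function(b) {
  stopifnot(inherits(b, "snp_barcode"))
  e <- b$entries
  if (nrow(e) == 0L) {
    b$sorted_entries <- data.frame(position = integer(0),
                                   nucleotide = character(0))
    return(b)
  }
  conflict <- vapply(split(e$nucleotide, e$position),
                     function(nt) length(unique(nt)) > 1L, logical(1L))
  if (any(conflict))
    stop("conflicting nucleotides at duplicated position(s) ",
         paste(names(conflict)[conflict], collapse = ", "),
         " in barcode for ", b$species)
  first <- e[!duplicated(e$position), c("position", "nucleotide")]
  first <- first[order(first$position), ]
  rownames(first) <- NULL
  b$sorted_entries <- first
  b
}

#' @export
print.snp_barcode <- function(x, ...) {
  cat("snp_barcode ", x$species, ": ", barcode_string(x), "\n", sep = "")
  invisible(x)
}

barcode_string <- function(b) {
  if (is.null(b$sorted_entries) || nrow(b$sorted_entries) == 0L) return("")
  paste(sprintf("p%d:%s", b$sorted_entries$position,
                b$sorted_entries$nucleotide), collapse = ";")
}

#' Assign a sequence to a species by barcode matching
#'
#' Returns the unique species whose every sorted (position, nucleotide)
#' entry matches the query; `"unknown"` when none matches. Multiple matches
#' are impossible for barcodes extracted from one tree and signal a
#' corrupted barcode set, hence an error.
#'
#' @param barcodes list of `snp_barcode` objects (see [extract_barcodes()]).
#' @param sequence aligned query: character string or symbol vector on the
#'   same coordinate frame as the barcodes.
#' @return A species label, or `"unknown"`.
#' @export
match_barcode <- function(barcodes, sequence) {
  if (is.character(sequence) && length(sequence) == 1L)
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sequence <- toupper(sequence)
  hits <- vapply(barcodes, function(b) {
    se <- b$sorted_entries
    if (any(se$position > length(sequence))) return(FALSE)
    all(sequence[se$position] == se$nucleotide)
  }, logical(1L))
  matched <- vapply(barcodes[hits], function(b) b$species, character(1L))
  if (length(matched) == 0L) return("unknown")
  if (length(matched) > 1L)
    stop("ambiguous barcode set: sequence matches ",
         paste(matched, collapse = ", "))
  unname(matched)
}

#' Write a barcode table as TSV
#'
#' Columns: species, n_positions, positions (comma-joined), nucleotides
#' (concatenated), barcode_string ("p12:A;p87:T;..."). Rows follow the
#' input species order.
#'
#' @param barcodes non-empty list of `snp_barcode` objects.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_barcode_table <- function(barcodes, path) {
  if (length(barcodes) == 0L) stop("empty barcode list")
  tab <- do.call(rbind, lapply(barcodes, function(b) {
    se <- b$sorted_entries
    data.frame(species = b$species,
               n_positions = nrow(se),
               positions = paste(se$position, collapse = ","),
               nucleotides = paste(se$nucleotide, collapse = ""),
               barcode_string = barcode_string(b))
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a barcode table written by [write_barcode_table()]
#'
#' @param path TSV file path.
#' @return Named list of `snp_barcode` objects with `sorted_entries`
#'   reconstructed (`entries` level information is not stored in the table
#'   and comes back empty).
#' @export
read_barcode_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  barcodes <- lapply(seq_len(nrow(tab)), function(i) {
    pos <- as.integer(strsplit(tab$positions[i], ",", fixed = TRUE)[[1L]])
    nts <- strsplit(tab$nucleotides[i], "", fixed = TRUE)[[1L]]
    structure(list(species = tab$species[i],
                   entries = data.frame(level = integer(0),
                                        position = integer(0),
                                        nucleotide = character(0)),
                   sorted_entries = data.frame(position = pos,
                                               nucleotide = nts)),
              class = "snp_barcode")
  })
  names(barcodes) <- tab$species
  barcodes
}
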