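#' Labelled sequence alignments
#'
#' A `labeled_alignment` couples an aligned set of barcode sequences with
#' per-sequence metadata (species, population, locality). It is the universal
#' input of the package: distance, diversity, network and mismatch analyses
#' all consume it. Sequences are stored as an upper-case character matrix
#' (rows = sequences, columns = alignment sites) over the alphabet
#' `A`, `C`, `G`, `T`, `N`, `-`.
#'
#' @param sequences Named character vector of equal-length sequence strings,
#'   or a character matrix with one row per sequence (rownames = ids).
#' @param metadata Data frame with at least columns `id`, `species`,
#'   `population`; a `locality` column and any extra columns are preserved.
#'
#' @return An object of class `labeled_alignment` with elements `seq`
#'   (character matrix) and `meta` (data frame), in matching order.
#' @export
labeled_alignment <- function(sequences, metadata) {
  if (is.matrix(sequences)) {
    seq_mat <- toupper(sequences)
  } else {
    if (is.null(names(sequences))) stop("sequences must be named by id")
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1L) {
      bad <- names(sequences)[lens != stats::median(lens)]
      stop("sequences differ in length; offending ids: ",
           paste(bad, collapse = ", "))
    }
    seq_mat <- do.call(rbind, strsplit(toupper(sequences), ""))
    rownames(seq_mat) <- names(sequences)
  }
  validate_labeled_alignment(new_labeled_alignment(seq_mat, metadata))
}

new_labeled_alignment <- function(seq_mat, meta) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!all(c("id", "species", "population") %in% names(meta))) {
    stop("metadata must contain columns id, species, population")
  }
  if (!"locality" %in% names(meta)) meta$locality <- ""
  idx <- match(rownames(seq_mat), meta$id)
  if (anyNA(idx)) {
    stop("no metadata for sequence id(s): ",
         paste(rownames(seq_mat)[is.na(idx)], collapse = ", "))
  }
  extra <- setdiff(meta$id, rownames(seq_mat))
  if (length(extra)) {
    warning("metadata rows without sequences ignored: ",
            paste(extra, collapse = ", "))
  }
  structure(list(seq = seq_mat, meta = meta[idx, , drop = FALSE]),
            class = "labeled_alignment")
}

validate_labeled_alignment <- function(x) {
  stopifnot(is.matrix(x$seq), nrow(x$seq) >= 1L, ncol(x$seq) >= 1L)
  if (anyDuplicated(rownames(x$seq))) {
    stop("duplicate sequence ids: ",
         paste(unique(rownames(x$seq)[duplicated(rownames(x$seq))]),
               collapse = ", "))
  }
  bad <- !(x$seq %in% c("A", "C", "G", "T", "N", "-"))
  if (any(bad)) {
    ids <- unique(rownames(x$seq)[row(x$seq)[bad]])
    stop("invalid characters (allowed A,C,G,T,N,-) in: ",
         paste(ids, collapse = ", "))
  }
  x
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat(sprintf("<labeled_alignment> %d sequences x %d sites\n",
              nrow(x$seq), ncol(x$seq)))
  sp <- table(x$meta$species)
  cat("  species:",
      paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "), "\n")
  invisible(x)
}

#' Number of sequences / sites in an alignment
#' @param aln A `labeled_alignment`.
#' @return Integer count.
#' @export
n_sequences <- function(aln) nrow(aln$seq)

#' @rdname n_sequences
#' @export
n_sites <- function(aln) ncol(aln$seq)

#' Subset an alignment by sequence id or condition
#'
#' @param aln A `labeled_alignment`.
#' @param ids Character vector of ids, or a logical/integer index over rows.
#' @return A `labeled_alignment` restricted to the selected sequences.
#' @export
subset_alignment <- function(aln, ids) {
  if (is.character(ids)) {
    keep <- match(ids, rownames(aln$seq))
    if (anyNA(keep)) stop("unknown ids: ", paste(ids[is.na(keep)], collapse = ", "))
  } else {
    keep <- ids
  }
  structure(list(seq = aln$seq[keep, , drop = FALSE],
                 meta = aln$meta[keep, , drop = FALSE]),
            class = "labeled_alignment")
}

# Integer-encode an alignment matrix: A,C,G,T -> 1..4, N and gaps -> NA.
encode_alignment <- function(seq_mat) {
  code <- matrix(match(seq_mat, c("A", "C", "G", "T")),
                 nrow = nrow(seq_mat), dimnames = dimnames(seq_mat))
  code
}

decode_states <- function(int_mat) {
  out <- matrix(c("A", "C", "G", "T")[int_mat], nrow = nrow(int_mat),
                dimnames = dimnames(int_mat))
  out[is.na(out)] <- "N"
  out
}
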