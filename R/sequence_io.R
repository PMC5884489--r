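#' Read an aligned FASTA plus a sample-metadata table
#'
#' Reads a pre-aligned FASTA file together with a tab-separated metadata table
#' (required columns `id`, `species`, `population`; `locality` and extra
#' columns are kept verbatim) and returns a validated [labeled_alignment].
#' Every FASTA id must have a metadata row; metadata rows without a sequence
#' are reported as a warning. Sequences of unequal length are a hard error
#' naming the offending ids.
#'
#' @param fasta_path Path to an aligned FASTA file.
#' @param metadata_path Path to a TSV with header.
#' @return A [labeled_alignment].
#' @export
read_alignment <- function(fasta_path, metadata_path) {
  dna <- ape::read.FASTA(fasta_path)
  if (length(dna) == 0L) stop("empty FASTA: ", fasta_path)
  seqs <- vapply(as.character(dna), function(x) paste(toupper(x), collapse = ""),
                 character(1))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    common <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    stop("aligned sequences must share one length; offending ids: ",
         paste(names(seqs)[lens != common], collapse = ", "))
  }
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  labeled_alignment(seqs, meta)
}

#' Write an alignment back to FASTA (+ optional metadata TSV)
#'
#' @param aln A [labeled_alignment].
#' @param fasta_path Output FASTA path.
#' @param metadata_path Optional output TSV path.
#' @return `aln`, invisibly.
#' @export
write_alignment <- function(aln, fasta_path, metadata_path = NULL) {
  con <- file(fasta_path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln$seq))) {
    writeLines(c(paste0(">", rownames(aln$seq)[i]),
                 paste(aln$seq[i, ], collapse = "")), con)
  }
  if (!is.null(metadata_path)) {
    utils::write.table(aln$meta, metadata_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(aln)
}

#' Trim an alignment to the common overlapping window
#'
#' Records whose informative length (number of A/C/G/T sites) falls below
#' `min_keep` are dropped with a message; the remaining sequences are
#' truncated to the window shared by all of them, i.e. columns from the
#' latest first informative site to the earliest last informative site.
#' This mirrors the usual curation step of cutting heterogeneous-length
#' GenBank records down to their minimal common length. The operation is
#' idempotent. Column positions are reported 1-based.
#'
#' @param aln A [labeled_alignment].
#' @param min_keep Minimum informative length a record must have to be kept.
#'   Default 1 keeps everything with at least one called base.
#' @return A trimmed [labeled_alignment].
#' @export
trim_to_common_length <- function(aln, min_keep = 1L) {
  if (min_keep > n_sites(aln)) stop("min_keep exceeds alignment length")
  informative <- aln$seq %in% c("A", "C", "G", "T")
  dim(informative) <- dim(aln$seq)
  n_inf <- rowSums(informative)
  drop <- n_inf < min_keep
  if (all(drop)) stop("no sequence reaches min_keep = ", min_keep)
  if (any(drop)) {
    message(sum(drop), " shorter sequence(s) removed: ",
            paste(rownames(aln$seq)[drop], collapse = ", "))
  }
  keep_mat <- informative[!drop, , drop = FALSE]
  firsts <- apply(keep_mat, 1, function(r) which(r)[1])
  lasts  <- apply(keep_mat, 1, function(r) max(which(r)))
  lo <- max(firsts); hi <- min(lasts)
  if (lo > hi) stop("retained sequences share no overlapping window")
  structure(list(seq = aln$seq[!drop, lo:hi, drop = FALSE],
                 meta = aln$meta[!drop, , drop = FALSE]),
            class = "labeled_alignment")
}

#' Collapse identical sequences into haplotypes
#'
#' Merges identical aligned sequences into unique haplotypes, preserving the
#' membership map back to the input records. By default collapsing uses exact
#' string identity, so sequences that differ only at `N` positions stay
#' separate; `merge_ambiguous = TRUE` additionally merges a sequence into a
#' haplotype it matches at every mutually called site (ambiguous sites are
#' resolved from the partner). Haplotype ids `H001, H002, ...` are assigned
#' by the sorted first member id, so output is deterministic.
#'
#' @param aln A [labeled_alignment].
#' @param merge_ambiguous Merge sequences compatible up to N/gap sites.
#' @return An object of class `haplotype_set`: list with `seq` (matrix of
#'   unique haplotype sequences), `count`, `members` (list of member id
#'   vectors), `meta` (the input metadata) and `length`.
#' @export
collapse_haplotypes <- function(aln, merge_ambiguous = FALSE) {
  keys <- apply(aln$seq, 1, paste, collapse = "")
  groups <- split(rownames(aln$seq), keys)
  reps <- vapply(groups, function(ids) sort(ids)[1], character(1))
  if (merge_ambiguous) {
    groups <- merge_ambiguous_groups(aln, groups, reps)
    reps <- vapply(groups, function(ids) sort(ids)[1], character(1))
  }
  ord <- order(reps)
  groups <- groups[ord]; reps <- reps[ord]
  hap_id <- sprintf("H%03d", seq_along(groups))
  seq_mat <- aln$seq[reps, , drop = FALSE]
  rownames(seq_mat) <- hap_id
  members <- lapply(groups, function(ids) sort(ids))
  names(members) <- hap_id
  structure(list(seq = seq_mat,
                 count = vapply(members, length, integer(1)),
                 members = members,
                 meta = aln$meta,
                 length = ncol(aln$seq)),
            class = "haplotype_set")
}

# Greedy N-tolerant merging: fold a group into the first earlier group whose
# representative matches at all mutually called sites.
merge_ambiguous_groups <- function(aln, groups, reps) {
  ord <- order(-vapply(groups, length, integer(1)), reps)
  groups <- groups[ord]; reps <- reps[ord]
  enc <- encode_alignment(aln$seq)
  out <- list(); out_rep <- character(0)
  for (g in seq_along(groups)) {
    x <- enc[reps[g], ]
    hit <- 0L
    for (h in seq_along(out)) {
      y <- enc[out_rep[h], ]
      ok <- is.na(x) | is.na(y) | x == y
      if (all(ok)) { hit <- h; break }
    }
    if (hit > 0L) {
      out[[hit]] <- c(out[[hit]], groups[[g]])
    } else {
      out <- c(out, groups[g])
      out_rep <- c(out_rep, reps[g])
    }
  }
  out
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes from %d sequences, %d sites\n",
              length(x$count), sum(x$count), x$length))
  invisible(x)
}

#' Number of haplotypes
#' @param hs A `haplotype_set`.
#' @return Integer.
#' @export
n_haplotypes <- function(hs) length(hs$count)

#' Expand a haplotype set back to its member sequences
#'
#' Inverse of [collapse_haplotypes()]: reconstructs the per-record sequence
#' matrix from the membership map (useful for round-trip checks).
#'
#' @param hs A `haplotype_set`.
#' @return Character matrix with one row per original record.
#' @export
expand_haplotypes <- function(hs) {
  ids <- unlist(hs$members, use.names = FALSE)
  hap_of <- rep(names(hs$members), lengths(hs$members))
  out <- hs$seq[hap_of, , drop = FALSE]
  rownames(out) <- ids
  out[order(ids), , drop = FALSE]
}

#' Write the haplotype membership table
#'
#' TSV with columns `hap_id`, `count`, `member_ids` (semicolon-joined).
#'
#' @param hs A `haplotype_set`.
#' @param path Output path.
#' @return `hs`, invisibly.
#' @export
write_haplotype_table <- function(hs, path) {
  df <- data.frame(hap_id = names(hs$members),
                   count = unname(hs$count),
                   member_ids = vapply(hs$members, paste, character(1),
                                       collapse = ";"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(hs)
}

# Species/population composition of each haplotype (for network annotation).
haplotype_groups <- function(hs, column = "population") {
  lapply(hs$members, function(ids) {
    table(hs$meta[[column]][match(ids, hs$meta$id)])
  })
}
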