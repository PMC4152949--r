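#' Construct a labeled DNA sequence dataset
#'
#' A `dhs_dataset` holds parallel vectors of sequence identifiers, residue
#' strings over the alphabet A/C/G/T, and binary class labels
#' (`"positive"` = DHS, `"negative"` = non-DHS, or `NA` when unlabeled).
#'
#' @param seqs character vector of residue strings (case-insensitive).
#' @param ids character vector of identifiers, same length as `seqs`.
#' @param labels `"positive"`, `"negative"` or `NA`, recycled if length 1.
#' @param name free-text dataset name.
#' @param drop_ambiguous if `TRUE`, sequences containing `N` are removed
#'   (with a message giving the count) instead of raising an error.
#' @return an object of class `dhs_dataset`.
#' @export
dhs_dataset <- function(seqs, ids = NULL, labels = NA_character_,
                        name = "", drop_ambiguous = FALSE) {
  seqs <- as.character(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  ids <- as.character(ids)
  if (length(ids) != length(seqs))
    stop("`ids` and `seqs` must have equal length")
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  labels <- rep_len(as.character(labels), length(seqs))
  bad_lab <- !is.na(labels) & !labels %in% c("positive", "negative")
  if (any(bad_lab))
    stop("labels must be 'positive', 'negative' or NA; got: ",
         paste(unique(labels[bad_lab]), collapse = ", "))

  seqs <- toupper(gsub("[ \t\r]", "", seqs))
  has_n <- grepl("N", seqs, fixed = TRUE)
  if (drop_ambiguous && any(has_n)) {
    message(sum(has_n), " sequence(s) containing N dropped")
    seqs <- seqs[!has_n]; ids <- ids[!has_n]; labels <- labels[!has_n]
    has_n <- logical(length(seqs))
  }
  bad <- regexpr("[^ACGT]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("invalid residue '", substr(seqs[i], bad[i], bad[i]),
         "' in record '", ids[i], "' at position ", bad[i],
         if (has_n[i]) " (ambiguous base; see drop_ambiguous)" else "")
  }
  if (any(nchar(seqs) < 2)) {
    i <- which(nchar(seqs) < 2)[1]
    stop("sequence '", ids[i], "' has length ", nchar(seqs[i]),
         "; at least one dinucleotide (length >= 2) is required")
  }
  structure(list(id = ids, seq = seqs,
                 label = factor(labels, levels = c("positive", "negative")),
                 name = name),
            class = "dhs_dataset")
}

#' @export
length.dhs_dataset <- function(x) length(x$seq)

#' @export
`[.dhs_dataset` <- function(x, i) {
  structure(list(id = x$id[i], seq = x$seq[i], label = x$label[i],
                 name = x$name),
            class = "dhs_dataset")
}

#' @export
print.dhs_dataset <- function(x, ...) {
  tab <- table(x$label, useNA = "ifany")
  cat("<dhs_dataset", if (nzchar(x$name)) paste0(" '", x$name, "'"), "> ",
      length(x), " sequence(s): ",
      paste(names(tab), tab, sep = "=", collapse = ", "),
      "; lengths ", if (length(x)) paste(range(nchar(x$seq)), collapse = "-")
      else "-", "\n", sep = "")
  invisible(x)
}

#' Read a FASTA file into a labeled dataset
#'
#' FASTA structure (headers, line wrapping) is parsed by
#' [Biostrings::readBStringSet()]; residues are then upper-cased,
#' whitespace-stripped and validated against the A/C/G/T alphabet. The
#' record identifier is the first whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file.
#' @param label class label applied to every record (`"positive"`,
#'   `"negative"`), or `NULL` for unlabeled sequences.
#' @param drop_ambiguous drop records containing `N` instead of erroring.
#' @return a [dhs_dataset()].
#' @export
read_fasta_dataset <- function(path, label = NULL, drop_ambiguous = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                   error = function(e)
                     stop("malformed FASTA in '", path, "': ",
                          conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(recs))
  dhs_dataset(as.character(recs), ids = ids,
              labels = if (is.null(label)) NA_character_ else label,
              name = basename(path), drop_ambiguous = drop_ambiguous)
}

#' Write a dataset to FASTA
#'
#' @param data a [dhs_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_dataset <- function(data, path) {
  x <- Biostrings::DNAStringSet(data$seq)
  names(x) <- data$id
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Merge a positive and a negative dataset
#'
#' Concatenates the two class subsets into one benchmark set, positives
#' first, preserving within-class order. Identifiers must not collide.
#'
#' @param pos all-positive [dhs_dataset()].
#' @param neg all-negative [dhs_dataset()].
#' @param name name for the merged dataset.
#' @return a [dhs_dataset()] of `length(pos) + length(neg)` sequences.
#' @export
merge_datasets <- function(pos, neg, name = "benchmark") {
  stopifnot(inherits(pos, "dhs_dataset"), inherits(neg, "dhs_dataset"))
  if (length(pos) && !isTRUE(all(pos$label == "positive")))
    stop("`pos` must contain only positive-labeled sequences")
  if (length(neg) && !isTRUE(all(neg$label == "negative")))
    stop("`neg` must contain only negative-labeled sequences")
  clash <- intersect(pos$id, neg$id)
  if (length(clash))
    stop("identifier collision between datasets: ",
         paste(clash, collapse = ", "))
  structure(list(id = c(pos$id, neg$id), seq = c(pos$seq, neg$seq),
                 label = factor(c(as.character(pos$label),
                                  as.character(neg$label)),
                                levels = c("positive", "negative")),
                 name = name),
            class = "dhs_dataset")
}
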