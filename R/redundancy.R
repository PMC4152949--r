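#' Pairwise sequence identity
#'
#' Identity is defined as the number of matched bases in the
#' maximal-match global alignment (match = 1, mismatch = 0, gaps free)
#' divided by the length of the shorter sequence — the convention of
#' greedy identity-threshold clustering tools. With free gaps and zero
#' mismatch cost the alignment score equals the length of the longest
#' common subsequence, computed here through
#' [Biostrings::pairwiseAlignment()].
#'
#' @param a,b residue strings or single-sequence [dhs_dataset()] objects.
#' @return identity fraction in `[0, 1]`; symmetric, and 1 for `a == a`.
#' @export
pairwise_identity <- function(a, b) {
  a <- as_residues(a); b <- as_residues(b)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = TRUE)
  score <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 0,
    type = "global", scoreOnly = TRUE)
  score / min(nchar(a), nchar(b))
}

as_residues <- function(x) {
  if (inherits(x, "dhs_dataset")) {
    if (length(x) != 1L) stop("expected a single sequence")
    x <- x$seq
  }
  x <- toupper(as.character(x))
  if (grepl("[^ACGT]", x)) stop("sequence contains non-ACGT residues")
  x
}

#' Greedy identity-threshold redundancy filtering
#'
#' Removes sequences so that no two retained representatives share
#' pairwise identity at or above `threshold`. Sequences are visited in
#' order of decreasing length (ties: input order); each joins the first
#' existing representative (in creation order) with identity >=
#' `threshold`, otherwise it founds a new cluster. By default the
#' positive and negative classes are clustered separately, so a positive
#' sequence is never discarded for resembling a negative one; set
#' `cross_class = TRUE` for joint clustering.
#'
#' @param data a [dhs_dataset()].
#' @param threshold identity fraction in `(0, 1]` (e.g. 0.6).
#' @param cross_class cluster all sequences jointly regardless of label.
#' @return an object of class `dhs_clusters` with elements
#'   `representatives` (a [dhs_dataset()] of retained sequences, in input
#'   order), `cluster_map` (data.frame `member_id`, `representative_id`
#'   covering every input id; representatives map to themselves) and
#'   `threshold`.
#' @export
filter_redundant <- function(data, threshold, cross_class = FALSE) {
  stopifnot(inherits(data, "dhs_dataset"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("`threshold` must be a single number in (0, 1]")
  n <- length(data)
  if (n == 0L)
    return(structure(list(representatives = data,
                          cluster_map = data.frame(member_id = character(),
                                                   representative_id = character()),
                          threshold = threshold),
                     class = "dhs_clusters"))

  groups <- if (cross_class) list(seq_len(n))
            else split(seq_len(n), data$label, drop = TRUE)
  rep_of <- character(n)
  keep <- logical(n)
  for (idx in groups) {
    ord <- idx[order(-nchar(data$seq[idx]), seq_along(idx))]
    reps <- integer(0)
    for (i in ord) {
      hit <- 0L
      for (r in reps) {
        if (pairwise_identity(data$seq[i], data$seq[r]) >= threshold) {
          hit <- r; break
        }
      }
      if (hit == 0L) {
        reps <- c(reps, i)
        keep[i] <- TRUE
        rep_of[i] <- data$id[i]
      } else rep_of[i] <- data$id[hit]
    }
  }
  structure(list(representatives = data[which(keep)],
                 cluster_map = data.frame(member_id = data$id,
                                          representative_id = rep_of,
                                          stringsAsFactors = FALSE),
                 threshold = threshold),
            class = "dhs_clusters")
}

#' @export
print.dhs_clusters <- function(x, ...) {
  cat("<dhs_clusters> ", nrow(x$cluster_map), " sequence(s) -> ",
      length(x$representatives), " representative(s) at identity < ",
      x$threshold, "\n", sep = "")
  invisible(x)
}

#' Write a cluster map as a two-column TSV
#'
#' @param clusters a `dhs_clusters` object from [filter_redundant()].
#' @param path output path; columns `member_id`, `representative_id`.
#' @return `path`, invisibly.
#' @export
write_cluster_map <- function(clusters, path) {
  write.table(clusters$cluster_map, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
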