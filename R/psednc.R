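#' Overlapping dinucleotide frequencies
#'
#' Counts the `L - 1` overlapping dinucleotides of a sequence and
#' normalizes by `L - 1`, giving the 16-component dinucleotide
#' composition in fixed lexicographic order.
#'
#' @param seq a residue string or single-sequence [dhs_dataset()].
#' @return named numeric vector of length 16 summing to 1.
#' @export
dinucleotide_frequencies <- function(seq) {
  idx <- dinuc_indices(seq)
  stats::setNames(tabulate(idx, nbins = 16L) / length(idx), DINUCLEOTIDES)
}

# Map a sequence to the integer codes (1..16) of its L-1 overlapping
# dinucleotides, in order along the sequence.
dinuc_indices <- function(seq) {
  s <- as_residues(seq)
  L <- nchar(s)
  if (L < 2L) stop("sequence length ", L, " < 2: no dinucleotides")
  b <- match(strsplit(s, "", fixed = TRUE)[[1]], BASES) - 1L
  4L * b[-L] + b[-1L] + 1L
}

#' Tier correlation factors along a sequence
#'
#' The j-th tier correlation factor is the average structural distance
#' [theta_pair()] between dinucleotides `j` positions apart:
#' `theta_j = mean_i Theta(R_i R_{i+1}, R_{i+j} R_{i+j+1})`,
#' `i = 1 ... L - 1 - j`. Tiers capture sequence-order information that
#' plain composition discards.
#'
#' @param seq residue string or single-sequence [dhs_dataset()].
#' @param lambda number of tiers; requires `L >= lambda + 2`.
#' @param table a [property_table()] (standardized if not already).
#' @return numeric vector `theta` of length `lambda`, all `>= 0`.
#' @export
tier_correlations <- function(seq, lambda, table = default_property_table()) {
  lambda <- check_lambda(lambda)
  table <- ensure_standardized(table)
  idx <- dinuc_indices(seq)
  n <- length(idx)  # = L - 1
  if (n < lambda + 1L)
    stop("sequence too short: L = ", n + 1L, " but lambda = ", lambda,
         " requires L >= lambda + 2")
  th <- theta_matrix(table)
  vapply(seq_len(lambda), function(j) {
    mean(th[cbind(idx[1:(n - j)], idx[(1 + j):n])])
  }, numeric(1))
}

#' Pseudo dinucleotide composition of a sequence
#'
#' Encodes a sequence as the `16 + lambda` dimensional PseDNC vector
#' `d`: the first 16 components are the dinucleotide frequencies damped
#' by the correlation mass, `d_u = f_u / (1 + w * sum(theta))`, and the
#' last `lambda` components are the weighted tier correlation factors,
#' `d_{16+j} = w * theta_j / (1 + w * sum(theta))`. The vector is
#' non-negative and sums to 1; at `w = 0` it reduces exactly to the
#' plain dinucleotide composition padded with zeros.
#'
#' @param seq residue string or single-sequence [dhs_dataset()].
#' @param w weight factor in `[0, 1]` balancing composition against
#'   sequence-order correlation.
#' @param lambda number of correlation tiers (sequence must satisfy
#'   `L >= lambda + 2`).
#' @param table a [property_table()].
#' @return named numeric vector of length `16 + lambda` with attributes
#'   `f` (raw frequencies), `theta`, `w` and `lambda`.
#' @export
psednc <- function(seq, w = 0.2, lambda = 6, table = default_property_table()) {
  if (!is.numeric(w) || length(w) != 1L || w < 0 || w > 1)
    stop("`w` must be a single number in [0, 1]")
  lambda <- check_lambda(lambda)
  f <- dinucleotide_frequencies(seq)
  theta <- tier_correlations(seq, lambda, table)
  denom <- 1 + w * sum(theta)
  d <- c(f, w * theta) / denom
  names(d) <- c(DINUCLEOTIDES, paste0("theta", seq_len(lambda)))
  structure(d, f = f, theta = theta, w = w, lambda = lambda)
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 1 ||
      lambda != round(lambda))
    stop("`lambda` must be a positive integer")
  as.integer(lambda)
}

#' Encode a whole dataset as a PseDNC feature matrix
#'
#' @param data a [dhs_dataset()].
#' @param w,lambda,table as in [psednc()].
#' @return list with `features` (matrix, one row per sequence, `16 +
#'   lambda` columns, row names = ids), `labels` (`+1` positive, `-1`
#'   negative, `NA` unlabeled), `ids`, `w`, `lambda`.
#' @export
encode_dataset <- function(data, w = 0.2, lambda = 6,
                           table = default_property_table()) {
  stopifnot(inherits(data, "dhs_dataset"))
  lambda <- check_lambda(lambda)
  table <- ensure_standardized(table)
  too_short <- nchar(data$seq) < lambda + 2L
  if (any(too_short))
    stop("sequences too short for lambda = ", lambda, ": ",
         paste(data$id[too_short], collapse = ", "))
  feats <- matrix(0, nrow = length(data), ncol = 16L + lambda,
                  dimnames = list(data$id,
                                  c(DINUCLEOTIDES,
                                    paste0("theta", seq_len(lambda)))))
  for (i in seq_len(length(data)))
    feats[i, ] <- psednc(data$seq[i], w, lambda, table)
  labels <- ifelse(data$label == "positive", 1, -1)
  list(features = feats, labels = as.numeric(labels), ids = data$id,
       w = w, lambda = lambda)
}

#' Write an encoded dataset as TSV or sparse libsvm text
#'
#' `write_feature_tsv()` writes `id`, `label` and the `16 + lambda`
#' components with their names. `write_feature_libsvm()` writes the
#' sparse `label index:value ...` format used by libsvm tools.
#'
#' @param encoded result of [encode_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(encoded, path) {
  df <- data.frame(id = encoded$ids, label = encoded$labels,
                   encoded$features, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
write_feature_libsvm <- function(encoded, path) {
  x <- encoded$features
  lines <- vapply(seq_len(nrow(x)), function(i) {
    nz <- which(x[i, ] != 0)
    paste(c(format(encoded$labels[i]),
            paste0(nz, ":", format(x[i, nz], digits = 12, trim = TRUE))),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
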