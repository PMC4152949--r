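#' First-order Markov DNA sequence sampler
#'
#' Draws one sequence: the first base uniform over A/C/G/T, each
#' subsequent base from the transition-matrix row of the previous base.
#' First-order chains make the dinucleotide frequencies — the
#' discriminative signal of the DHS classifier — directly controllable.
#'
#' @param length number of bases, `>= 2`.
#' @param transition 4x4 row-stochastic matrix over A, C, G, T (rows =
#'   current base, columns = next base).
#' @param seed integer seed for this sequence's private random stream.
#' @return a residue string.
#' @export
generate_sequence <- function(length, transition = uniform_transition(),
                              seed = 0) {
  if (length < 2) stop("`length` must be >= 2")
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(4L, 4L)) || any(transition < 0) ||
      any(abs(rowSums(transition) - 1) > 1e-9))
    stop("`transition` must be a 4x4 row-stochastic matrix")
  with_local_seed(seed, {
    b <- integer(length)
    b[1] <- sample.int(4L, 1L)
    for (i in 2:length)
      b[i] <- sample.int(4L, 1L, prob = transition[b[i - 1], ])
    paste(BASES[b], collapse = "")
  })
}

#' Baseline and GC-boosted transition matrices
#'
#' `uniform_transition()` is the neutral background (all entries 1/4).
#' `gc_boosted_transition(delta)` adds `delta` to the log-odds of every
#' transition into C and into G and renormalizes each row, producing the
#' CC/CG/GC/GG dinucleotide enrichment that distinguishes DHS-like from
#' background sequences. `delta = 0` recovers the baseline exactly.
#'
#' @param delta log-odds boost, `>= 0`.
#' @return a 4x4 row-stochastic matrix with A, C, G, T dimnames.
#' @export
uniform_transition <- function() {
  matrix(0.25, 4, 4, dimnames = list(BASES, BASES))
}

#' @rdname uniform_transition
#' @export
gc_boosted_transition <- function(delta) {
  if (delta < 0) stop("`delta` must be >= 0")
  logits <- log(uniform_transition())
  logits[, c("C", "G")] <- logits[, c("C", "G")] + delta
  p <- exp(logits)
  p / rowSums(p)
}

#' Simulate a labeled two-class DHS-like dataset
#'
#' Positives are drawn from the `delta`-boosted chain (enriched in the
#' CC, CG, GC, GG dinucleotides), negatives from the uniform baseline;
#' at `delta = 0` the two classes are identically distributed. Lengths
#' are uniform in `[length_min, length_max]`. One master seed expands
#' deterministically into an independent stream per sequence, so that
#' changing the count of one class does not perturb the other class's
#' sequences.
#'
#' @param n_pos,n_neg class sizes.
#' @param delta log-odds GC-transition boost for the positive class,
#'   `>= 0`.
#' @param length_min,length_max sequence length bounds, `2 <= min <=
#'   max`.
#' @param seed master integer seed.
#' @return a labeled [dhs_dataset()] (positives first).
#' @export
simulate_dhs_dataset <- function(n_pos = 200, n_neg = 200, delta = 1.0,
                                 length_min = 200, length_max = 400,
                                 seed = 0) {
  if (length_min < 2 || length_min > length_max)
    stop("need 2 <= length_min <= length_max")
  sim_class <- function(n, transition, offset, label) {
    if (n == 0)
      return(dhs_dataset(character(), character(), name = ""))
    seqs <- character(n)
    for (i in seq_len(n)) {
      si <- stream_seed(seed, offset + i)
      len <- with_local_seed(si,
               sample.int(length_max - length_min + 1L, 1L) +
                 length_min - 1L)
      seqs[i] <- generate_sequence(len, transition, seed = si + 1L)
    }
    dhs_dataset(seqs, ids = paste0(substr(label, 1, 3), seq_len(n)),
                labels = label)
  }
  pos <- sim_class(n_pos, gc_boosted_transition(delta), 0L, "positive")
  neg <- sim_class(n_neg, uniform_transition(), 500000L, "negative")
  merge_datasets(pos, neg,
                 name = sprintf("simulated (delta = %g, seed = %d)",
                                delta, seed))
}

# Deterministic per-sequence seed below 2^31, well-spread in the
# low-order bits so neighbouring indices get unrelated streams.
stream_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 16807 +
                12345) %% 2147483629)
}
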