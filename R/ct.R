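# Fixed residue order of the binary profile rows.
PROFILE_RESIDUE_ORDER <- c("A","R","N","D","C","E","Q","G","H","I",
                           "L","K","M","F","P","S","T","W","Y","V")

#' Binary occupancy profile of a sequence
#'
#' A 20 x n 0/1 matrix: row i, column j is 1 iff the residue at position j is
#' the i-th residue of the fixed order A,R,N,D,C,E,Q,G,H,I,L,K,M,F,P,S,T,W,Y,V.
#' Every column sums to 1.
#'
#' @param seq Cleaned residue string.
#' @return Integer matrix (20 rows, named), n columns.
#' @export
binary_profile <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 1L) stop("empty sequence")
  if (!all(chars %in% PROFILE_RESIDUE_ORDER)) {
    stop("sequence contains non-standard residues; clean_sequence() it first")
  }
  m <- matrix(0L, nrow = 20L, ncol = n,
              dimnames = list(PROFILE_RESIDUE_ORDER, NULL))
  m[cbind(match(chars, PROFILE_RESIDUE_ORDER), seq_len(n))] <- 1L
  m
}

#' Composition and transition statistics of one bit segment
#'
#' Five statistics, in percent: frequency of 0s and of 1s (denominator m),
#' frequency of overlapping "11" pairs and of overlapping "111" triples
#' (denominators m-1 and m-2), and the transition frequency of adjacent
#' unequal bits (denominator m-1). A statistic whose denominator is not
#' positive is defined as 0.
#'
#' @param bits 0/1 integer vector or a character string of 0s and 1s.
#' @return Named numeric vector `(freq0, freq1, freq11, freq111, trans)`,
#'   percent units.
#' @export
#' @examples
#' segment_stats("11000011101010011010")
segment_stats <- function(bits) {
  if (is.character(bits)) {
    bits <- as.integer(strsplit(bits, "")[[1]])
  }
  m <- length(bits)
  if (m < 1L) stop("empty segment")
  if (!all(bits %in% c(0L, 1L))) stop("segment must be binary")
  ones <- sum(bits)
  freq0 <- 100 * (m - ones) / m
  freq1 <- 100 * ones / m
  freq11 <- if (m >= 2L) 100 * sum(bits[-m] & bits[-1L]) / (m - 1L) else 0
  freq111 <- if (m >= 3L) {
    100 * sum(bits[seq_len(m - 2L)] & bits[seq_len(m - 2L) + 1L] &
                bits[seq_len(m - 2L) + 2L]) / (m - 2L)
  } else 0
  trans <- if (m >= 2L) 100 * sum(bits[-m] != bits[-1L]) / (m - 1L) else 0
  c(freq0 = freq0, freq1 = freq1, freq11 = freq11,
    freq111 = freq111, trans = trans)
}

#' Split a bit vector into L near-equal contiguous segments
#'
#' Segment i covers positions `(floor((i-1)*n/L) + 1) .. floor(i*n/L)`;
#' segment lengths differ by at most one and concatenate back to the input.
#'
#' @param bits 0/1 integer vector or 0/1 character string.
#' @param L Number of segments.
#' @return List of L integer vectors.
#' @export
split_segments <- function(bits, L) {
  if (is.character(bits)) bits <- as.integer(strsplit(bits, "")[[1]])
  n <- length(bits)
  if (n < L) stop(sprintf("sequence too short: length %d < %d segments", n, L))
  bounds <- floor(seq_len(L) * n / L)
  starts <- c(0L, bounds[-L]) + 1L
  lapply(seq_len(L), function(i) bits[starts[i]:bounds[i]])
}

#' 400-dimensional composition/transition descriptor
#'
#' Each of the 20 binary-profile rows is split into `L` segments and each
#' segment summarised by [segment_stats()]. Output is residue-major: for each
#' residue (profile row order), for each segment 1..L, the five statistics.
#'
#' @param seq Protein sequence; cleaned with [clean_sequence()] first.
#' @param L Number of segments per row (default 4, giving 4 x 20 x 5 = 400
#'   features).
#' @return Numeric vector of length `20 * L * 5`, percent units.
#' @export
ct_vector <- function(seq, L = 4L) {
  seq <- clean_sequence(seq)
  prof <- binary_profile(seq)
  if (ncol(prof) < L) {
    stop(sprintf("sequence too short: length %d < %d segments", ncol(prof), L))
  }
  out <- numeric(0)
  nm <- character(0)
  for (res in rownames(prof)) {
    segs <- split_segments(prof[res, ], L)
    for (s in seq_len(L)) {
      st <- segment_stats(segs[[s]])
      out <- c(out, st)
      nm <- c(nm, paste(res, s, names(st), sep = "."))
    }
  }
  names(out) <- nm
  out
}
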