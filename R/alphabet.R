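#' @keywords internal
"_PACKAGE"

# The 20 standard residues, alphabetical one-letter order used for cleaning.
STANDARD_RESIDUES <- c("A","C","D","E","F","G","H","I","K","L",
                       "M","N","P","Q","R","S","T","V","W","Y")

#' Six-class reduced amino acid alphabet
#'
#' Physicochemical partition of the 20 standard residues into six classes:
#' aliphatic (AVLIMC), aromatic (FWYH), polar (STNQ), positively charged (KR),
#' negatively charged (DE), and special conformation (GP).
#'
#' @return Named character vector mapping each residue letter to a class
#'   label `"A1"`..`"A6"`.
#' @export
#' @examples
#' reduced_alphabet()[["W"]]  # "A2"
reduced_alphabet <- function() {
  classes <- list(
    A1 = c("A","V","L","I","M","C"),
    A2 = c("F","W","Y","H"),
    A3 = c("S","T","N","Q"),
    A4 = c("K","R"),
    A5 = c("D","E"),
    A6 = c("G","P")
  )
  map <- character(0)
  for (cl in names(classes)) {
    map[classes[[cl]]] <- cl
  }
  map[STANDARD_RESIDUES]
}

#' Four-group combination patterns over the six residue classes
#'
#' The six classes are regrouped into four super-groups labelled B, J, O and U,
#' one per quadrant of the unit circle. B always merges three classes
#' (always including the aliphatic class A1); J, O and U each keep a single
#' class. Ten fixed patterns are used.
#'
#' @return A list of 10 patterns; each has `id`, `b_classes` (3 class labels),
#'   and `j_class`, `o_class`, `u_class` (single labels).
#' @export
combination_patterns <- function() {
  rows <- list(
    list(b = c("A1","A2","A3"), j = "A4", o = "A5", u = "A6"),
    list(b = c("A1","A2","A4"), j = "A3", o = "A5", u = "A6"),
    list(b = c("A1","A2","A5"), j = "A3", o = "A4", u = "A6"),
    list(b = c("A1","A2","A6"), j = "A3", o = "A4", u = "A5"),
    list(b = c("A1","A3","A4"), j = "A2", o = "A5", u = "A6"),
    list(b = c("A1","A3","A5"), j = "A2", o = "A4", u = "A6"),
    list(b = c("A1","A3","A6"), j = "A2", o = "A4", u = "A5"),
    list(b = c("A1","A4","A5"), j = "A2", o = "A3", u = "A6"),
    list(b = c("A1","A4","A6"), j = "A2", o = "A3", u = "A5"),
    list(b = c("A1","A5","A6"), j = "A2", o = "A3", u = "A4")
  )
  lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    list(id = i, b_classes = r$b,
         j_class = r$j, o_class = r$o, u_class = r$u)
  })
}

# residue -> {B,J,O,U} lookup for one pattern
pattern_letter_map <- function(pattern) {
  alpha <- reduced_alphabet()
  cls <- alpha  # residue -> class
  out <- character(length(cls))
  names(out) <- names(cls)
  out[cls %in% pattern$b_classes] <- "B"
  out[cls == pattern$j_class] <- "J"
  out[cls == pattern$o_class] <- "O"
  out[cls == pattern$u_class] <- "U"
  out
}

#' Clean a raw residue string
#'
#' Uppercases the input and removes every character that is not one of the 20
#' standard one-letter residue codes (ambiguity codes such as X, B, Z, as well
#' as gaps and stops are dropped with a warning).
#'
#' @param raw Character scalar, a protein sequence.
#' @return Cleaned uppercase residue string.
#' @export
#' @examples
#' clean_sequence("metkdgirwa")
clean_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- gsub("[[:space:]]", "", toupper(raw))
  if (nchar(s) == 0L) stop("unencodable sequence: empty input")
  chars <- strsplit(s, "")[[1]]
  keep <- chars %in% STANDARD_RESIDUES
  if (!all(keep)) {
    bad <- unique(chars[!keep])
    warning(sprintf("removed non-standard characters: %s",
                    paste(bad, collapse = ", ")))
  }
  out <- paste(chars[keep], collapse = "")
  if (nchar(out) == 0L) {
    stop("unencodable sequence: no standard residues remain after cleaning")
  }
  out
}

#' Reduce a sequence to the four-letter B/J/O/U alphabet
#'
#' @param seq Cleaned residue string (see [clean_sequence()]).
#' @param pattern One element of [combination_patterns()], or a pattern index
#'   1..10.
#' @return Character scalar over `{B, J, O, U}` of the same length as `seq`.
#' @export
#' @examples
#' reduce_sequence("METKDGIRWA", 1)  # "BOBJOUBJBB"
reduce_sequence <- function(seq, pattern) {
  if (is.numeric(pattern)) pattern <- combination_patterns()[[pattern]]
  map <- pattern_letter_map(pattern)
  chars <- strsplit(seq, "")[[1]]
  if (!all(chars %in% names(map))) {
    stop("sequence contains non-standard residues; clean_sequence() it first")
  }
  paste(map[chars], collapse = "")
}
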