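#' Map a reduced sequence onto the unit circle
#'
#' Each quadrant of the unit circle hosts one of the four letters (B: first,
#' J: second, O: third, U: fourth). The q-th occurrence of letter X (out of
#' X_n occurrences in total) is placed at angle
#' `base(X) + (pi/2) * q / (X_n + 1)`, so the occurrences of a letter are
#' spread over the open interior of its quadrant in order of appearance.
#'
#' @param rs Reduced sequence over `{B, J, O, U}` (see [reduce_sequence()]).
#' @return Numeric matrix with `n` rows and columns `x`, `y`; every row lies
#'   on the unit circle.
#' @export
circle_map <- function(rs) {
  chars <- strsplit(rs, "")[[1]]
  n <- length(chars)
  if (n < 1L) stop("empty reduced sequence")
  if (!all(chars %in% c("B","J","O","U"))) {
    stop("reduced sequence must be over {B, J, O, U}")
  }
  base <- c(B = 0, J = pi/2, O = pi, U = 3*pi/2)
  fac <- factor(chars, levels = c("B","J","O","U"))
  totals <- tabulate(fac, nbins = 4L)
  names(totals) <- c("B","J","O","U")
  # cumulative occurrence index of each letter at each position
  occ <- stats::ave(rep(1, n), fac, FUN = cumsum)
  angle <- unname(base[chars]) + (pi/2) * occ / unname(totals[chars] + 1)
  cbind(x = cos(angle), y = sin(angle))
}

#' First and second moments of circle points
#'
#' Means and sample variances (denominator `n - 1`) of the x and y
#' coordinates. For a single point the variances are defined as 0.
#'
#' @param cp Matrix of points from [circle_map()].
#' @return Named numeric vector `(mx, my, vx, vy)`.
#' @export
pattern_moments <- function(cp) {
  if (is.null(dim(cp)) || nrow(cp) < 1L) stop("empty point set")
  n <- nrow(cp)
  mx <- mean(cp[, 1]); my <- mean(cp[, 2])
  if (n == 1L) {
    vx <- 0; vy <- 0
  } else {
    vx <- sum((cp[, 1] - mx)^2) / (n - 1)
    vy <- sum((cp[, 2] - my)^2) / (n - 1)
  }
  c(mx = mx, my = my, vx = vx, vy = vy)
}

#' 40-dimensional F-vector of a protein sequence
#'
#' For each of the ten combination patterns the sequence is reduced to the
#' B/J/O/U alphabet, mapped onto the unit circle, and summarised by the four
#' moments `(Mx, My, Vx, Vy)`. The result concatenates the moment blocks in
#' pattern order (pattern-major).
#'
#' @param seq Protein sequence; cleaned with [clean_sequence()] first.
#' @return Numeric vector of length 40, names `v<i>.<moment>`.
#' @export
#' @examples
#' length(f_vector("METKDGIRWA"))  # 40
f_vector <- function(seq) {
  seq <- clean_sequence(seq)
  pats <- combination_patterns()
  out <- lapply(pats, function(p) {
    pattern_moments(circle_map(reduce_sequence(seq, p)))
  })
  v <- unlist(out, use.names = FALSE)
  names(v) <- as.vector(t(outer(paste0("v", 1:10),
                                c("mx","my","vx","vy"), paste, sep = ".")))
  v
}
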