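#' Perceptually weighted RGB color distance
#'
#' Distance between two RGB colors using channel weights chosen to
#' approximate human color perception:
#' \deqn{D = \sqrt{2(R_1-R_2)^2 + 4(G_1-G_2)^2 + 3(B_1-B_2)^2}}
#' The maximum over 8-bit channels is \eqn{\sqrt{9\cdot 255^2} = 765}
#' (black vs. white).
#'
#' @param a,b numeric length-3 vectors (r, g, b), each channel in 0--255.
#' @return Non-negative scalar distance; 0 iff `a == b`.
#' @examples
#' color_distance(c(0, 0, 0), c(255, 255, 255)) # 765
#' @export
color_distance <- function(a, b) {
  a <- validate_rgb(a)
  b <- validate_rgb(b)
  d <- a - b
  sqrt(2 * d[1]^2 + 4 * d[2]^2 + 3 * d[3]^2)
}

validate_rgb <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L || anyNA(x) || any(x < 0) || any(x > 255)) {
    stop("RGB color must be 3 channel values within [0, 255]", call. = FALSE)
  }
  x
}

# Similarity-class distance ranges; half-open except the closed top class.
# "high" similarity = small distance.
.color_ranges <- list(
  high   = c(0, 200),
  medium = c(200, 475),
  low    = c(475, 765)
)

#' Color-similarity class of a distance value
#'
#' @param d distance as returned by [color_distance()].
#' @return `"high"`, `"medium"` or `"low"` similarity. Boundaries are
#'   half-open: `[0,200)` high, `[200,475)` medium, `[475,765]` low.
#' @export
color_similarity_class <- function(d) {
  stopifnot(d >= 0, d <= 765)
  if (d < 200) "high" else if (d < 475) "medium" else "low"
}

#' Sample a color pair within a similarity class
#'
#' Draws two RGB colors by rejection sampling until their
#' [color_distance()] falls inside the class range: `[0,200)` for high
#' similarity, `[200,475)` for medium, `[475,765]` for low.
#'
#' @param level one of `"high"`, `"medium"`, `"low"`.
#' @param max_attempts rejection-sampling cap before erroring.
#' @return list with `a`, `b` (RGB vectors) and `distance`.
#' @export
sample_color_pair <- function(level = c("high", "medium", "low"),
                              max_attempts = 10000L) {
  level <- match.arg(level)
  rng <- .color_ranges[[level]]
  closed_top <- identical(level, "low")
  for (i in seq_len(max_attempts)) {
    a <- sample(0:255, 3, replace = TRUE)
    b <- sample_color_near(a, rng)
    d <- color_distance(a, b)
    if (d >= rng[1] && (d < rng[2] || (closed_top && d <= rng[2]))) {
      return(list(a = a, b = b, distance = d))
    }
  }
  stop("sample_color_pair: rejection sampling exhausted after ",
       max_attempts, " attempts", call. = FALSE)
}

# Propose b given a; for wide target distances a uniform proposal rarely
# lands in-class, so bias proposals toward the required radius.
sample_color_near <- function(a, rng) {
  target <- stats::runif(1, rng[1], rng[2])
  # random direction in weighted color space, step of length ~ target
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  w <- sqrt(c(2, 4, 3))
  step <- target * dir / w
  b <- round(a + step)
  pmin(pmax(b, 0), 255)
}
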