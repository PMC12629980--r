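# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the package's own computation paths.

# Random positive ring series at Tucson storage precision.
random_series <- function(n, last_year = 1600L, seed = NULL,
                          unit = "0.01 mm", id = "RND") {
  if (!is.null(seed)) set.seed(seed)
  div <- if (unit == "0.01 mm") 100 else 1000
  raw <- pmax(1L, round(exp(rnorm(n, log(120), 0.35))))
  ring_series(raw / div, last_year = last_year, series_id = id,
              units_raw = unit)
}

# Pearson correlation from the raw sum formula (no cor()).
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

oracle_tbp <- function(x, y) {
  r <- oracle_pearson(x, y)
  list(r = r, t = r * sqrt(length(x) - 2) / sqrt(1 - r^2))
}

# Sign-agreement score by explicit case analysis, with normal-approximation p.
oracle_glk <- function(sa, sb) {
  stopifnot(length(sa) == length(sb))
  score <- numeric(length(sa))
  for (i in seq_along(sa)) {
    if (sa[i] != 0 && sa[i] == sb[i]) score[i] <- 1
    else if (sa[i] == 0 && sb[i] == 0) score[i] <- 0
    else if (sa[i] == 0 || sb[i] == 0) score[i] <- 0.5
    else score[i] <- 0
  }
  n <- length(score)
  glk <- 100 * mean(score)
  p <- 1 - pnorm((mean(score) - 0.5) * 2 * sqrt(n))
  list(glk = glk, p = p)
}

# Baillie-Pilcher index by direct 5-term window evaluation.
oracle_bp <- function(w) {
  n <- length(w)
  vapply(3:(n - 2), function(i) log(w[i] / mean(w[(i - 2):(i + 2)])),
         numeric(1))
}

# Two same-tree boards (length 210, ending 1606) for error-localization
# tests; measurement noise as per scenario defaults.
same_tree_pair <- function(seed) {
  sc <- synthetic_scenario(
    seed = seed,
    boards = data.frame(tree = c(1L, 1L), length = 210L, end_year = 1606L,
                        n_sapwood = 0L))
  gb <- generate_boards(sc)
  list(reference = gb$boards[[1L]], clean = gb$boards[[2L]])
}
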