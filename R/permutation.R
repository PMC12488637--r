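#' Spearman correlation with a permutation p-value
#'
#' Spearman's rho is the Pearson correlation of the average-ranked vectors
#' (ties get average ranks). Significance comes from a seeded permutation
#' test that shuffles `y`: with the add-one correction,
#' `p = (1 + #permutations with a statistic at least as extreme) /
#' (n_permutations + 1)`, so p is bounded below by `1/(n_permutations + 1)`
#' and never zero. Two-sided (on `|rho|`) and both one-sided p-values are
#' returned; the caller picks the one matching its hypothesis.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param n_permutations number of random permutations (default 999).
#' @param seed integer seed for the permutation stream; the global RNG state
#'   is left untouched. NULL uses (and advances) the current RNG.
#' @param exact enumerate all `factorial(n)` permutations instead of
#'   sampling (requires `n <= 8`); p-values then use plain proportions over
#'   the full permutation distribution, which contains the identity.
#' @return a list with `rho`, `p_two_sided`, `p_greater`, `p_less`, `n`,
#'   `n_permutations`, `degenerate`. A constant `x` or `y` gives `rho = 0`,
#'   all p-values 1 and `degenerate = TRUE`.
#' @export
spearman_permutation <- function(x, y, n_permutations = 999, seed = NULL,
                                 exact = FALSE) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3) abort("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")

  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = 0, p_two_sided = 1, p_greater = 1, p_less = 1,
                n = n, n_permutations = 0L, degenerate = TRUE))
  }

  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  rho_obs <- sum(rxc * ryc) / denom

  stat <- function(perm) sum(rxc * ryc[perm]) / denom
  eps <- 1e-12                                  # guard FP noise in |rho| comparisons

  if (exact) {
    if (n > 8) abort("exact enumeration supported only for n <= 8")
    perms <- all_permutations(n)
    rho_b <- vapply(perms, stat, numeric(1))
    p_two <- mean(abs(rho_b) >= abs(rho_obs) - eps)
    p_gt <- mean(rho_b >= rho_obs - eps)
    p_lt <- mean(rho_b <= rho_obs + eps)
    n_perm <- length(perms)
  } else {
    rho_b <- with_seed_if(seed, vapply(seq_len(n_permutations),
                                       function(i) stat(sample.int(n)), numeric(1)))
    p_two <- (1 + sum(abs(rho_b) >= abs(rho_obs) - eps)) / (n_permutations + 1)
    p_gt <- (1 + sum(rho_b >= rho_obs - eps)) / (n_permutations + 1)
    p_lt <- (1 + sum(rho_b <= rho_obs + eps)) / (n_permutations + 1)
    n_perm <- as.integer(n_permutations)
  }

  list(rho = rho_obs, p_two_sided = p_two, p_greater = p_gt, p_less = p_lt,
       n = n, n_permutations = n_perm, degenerate = FALSE)
}

# list of all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  shorter <- all_permutations(n - 1L)
  out <- vector("list", n * length(shorter))
  k <- 0L
  for (p in shorter) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# evaluate expr under a temporary seed without touching the global RNG state
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
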