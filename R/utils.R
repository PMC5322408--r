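#' @importFrom rlang abort warn %||%
#' @importFrom stats dnorm pnorm qnorm rnorm runif rgamma optim uniroot
#'   shapiro.test wilcox.test t.test lm anova p.adjust median sd var quantile
#'   density approx setNames complete.cases prcomp predict cor rbinom rmultinom
#' @importFrom utils combn head
NULL

# Deterministic sub-seed for a named random sub-stream. All simulation and
# permutation code draws its seed through here so one user-facing integer
# seed governs every stage without coupling their RNG streams.
split_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

# Run `expr` under a locally-set seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Off-diagonal lower-triangle vector of a square symmetric matrix.
lower_vec <- function(m) m[lower.tri(m)]

check_square_symmetric <- function(m, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(paste0(name, " must be a square matrix"))
  }
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8) {
    abort(paste0(name, " must be symmetric"))
  }
  invisible(m)
}

# Truncated-at-zero normal draw via inverse CDF (vectorised).
rtruncnorm0 <- function(n, mean, sd) {
  lo <- pnorm(0, mean, sd)
  qnorm(lo + runif(n) * (1 - lo), mean, sd)
}
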