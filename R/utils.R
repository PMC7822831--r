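# Internal helpers shared across stages.

#' Derive a reproducible child seed from a master seed and a stream name
#'
#' All randomness in the package flows from one user-supplied master seed.
#' Each randomized stage draws from its own named stream so that re-running a
#' single stage (or reordering stages) does not perturb the others.
#'
#' @param seed Master seed (single integer).
#' @param name Character stream name, e.g. `"simulate/participant3/run2"`.
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
seed_stream <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name),
            length(name) == 1L)
  # FNV-1a-style over the name bytes, folded with the master seed; kept < 2^31
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(name)) {
    h <- bitwXor(as.integer(h), b)
    h <- (as.numeric(h) * 16777619) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483646)
}

#' Evaluate an expression under a local RNG state
#'
#' Seeds the generator, evaluates `expr`, and restores the caller's RNG
#' state, so seeded computations do not perturb surrounding randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Remove the per-sample channel mean (average reference) from a
# channels x samples matrix or a single map vector.
avg_ref <- function(x) {
  if (is.matrix(x)) sweep(x, 2L, colMeans(x)) else x - mean(x)
}

# Unit Euclidean norm (columns of a matrix, or a vector).
unit_norm <- function(x) {
  if (is.matrix(x)) {
    n <- sqrt(colSums(x^2))
    n[n == 0] <- 1
    sweep(x, 2L, n, "/")
  } else {
    n <- sqrt(sum(x^2))
    if (n == 0) x else x / n
  }
}

# Pearson spatial correlation between average-referenced maps; columns of B
# against the vector or matched columns of A.
spatial_cor <- function(a, b) stats::cor(a, b)

# Stable, dependency-free content hash (FNV-1a over a serialized text form),
# used to stamp pipeline outputs with their configuration.
content_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 15, vec.len = 1e6,
                                              list.len = 1e6)), collapse = "\n")
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), b)
    h <- (as.numeric(h) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

condition_levels <- function() c("rest", "generation", "evolution", "evaluation")
task_conditions <- function() c("generation", "evolution", "evaluation")
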