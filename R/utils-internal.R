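# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic per-component seeds derived from one master seed.
## Keeps every derived seed strictly below .Machine$integer.max.
substreamSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

## Evaluate `expr` under a temporary RNG state so callers' streams are
## untouched (all stochastic entry points take an explicit seed).
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## largest-remainder allocation of n items to fractions (deterministic)
largestRemainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

clampProb <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

## mean binary cross-entropy over all entries of a binary target matrix
meanBCE <- function(target, prob, eps = 1e-12) {
  p <- clampProb(prob, eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}
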