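# Internal numerics and seeding helpers.

#' Evaluate an expression under a fixed RNG state
#'
#' Seeds the global RNG, runs `expr`, and restores the previous RNG state so
#' library code never clobbers the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed for a named random stream. Keeps results in
# [1, 2^31 - 2] so they remain valid 32-bit seeds.
derive_seed <- function(seed, ...) {
  parts <- c(as.character(seed), vapply(list(...), as.character, character(1)))
  key <- paste(parts, collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

# Numerically stable log(sum(exp(x))).
log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

l2_normalize_rows <- function(x, eps = 1e-8) {
  nrm <- sqrt(rowSums(x^2))
  x / pmax(nrm, eps)
}

# Adam optimizer step on a flat numeric vector. State carries first/second
# moments and the step counter.
adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, delta = lr * mhat / (sqrt(vhat) + eps))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
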