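## Small internal numerical helpers shared across the package.

sigmoid <- function(x) 1 / (1 + exp(-x))

## log(sum(exp(x))) along rows of a matrix, guarded against -Inf rows
logsumexp_rows <- function(x) {
  m <- apply(x, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(x - m)))
}

## Glorot-uniform initialisation for a fan_in x fan_out weight matrix
glorot <- function(fan_in, fan_out) {
  r <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out)
}

## Adam optimiser state for a list of parameter matrices. The state (and the
## parameter list handed to adam_step) must be private to the training loop:
## updates happen in place through compiled code.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

## One in-place Adam update; params and state$m/state$v are mutated.
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  adam_update_inplace(params, grads, state$m, state$v,
                      lr, beta1, beta2, eps, state$t)
  list(params = params, state = state)
}

## force an unshared copy of a parameter list before in-place training
copy_params <- function(params) lapply(params, function(p) p + 0)

## Derive a child seed from a base seed and a stage label; kept < 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
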