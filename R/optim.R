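#' @title Adam optimizer over nested parameter lists
#' @name optim
#' @keywords internal
NULL

zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  if (is.numeric(p)) return(p * 0)
  NULL
}

adam_init <- function(params) {
  num <- params[vapply(params, function(x) is.numeric(x) || is.list(x), TRUE)]
  num$schema_id <- NULL
  list(m = zero_like(num), v = zero_like(num), t = 0L)
}

adam_walk <- function(param, grad, m, v, lr_t, beta1, beta2, eps, wd) {
  if (is.list(grad)) {
    idx <- if (is.null(names(grad))) seq_along(grad) else names(grad)
    for (k in idx) {
      res <- adam_walk(param[[k]], grad[[k]], m[[k]], v[[k]],
                       lr_t, beta1, beta2, eps, wd)
      param[[k]] <- res$param
      m[[k]] <- res$m
      v[[k]] <- res$v
    }
    return(list(param = param, m = m, v = v))
  }
  g <- grad + wd * param
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  param <- param - lr_t * m / (sqrt(v) + eps)
  list(param = param, m = m, v = v)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  grads$datom <- NULL
  res <- adam_walk(params[names(grads)], grads, state$m[names(grads)],
                   state$v[names(grads)], lr_t, beta1, beta2, eps, weight_decay)
  params[names(grads)] <- res$param
  state$m[names(grads)] <- res$m
  state$v[names(grads)] <- res$v
  list(params = params, state = state)
}
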