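#' @keywords internal
#' @useDynLib plugingan, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# ---- seeded RNG helpers -----------------------------------------------------

#' Evaluate an expression under a local, restorable RNG state
#'
#' Sets the Mersenne-Twister seed for the duration of `expr` and restores the
#' caller's RNG state afterwards, so library code never perturbs user-level
#' random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Deterministically derive a sub-seed from (seed, k). Lehmer-style mix kept
# below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, k) {
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  k <- as.double(k) %% m
  as.integer(((s * 48271) %% m + k * 69621) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(structure(class = c("plugingan_input_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_config <- function(...) {
  stop(structure(class = c("plugingan_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_format <- function(...) {
  stop(structure(class = c("plugingan_format_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

is_power_of_two <- function(x) {
  x <- as.double(x)
  length(x) == 1L && is.finite(x) && x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
}

# ---- parameter collections --------------------------------------------------

# Parameters are flat named lists of numeric arrays. Gradients mirror names.

param_count <- function(params) sum(vapply(params, length, 0L))

# MD5 content hash of a parameter list at full binary precision (used for
# freeze assertions and checkpoint integrity).
param_hash <- function(params) {
  stopifnot(is.list(params))
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  ord <- order(names(params))
  for (i in ord) {
    writeChar(names(params)[i], con, eos = "\n")
    writeBin(as.double(params[[i]]), con)
  }
  close(con)
  unname(tools::md5sum(tmp))
}

# ---- Adam optimiser ---------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

# One Adam update. `grads` may omit parameters (treated as zero gradient).
adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# elementwise sum of two (possibly partial) gradient lists
grad_add <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

grad_scale <- function(g, s) lapply(g, function(x) x * s)
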