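# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stream seed from a master seed and a label
#'
#' Stable string hashing of `(seed, label)` keeps independent random streams
#' per cell or per train: adding a new cell to a batch never perturbs the
#' draws of the others. The result is a positive integer below 2^31.
#'
#' @param seed master integer seed.
#' @param label character stream label (e.g. a cell id).
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(paste0(label, ":", format(seed, scientific = FALSE)))
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483629
  as.integer(h + 1)
}
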