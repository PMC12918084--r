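# internal helpers: classed errors and seed scoping

hl_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hlmrp_error")))
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so generators are pure functions of their arguments.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# paste a cell assignment into a single lookup key
cell_paste_key <- function(df) {
  do.call(paste, c(as.list(df), sep = "\r"))
}
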