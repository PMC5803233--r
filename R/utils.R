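# internal helpers

# evaluate expr under a temporary RNG seed, restoring global RNG state
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
  set.seed(seed)
  expr
}

# derived seed streams so phantom / noise / init / shuffle draws are
# independent for one master seed; kept below 2^31
seed_for <- function(master, stream) {
  as.integer((as.numeric(master) %% 65536 * 7919 + stream * 104729) %%
               .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(name, " must be a numeric matrix", call. = FALSE)
  }
}
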