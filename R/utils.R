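# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Classed error so callers can drop a line / frame and log the reason.
gcxi_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "gcxi_error"), call = call))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x > 0 && x == as.integer(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
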