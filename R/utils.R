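# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  force(code)
}

logistic <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Condition-class aware stop so the CLI can map failures to exit codes.
stop_mdassoc <- function(msg, class = "mdassoc_error", call. = FALSE) {
  stop(structure(
    class = c(class, "mdassoc_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

msg_info <- function(..., verbose = getOption("mdassoc.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)
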