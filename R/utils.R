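#' @keywords internal
"_PACKAGE"

# Classed conditions so callers/tests can distinguish failure modes:
#   sidmap_format_error     - unreadable/ill-shaped input file
#   sidmap_validation_error - readable input violating an invariant
#   sidmap_usage_error      - bad arguments / infeasible request
stop_sidmap <- function(msg, class) {
  stop(structure(
    class = c(class, "sidmap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_format     <- function(msg) stop_sidmap(msg, "sidmap_format_error")
stop_validation <- function(msg) stop_sidmap(msg, "sidmap_validation_error")
stop_usage      <- function(msg) stop_sidmap(msg, "sidmap_usage_error")

# Round halves away from zero (2/3 -> 67%, 0.5 -> 1), unlike base round()'s
# round-half-even. Percentages in screen reports use this rule.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x == as.integer(x)
}
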