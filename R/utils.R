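# internal helpers: classed conditions and seeded RNG scoping

qsar_stop <- function(msg, class, ..., call = sys.call(-1)) {
  stop(errorCondition(msg, ..., class = c(class, "qsar_error"), call = call))
}

qsar_warn <- function(msg, class = "qsar_warning") {
  warning(warningCondition(msg, class = class))
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All package randomness goes through this so
# results are a pure function of the named seeds.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    qsar_stop("seed must be a single finite number", "qsar_config_error")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# population (1/n) standard deviation, used for standardized coefficients
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
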