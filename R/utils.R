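#' @keywords internal
"_PACKAGE"

# shared argument checks -------------------------------------------------

stop_fd <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "fdgradient_error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_fd("'%s' must be a single finite number", name, class = "invalid_config")
  if (x < lower || x > upper)
    stop_fd("'%s' must be in [%s, %s], got %s", name, lower, upper, x,
            class = "invalid_config")
  x
}

check_count <- function(x, name, lower = 1L) {
  x <- check_number(x, name, lower = lower)
  if (x != round(x))
    stop_fd("'%s' must be an integer, got %s", name, x, class = "invalid_config")
  as.integer(x)
}

as_numeric_matrix <- function(x, name = deparse(substitute(x))) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  if (anyNA(x))
    stop_fd("'%s' contains missing values", name, class = "missing_values")
  x
}

# Deterministic per-stage child seeds: a counter scheme so that adding a
# stage never shifts the random stream of another stage.  Kept below 2^31.
child_seed <- function(seed, stage) {
  seed <- as.double(seed)
  idx <- as.double(stage)
  ((seed %% 2147483647) * 48271 + idx * 16807) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
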