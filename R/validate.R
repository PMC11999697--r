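# Internal validation helpers. All user-facing validation errors carry the
# class "smfret_validation_error" so callers (and the CLI wrapper) can map
# them onto exit codes; data-insufficiency errors carry "smfret_data_error".

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("smfret_validation_error", "error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("smfret_data_error", "error")))
}

stop_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("smfret_parse_error",
                                "smfret_validation_error", "error")))
}

check_simplex <- function(p, what, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop_invalid("%s must be non-negative and finite", what)
  }
  if (abs(sum(p) - 1) > tol) {
    stop_invalid("%s must sum to 1 (got %.12g)", what, sum(p))
  }
  invisible(p)
}

check_stochastic_matrix <- function(A, what, tol = 1e-9) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop_invalid("%s must be a square matrix", what)
  }
  for (i in seq_len(nrow(A))) {
    check_simplex(A[i, ], sprintf("%s row %d", what, i), tol)
  }
  invisible(A)
}

check_scalar <- function(x, what, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (closed_lower) x >= lower else x > lower) &&
    (if (closed_upper) x <= upper else x < upper)
  if (!ok) stop_invalid("%s must be a finite scalar in the stated range", what)
  invisible(x)
}

check_count <- function(x, what, lower = 0L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && x >= lower
  if (!ok) stop_invalid("%s must be an integer >= %d", what, lower)
  invisible(as.integer(x))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's generator
# state afterwards so package functions never disturb the global stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-trace seed derivation: a Lehmer-style integer hash of
# (master seed, index), exact in double arithmetic and < 2^31 on every
# platform.
derive_seed <- function(master_seed, index) {
  m <- 2147483629
  h <- (abs(as.numeric(master_seed)) %% m) * 48271 %% m
  h <- (h + (as.numeric(index) %% m) * 16807) %% m
  as.integer(h %% 2147483562 + 1)
}
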