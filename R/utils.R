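# internal helpers shared across modules

.assert_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("'%s' must be numeric and non-missing", name), call. = FALSE)
  }
  ok <- if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) {
    stop(sprintf("'%s' must lie in %s", name, if (open) "(0, 1)" else "[0, 1]"),
         call. = FALSE)
  }
  invisible(x)
}

.assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || anyNA(x) || any(x < min) || any(x != floor(x))) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Simpson composite weights for n equally spaced nodes (n odd) with spacing h.
.simpson_weights <- function(n, h) {
  stopifnot(n >= 3, n %% 2 == 1)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w * h / 3
}
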