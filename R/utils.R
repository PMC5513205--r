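# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}

# One Dirichlet draw via normalised gamma variates. alpha entries that are
# exactly zero stay structurally zero.
rdirichlet1 <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  g <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  # guard against all-zero gamma draws at tiny shapes
  if (sum(g) <= 0) g[] <- alpha[pos]
  x[pos] <- g / sum(g)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mgmp <- function(..., class) {
  stop(structure(
    class = c(class, "mgmp_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
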