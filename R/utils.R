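#' @keywords internal
"_PACKAGE"

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so generators are pure functions of (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_navcog <- function(..., class = "navcog_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_navcog(sprintf("`%s` must be a single number in [%s, %s]",
                        name, format(lower), format(upper)),
                class = "navcog_validation_error")
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x != as.integer(x) || x < lower) {
    stop_navcog(sprintf("`%s` must be an integer >= %d", name, lower),
                class = "navcog_validation_error")
  }
  invisible(as.integer(x))
}

vnorm <- function(v) sqrt(sum(v^2))

# round() in R rounds half to even; tables in validation reports use the
# conventional round-half-up at 2 decimals (0.005 -> 0.01).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}
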