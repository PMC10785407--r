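# internal helpers shared across modules

GENOTYPE_LEVELS <- c("AA", "AB", "BB")

GENETIC_MODELS <- c("recessive", "dominant", "super_dominant",
                    "homozygote", "additive", "allele")

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the global random number generator seeded at `seed`,
#' then restores the previous RNG state so callers do not perturb user
#' code.  Used internally so that every stochastic stage is reproducible
#' from a single integer.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# derive a bounded sub-seed from a master seed and a stream label,
# keeping the result inside the 32-bit integer range
subSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647) + 1L
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  invisible(x)
}

matchModel <- function(model) {
  match.arg(model, GENETIC_MODELS)
}
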