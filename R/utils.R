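#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state so library functions do not perturb user-level
#' reproducibility. A `NULL` seed evaluates `code` untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a root seed
#'
#' Deterministic LCG-style split so every sub-generator draws from its own
#' stream; results stay inside the 32-bit integer range.
#'
#' @param seed root integer seed.
#' @param k stream index (>= 1).
#' @return an integer seed.
#' @keywords internal
child_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer((s * 48271 + 7919 * as.double(k)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce any matrix-like input to a general numeric CSC sparse matrix
#' @keywords internal
as_csparse <- function(m) {
  if (!methods::is(m, "Matrix")) m <- Matrix::Matrix(as.matrix(m), sparse = TRUE)
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

#' @keywords internal
assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
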