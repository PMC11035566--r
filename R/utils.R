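#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
# seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds: keep everything inside 32-bit signed range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + k * 2654435761) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_anf <- function(msg, class) {
  stop(structure(
    class = c(class, "anfiber_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

anf_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[anfiber] ", ...)
  invisible(NULL)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
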