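#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards so that library calls never
#' perturb a user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Hashes the master seed together with arbitrary labels (strings or
#' integers) into a deterministic 31-bit seed, so that independent random
#' streams (per tree, per model variant, per replicate) can be derived from
#' one user-supplied seed without collisions in practice.
#'
#' @param seed Master integer seed.
#' @param ... Further labels distinguishing the stream.
#' @return An integer in `[1, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(1, "forest", "EHC-ERF")
derive_seed <- function(seed, ...) {
  tokens <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                  collapse = "/")
  codes <- utf8ToInt(tokens)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483563
  as.integer(h + 1L)
}

# round-half-up, used for the train fraction (round() in R rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ehc <- function(fmt, ..., class = "ehcforest_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
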