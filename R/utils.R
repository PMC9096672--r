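# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Deterministic rounding used wherever score points are rounded to integers.
#' `round()` in R rounds half to even, which makes point values depend on
#' floating-point parity; half-away-from-zero is stable across platforms and
#' is the convention used throughout score derivation here.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -0.5))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. Used by every operation that takes a `seed` argument.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

stop_if_not <- function(cond, ..., class = "proscore_error") {
  if (!isTRUE(cond)) {
    stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
  }
  invisible(TRUE)
}

# Outcome vectors arrive either as "yes"/"no" character, factor, logical or
# 0/1 numeric; normalise to 0/1 integer.
as_binary_outcome <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    stop_if_not(all(x %in% c("yes", "no"), na.rm = TRUE),
                "outcome values must be 'yes'/'no'")
    return(ifelse(is.na(x), NA_integer_, as.integer(x == "yes")))
  }
  if (is.logical(x)) return(as.integer(x))
  stop_if_not(all(x %in% c(0, 1), na.rm = TRUE), "outcome must be binary 0/1")
  as.integer(x)
}
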