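# Shared internal helpers: classed error conditions, seed hygiene, rounding.

#' Signal a classed kelpcoast error
#'
#' All user-facing failures carry a subclass (e.g. `kelp_alignment_error`)
#' so callers and tests can condition on the failure mode rather than on
#' message text.
#'
#' @param class character subclass of the condition.
#' @param msg message, passed through [sprintf()] when `...` is non-empty.
#' @param ... sprintf arguments.
#' @noRd
kelp_stop <- function(class, msg, ...) {
  if (length(list(...)) > 0) msg <- sprintf(msg, ...)
  stop(errorCondition(msg, class = c(class, "kelp_error")))
}

kelp_warn <- function(msg, ...) {
  if (length(list(...)) > 0) msg <- sprintf(msg, ...)
  warning(warningCondition(msg, class = c("kelp_warning")))
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded operations do not perturb the session stream.
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
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Round half away from zero
#'
#' Percentages are reported rounded half-up (1.35 -> 1.4 at one decimal),
#' matching the conventional presentation of sequence divergences, rather
#' than R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(1.35, 1)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# read a TSV with required columns, with a classed error naming the file
read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    kelp_stop("kelp_format_error", "%s table not found: %s", what, path)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    kelp_stop("kelp_format_error", "%s table %s lacks column(s): %s",
              what, path, paste(missing, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
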