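# small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a global seed
#'
#' One global seed determines every stage's seed deterministically, so that
#' re-running a single stage with the derived seed reproduces it bit-identically.
#' The result always fits in a 32-bit integer.
#'
#' @param seed global integer seed.
#' @param stage character stage name.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) %% 65521 * 7919 + h * 104729 + 17) %% 2147483629 + 1)
}

# consistent input-error signalling (no call noise for users)
stop_input <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

# named-list -> data.frame of (set, element) pairs; used by several writers
sets_to_table <- function(sets, names = c("set", "element")) {
  df <- data.frame(
    set = rep(names(sets), lengths(sets)),
    element = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  names(df) <- names
  df
}
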