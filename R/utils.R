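#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#'
#' All user-facing validation failures in the package raise classed errors so
#' callers (and the CLI) can react to the failure kind, not the message text.
#' @noRd
hrt_stop <- function(class, ...) {
  stop(structure(
    class = c(class, "hrtcst_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

hrt_warn <- function(...) warning(paste0(...), call. = FALSE)

#' Derive a per-call integer seed from a base seed and a stream label
#'
#' Keeps independent stages of a pipeline reproducible from one user seed
#' without re-using the same stream. Result is always < 2^31.
#' @noRd
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
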