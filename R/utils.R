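# internal helpers shared across modules

GAS_CONSTANT_KCAL <- 1.987e-3  # kcal/(mol K)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("sh2spec_invalid", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_invalid(msg)
  invisible(TRUE)
}

# robust noise scale: 1.4826 * MAD
robust_sigma <- function(x) stats::mad(x, constant = 1.4826)

# noise scale of a (possibly trending) series from first differences
diff_sigma <- function(x) robust_sigma(diff(x)) / sqrt(2)

#' Derive a child seed from a parent seed
#'
#' Deterministic splitting rule used by all generators so that one
#' user-facing seed drives many independent pseudorandom streams while
#' staying below 2^31.
#'
#' @param seed parent integer seed
#' @param k stream index (>= 0)
#' @return an integer seed
#' @export
split_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 9973 * (k + 1)) %% 2147483647)
}
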