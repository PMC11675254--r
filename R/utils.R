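#' @importFrom rlang abort warn .data %||%
#' @importFrom stats median pchisq phyper p.adjust qchisq rbinom runif setNames
#' @importFrom utils head
NULL

# internal: stop with a classed condition so callers can test on class
ptr_abort <- function(msg, class) {
  abort(msg, class = c(class, "pathtrio_error"))
}

ptr_assert <- function(ok, msg, class = "pathtrio_invalid") {
  if (!isTRUE(ok)) ptr_abort(msg, class)
  invisible(TRUE)
}

# key uniquely identifying an individual across families
ind_key <- function(family_id, individual_id) paste(family_id, individual_id, sep = ":")
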