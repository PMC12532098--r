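# Structured error conditions used across the package.
#
# - "rsmoco_config_error": a user-supplied configuration is invalid.
# - "rsmoco_contract_error": a function was called outside its contract
#   (shape mismatch, index out of range, ...).
# - "rsmoco_io_error": a file could not be read or written.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("rsmoco_config_error", "rsmoco_error")))
}

stop_contract <- function(...) {
  stop(errorCondition(paste0(...), class = c("rsmoco_contract_error", "rsmoco_error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("rsmoco_io_error", "rsmoco_error")))
}

check_same_shape <- function(a, b, what = "arrays") {
  da <- if (is.null(dim(a))) length(a) else dim(a)
  db <- if (is.null(dim(b))) length(b) else dim(b)
  if (!identical(da, db)) {
    stop_contract(what, " must share shape (got ", paste(da, collapse = "x"),
                  " vs ", paste(db, collapse = "x"), ")")
  }
  invisible(TRUE)
}
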