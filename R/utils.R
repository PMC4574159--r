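# condition helpers: paste-style messages, call suppressed
abort <- function(...) stop(paste0(...), call. = FALSE)
warn <- function(...) warning(paste0(...), call. = FALSE)
inform <- function(...) message(paste0(...))
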