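# Typed conditions so callers can distinguish failure modes with
# tryCatch(..., EmptyMaskError = ...) etc. All inherit from "astromorphError".

.amStop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "astromorphError")))
}

.amWarn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = c(class, "astromorphWarning")))
}
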