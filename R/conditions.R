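# Classed conditions so callers (and the CLI exit-code map) can distinguish
# bad user input, corrupt payloads, unsupported features and I/O failures.

szdpdStop <- function(class, fmt, ...) {
    msg <- if (length(list(...)) > 0) sprintf(fmt, ...) else fmt
    stop(structure(
        class = c(class, "szdpdError", "error", "condition"),
        list(message = msg, call = sys.call(-1))
    ))
}

stopInvalidInput <- function(fmt, ...) szdpdStop("szdpdInvalidInputError", fmt, ...)
stopRange        <- function(fmt, ...) szdpdStop("szdpdRangeError", fmt, ...)
stopFormat       <- function(fmt, ...) szdpdStop("szdpdFormatError", fmt, ...)
stopLookup       <- function(fmt, ...) szdpdStop("szdpdLookupError", fmt, ...)
stopParse        <- function(fmt, ...) szdpdStop("szdpdParseError", fmt, ...)
stopIO           <- function(fmt, ...) szdpdStop("szdpdIOError", fmt, ...)
stopUsage        <- function(fmt, ...) szdpdStop("szdpdUsageError", fmt, ...)
stopConfig       <- function(fmt, ...) szdpdStop(c("szdpdConfigError", "szdpdUsageError"), fmt, ...)
stopCapacity     <- function(fmt, ...) szdpdStop(c("szdpdCapacityError", "szdpdInvalidInputError"), fmt, ...)
stopUnsupported  <- function(fmt, ...) szdpdStop(c("szdpdUnsupportedError", "szdpdParseError"), fmt, ...)
stopVersion      <- function(fmt, ...) szdpdStop(c("szdpdVersionError", "szdpdFormatError"), fmt, ...)
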