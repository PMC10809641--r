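#' @keywords internal
skinclock_error <- function(message, class, ...) {
  cnd <- structure(
    class = c(class, "skinclock_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cnd)
}

config_error <- function(message, ...) {
  skinclock_error(message, "skinclock_config_error", ...)
}

data_error <- function(message, ...) {
  skinclock_error(message, "skinclock_data_error", ...)
}

model_error <- function(message, ...) {
  skinclock_error(message, "skinclock_model_error", ...)
}
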