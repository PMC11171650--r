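# Structured conditions for the pipeline. Every error a stage can raise gets a
# dedicated class so callers (and the CLI) can branch on failure mode rather
# than parsing messages.

stop_lesionfd <- function(message, class, ...) {
  abort(message, class = c(class, "lesionfd_error"), ...)
}

stop_ingest <- function(message, ...) {
  stop_lesionfd(message, "lesionfd_ingest_error", ...)
}

stop_degenerate_image <- function(message, ...) {
  stop_lesionfd(message, "lesionfd_degenerate_image_error", ...)
}

stop_empty_mask <- function(message, ...) {
  stop_lesionfd(message, "lesionfd_empty_mask_error", ...)
}

stop_vocabulary <- function(message, ...) {
  stop_lesionfd(message, "lesionfd_vocabulary_error", ...)
}

stop_insufficient_data <- function(message, ...) {
  stop_lesionfd(message, "lesionfd_insufficient_data_error", ...)
}

stop_degenerate_input <- function(message, ...) {
  stop_lesionfd(message, "lesionfd_degenerate_input_error", ...)
}

stop_value <- function(message, ...) {
  stop_lesionfd(message, "lesionfd_value_error", ...)
}
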