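## internal helpers

# Round half away from zero (commercial rounding), used only at report time.
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Format an integer-rounded count with thousands separator, as in the
# published tables ("1,680").
format_count <- function(x) {
  formatC(round_half_up(x), format = "d", big.mark = ",")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("ncdexcess_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
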