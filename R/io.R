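# Plain-text exchange formats: stimuli as two-column (t_ms, value) tables,
# spike trains as one-column spike-time lists, profiles as (f, value)
# tables, fingerprints as dense matrices with axis headers.

#' Read and write package objects as delimited text
#'
#' @param x Object to write.
#' @param path File path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_stimulus <- function(x, path) {
  write.table(data.frame(t_ms = x$t, value = x$value), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus
#' @export
write_spike_train <- function(x, path) {
  writeLines(c(sprintf("# T_s=%g trial=%d", x$T, x$trial),
               format(x$times, digits = 10, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_spike_train <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  T <- as.numeric(sub(".*T_s=([0-9.eE+-]+).*", "\\1", hdr))
  trial <- as.integer(sub(".*trial=([0-9]+).*", "\\1", hdr))
  times <- as.numeric(lines[-1])
  new_spike_train(times[!is.na(times)], T, trial)
}

#' @rdname write_stimulus
#' @export
write_profile <- function(x, path) {
  p <- profile_xy(x)
  df <- data.frame(f_hz = p$f, value = p$value)
  if (inherits(x, "nr_impedance")) names(df)[2] <- "impedance"
  if (inherits(x, "nr_coherence")) names(df)[2] <- "coherence"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus
#' @export
write_fingerprint <- function(x, path) {
  m <- expand_phase(x)
  df <- data.frame(f_hz = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
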