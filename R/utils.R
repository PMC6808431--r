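#' @keywords internal
"_PACKAGE"

# Internal assertion helper: stop with the caller's message if cond is FALSE.
stopifnot_msg <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Derive a child RNG seed from a master seed and a small stream index,
# keeping the result inside the 32-bit signed integer range. Each data
# product draws from its own stream so that, e.g., adding an outcome to the
# event generator never perturbs the panel draws.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103L + stream * 7919) %% 2147483647)
}

# Write a data.frame as TSV with stable formatting (used by the pipeline so
# repeated runs under the same seed are byte-identical).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
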