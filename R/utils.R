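# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the run
#' seed so that stages can be re-run independently yet reproducibly.
#' Seeds stay below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param stream Character label of the consumer (e.g. "founders").
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483587) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# canonical TSV writer: fixed number formatting so identical inputs give
# byte-identical files
write_tsv <- function(df, path, digits = 6) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = digits, format = "g")
      df[[j]][df[[j]] %in% c("NA", " NA")] <- NA
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE, ...)
}
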