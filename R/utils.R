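# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero (round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

read_tsv_checked <- function(path, cols, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot_cols(df, cols, what)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Create an empty filtering funnel log
#'
#' Every filtering stage of the pipeline appends one record per removal
#' reason, so the full funnel from raw sites to reported linked rSNPs can be
#' audited.
#'
#' @return An environment-backed logger with `$add(stage, n_in, n_out,
#'   reason)` and `$table()` accessors.
#' @export
funnel_log <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  add <- function(stage, n_in, n_out, reason = NA_character_) {
    env$rows[[length(env$rows) + 1L]] <- data.frame(
      stage = stage, n_in = as.integer(n_in), n_out = as.integer(n_out),
      removed = as.integer(n_in) - as.integer(n_out),
      reason = reason, stringsAsFactors = FALSE
    )
    invisible(NULL)
  }
  tab <- function() {
    if (!length(env$rows)) {
      return(data.frame(stage = character(), n_in = integer(),
                        n_out = integer(), removed = integer(),
                        reason = character(), stringsAsFactors = FALSE))
    }
    do.call(rbind, env$rows)
  }
  structure(list(add = add, table = tab), class = "rsnp_funnel")
}

#' @export
print.rsnp_funnel <- function(x, ...) {
  print(x$table())
  invisible(x)
}
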