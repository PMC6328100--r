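`%||%` <- function(x, y) if (is.null(x) || !length(x)) y else x

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' @noRd
yn <- function(x) if (isTRUE(x)) "yes" else "no"

# TRUE when `name` occurs in any of `values` delimited by non-alphanumeric
# characters, case-insensitively; "trnH" matches "trnH-GUG" but not "atrnH".
name_matches <- function(values, name) {
  if (!length(values) || !nzchar(name)) return(FALSE)
  pat <- paste0("(^|[^A-Za-z0-9])", escape_regex(name), "([^A-Za-z0-9]|$)")
  any(grepl(pat, values, ignore.case = TRUE))
}

# case-insensitive plain-substring match of any pattern in any value
contains_any <- function(values, patterns) {
  if (!length(values) || !length(patterns)) return(FALSE)
  values <- tolower(values)
  any(vapply(tolower(patterns), function(p) any(grepl(p, values, fixed = TRUE)),
             logical(1)))
}

# Checklist cells must not break the TSV layout.
sanitize_cell <- function(x) {
  x[is.na(x)] <- ""
  gsub("[\t\r\n]+", " ", x)
}

# Run `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
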