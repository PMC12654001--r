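# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a disease term
#'
#' Case-folds, trims leading/trailing whitespace and collapses internal
#' whitespace runs to a single space. All disease-term matching in the
#' pipeline (network assembly, gold-standard comparison, permutation
#' sampling) happens on normalized terms, so "Chronic  Colitis " and
#' "chronic colitis" are the same term.
#'
#' @param x character vector of terms.
#' @return normalized character vector of the same length.
#' @export
normalize_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Apply an optional synonym table (data.frame with columns term, canonical)
# after normalization. Unmatched terms pass through unchanged.
apply_synonyms <- function(x, synonyms = NULL) {
  if (is.null(synonyms)) {
    return(x)
  }
  stopifnot(is.data.frame(synonyms), all(c("term", "canonical") %in% names(synonyms)))
  from <- normalize_term(synonyms$term)
  to <- normalize_term(synonyms$canonical)
  idx <- match(x, from)
  x[!is.na(idx)] <- to[idx[!is.na(idx)]]
  x
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Independent random sub-streams (one per prescription and gold-standard
#' category, one per gene set, one per synthetic table) are derived from a
#' single master seed by hashing the master seed together with string
#' labels. Because the sub-seed depends only on the labels, adding a
#' prescription or gene set never perturbs the draws of any other.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the sub-stream.
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(format(master, scientific = FALSE), ...), collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(key)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

# Strict numeric parser for table loading: blank is NA (only when allowed),
# anything else must parse as a finite number.
parse_numeric_strict <- function(x, table, column, allow_blank = FALSE) {
  x <- trimws(as.character(x))
  blank <- is.na(x) | x == "" | toupper(x) == "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- !blank & (is.na(out) | !is.finite(out))
  if (any(bad)) {
    stop(sprintf(
      "table '%s', column '%s': unparseable numeric value(s): %s",
      table, column, paste(unique(x[bad])[seq_len(min(3, sum(bad)))], collapse = ", ")
    ), call. = FALSE)
  }
  if (any(blank) && !allow_blank) {
    stop(sprintf("table '%s', column '%s': blank values are not allowed", table, column),
      call. = FALSE
    )
  }
  out[blank] <- NA_real_
  out
}

require_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "table '%s' is missing required column(s): %s",
      table, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}
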