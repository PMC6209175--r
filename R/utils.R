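# internal helpers: name canonicalization, deterministic seeding, TSV output

MERSENNE31 <- 2147483647

#' Canonicalize species names
#'
#' Trims surrounding whitespace, collapses internal runs of whitespace and
#' case-folds to lower case, so that hand-entered field labels such as
#' `" B. Elongatulus"` and `"b. elongatulus"` refer to the same species.
#'
#' @param x Character vector of species names.
#' @return Character vector of canonical names.
#' @export
canonicalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

# deterministic 31-bit rolling hash of a string; never uses R's RNG
str_hash31 <- function(s) {
  codes <- utf8ToInt(enc2utf8(s))
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% MERSENNE31
  h
}

#' Derive a per-unit child seed from a root seed
#'
#' Child seeds are a deterministic function of the root seed and a string key
#' (e.g. `"site2/agg07"`), so per-aggregation results do not depend on the
#' order in which aggregations are processed.
#'
#' @param root_seed Integer root seed for the whole run.
#' @param key Character key identifying the unit of work.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(root_seed, key) {
  h <- str_hash31(paste0("aggmix:", key))
  # multiplier small enough that the product stays exact in double precision
  mixed <- ((root_seed %% MERSENNE31) * 48271 + h) %% MERSENNE31
  as.integer(mixed %% (MERSENNE31 - 2) + 1)
}

fmt_sig6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

#' Write a result table as TSV
#'
#' Writers emit tab-separated text with a header row, the tibble's column
#' order, and floating-point values at 6 significant digits, so repeated runs
#' with the same seed produce byte-identical artifacts.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  out <- x
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_sig6(out[[j]])
    if (is.list(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(e) paste(unlist(e), collapse = ";"),
                         character(1))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

abort_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
}
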