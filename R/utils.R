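#' @keywords internal
"_PACKAGE"

# Condition helper: every package error carries class c(<specific>, "orthomeld_error").
om_stop <- function(class, fmt, ..., data = NULL) {
  cond <- errorCondition(sprintf(fmt, ...), class = c(class, "orthomeld_error"),
                         data = data)
  stop(cond)
}

om_warn <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "orthomeld_warning")))
}

#' Round half away from zero
#'
#' Percent values in reports use commercial rounding (ties away from zero),
#' so 44.18 prints as 44 and 98.78 as 99; `round()`'s round-half-even rule
#' would disagree on exact .5 ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded with ties away from zero.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5))
#' round_half_away(98.78)
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percentage presentation pair: integer percent and one-decimal percent.
percent_pair <- function(fraction) {
  list(percent = round_half_away(100 * fraction),
       percent_1dp = round_half_away(100 * fraction, 1))
}

# Locale-independent sort (C collation) used for all deterministic outputs.
om_sort <- function(x) sort(x, method = "radix")

# Read a tab-separated file: '#' comment lines and blank lines dropped,
# optional header auto-detected by comparing the first surviving line's
# fields against the canonical column names.
om_read_tsv <- function(path, col_names) {
  if (!file.exists(path)) {
    om_stop("orthomeld_io_error", "file does not exist: %s", path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) && identical(tolower(strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]),
                                 tolower(col_names))) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops trailing empty fields; restore them from the tab count
  n_tabs <- lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE)))
  fields <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    c(f, rep("", n_tabs[i] + 1L - length(f)))
  })
  bad <- which(vapply(fields, length, 1L) != length(col_names))
  if (length(bad)) {
    om_stop("orthomeld_parse_error",
            "%s:%d: expected %d tab-separated fields, got %d in %s",
            path, lineno[bad[1]], length(col_names),
            length(fields[[bad[1]]]), sQuote(lines[bad[1]]))
  }
  out <- as.data.frame(do.call(rbind, c(fields, list(deparse.level = 0))),
                       stringsAsFactors = FALSE)
  if (!length(lines)) {
    out <- as.data.frame(matrix(character(), 0, length(col_names)),
                         stringsAsFactors = FALSE)
  }
  names(out) <- col_names
  attr(out, "line_numbers") <- lineno
  out
}

om_write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8",
                     eol = "\n")
  invisible(path)
}

# Extract the gene universe from either an ortho_consensus or a character vector.
#' Genes contained in a consensus
#'
#' Most evaluation functions accept either an [build_consensus()] object or a
#' plain character vector of canonical gene identifiers standing in for a
#' consensus list; this accessor unifies the two.
#'
#' @param consensus an `ortho_consensus` object or character vector.
#' @return character vector of gene identifiers.
#' @export
consensus_genes <- function(consensus) {
  if (inherits(consensus, "ortho_consensus")) return(consensus$entries$gene)
  if (is.character(consensus)) return(unique(consensus))
  om_stop("orthomeld_config_error",
          "expected an 'ortho_consensus' object or a character vector of genes")
}
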