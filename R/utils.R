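#' Build residue keys
#'
#' A residue key is the string `"<chain>:<resno><icode>"` built from the chain
#' identifier, the author residue number and the (possibly empty) insertion
#' code. Author numbering is preserved verbatim so results can be compared to
#' published residue labels.
#'
#' @param chain character vector of chain identifiers.
#' @param resno integer vector of author residue numbers.
#' @param icode character vector of insertion codes (`""` or `NA` for none).
#' @return character vector of keys.
#' @export
residue_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode), "", icode)
  paste0(chain, ":", resno, icode)
}

#' Select scores at or above an interpolated quantile threshold
#'
#' The threshold is the linear-interpolation percentile of `scores`
#' (`stats::quantile` type 7); entries tied with the threshold are included.
#' Used both for the top-25% essential-residue rule and the top-5% hub rule.
#'
#' @param scores numeric vector (no NAs).
#' @param quantile fraction in (0, 1).
#' @return logical vector, TRUE where `scores >= threshold`.
#' @export
select_top_quantile <- function(scores, quantile) {
  stopifnot(is.numeric(scores), length(scores) >= 1L, !anyNA(scores))
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile >= 1) {
    stop("`quantile` must be a single value in (0, 1)", call. = FALSE)
  }
  thr <- stats::quantile(scores, probs = quantile, type = 7, names = FALSE)
  scores >= thr
}

# Run code with a private, seeded RNG stream; the caller's global
# .Random.seed is restored afterwards so generation has no global side effect.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Population (n-denominator) standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Write a data.frame as a deterministic TSV (header, '.' decimal, UTF-8, LF).
write_tsv_det <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

# Recursively sort list names so JSON output is key-stable.
sort_keys <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x)))) x <- x[order(names(x))]
    x <- lapply(x, sort_keys)
  }
  x
}
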