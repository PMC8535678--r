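# Internal helpers shared across modules.

#' Geometric mean
#'
#' Geometric mean of a vector of strictly positive values, computed on the
#' log scale for numerical stability. Used for BestKeeper indices,
#' normalization factors and RefFinder rank aggregation.
#'
#' @param x Numeric vector, all values > 0.
#' @return A single number, `exp(mean(log(x)))`.
#' @export
#' @examples
#' geomean(c(2, 4, 8)) # 4
geomean <- function(x) {
  if (length(x) == 0L) {
    rlang::abort("`x` must be non-empty.", class = "refstab_input_error")
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    rlang::abort("geometric mean requires finite, strictly positive values.",
      class = "refstab_domain_error"
    )
  }
  exp(mean(log(x)))
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    rlang::abort("`seed` must be a single integer.", class = "refstab_config_error")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_complete <- function(mat, what = "Cq") {
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    cells <- paste0(rownames(mat)[bad[, 1]], "/", colnames(mat)[bad[, 2]])
    rlang::abort(
      paste0(
        "incomplete ", what, " matrix; missing cells (gene/sample): ",
        paste(utils::head(cells, 10L), collapse = ", "),
        if (nrow(bad) > 10L) " ..." else ""
      ),
      class = "refstab_missing_data_error"
    )
  }
  invisible(mat)
}
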