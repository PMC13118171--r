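#' Inverse logit
#'
#' @param x numeric vector on the real line.
#' @return numeric vector in (0, 1).
#' @export
expit <- function(x) 1 / (1 + exp(-x))

#' Logit transform
#'
#' @param p numeric vector in (0, 1).
#' @return numeric vector on the real line.
#' @export
logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_prevmapr <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "prevmapr_error")))
}

# variance floor below which a design variance is treated as zero / unusable
VAR_FLOOR <- 1e-12

check_columns <- function(df, required, what = "table") {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_prevmapr(
      "missing column(s) in ", what, ": ", paste(missing, collapse = ", "),
      class = "prevmapr_schema_error"
    )
  }
  invisible(TRUE)
}

# weighted quantiles of posterior draws (plain type-7 on equal weights)
draw_summary <- function(draws, probs = c(0.05, 0.5, 0.95)) {
  qs <- apply(draws, 2, stats::quantile, probs = probs, names = FALSE)
  data.frame(
    mean = colMeans(draws),
    median = qs[2, ],
    q05 = qs[1, ],
    q95 = qs[3, ]
  )
}
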