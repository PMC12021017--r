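# Evaluation metrics: coefficient of determination, Pearson correlation,
# RMSE, MAE, and grouped reporting (per EC class, similarity bin, or
# enzyme type). Undefined metrics raise rather than returning NaN so
# reports are explicit.

check_lengths <- function(y_true, y_pred, min_n = 1) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (length(y_true) < min_n) {
    stop("need at least ", min_n, " observations", call. = FALSE)
  }
}

#' Coefficient of determination
#'
#' R^2 = 1 - sum((y_e - y_p)^2) / sum((y_e - mean(y_e))^2). At most 1;
#' negative when predictions are worse than the mean.
#'
#' @param y_true Experimental values (not constant, length >= 2).
#' @param y_pred Predicted values.
#' @return Scalar R^2.
#' @export
r_squared <- function(y_true, y_pred) {
  check_lengths(y_true, y_pred, min_n = 2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    stop("R^2 undefined: y_true is constant", call. = FALSE)
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation between experimental and predicted
#' values; invariant under positive affine transforms of either
#' argument and symmetric in its arguments.
#'
#' @param y_true,y_pred Numeric vectors (both non-constant, length >= 2).
#' @return Scalar in [-1, 1].
#' @export
pearson <- function(y_true, y_pred) {
  check_lengths(y_true, y_pred, min_n = 2)
  d_e <- y_true - mean(y_true)
  d_p <- y_pred - mean(y_pred)
  denom <- sqrt(sum(d_e^2)) * sqrt(sum(d_p^2))
  if (denom == 0) {
    stop("PCC undefined: constant input", call. = FALSE)
  }
  sum(d_e * d_p) / denom
}

#' Root mean squared error
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 1.
#' @return Scalar; always >= [mae()].
#' @export
rmse <- function(y_true, y_pred) {
  check_lengths(y_true, y_pred, min_n = 1)
  sqrt(mean((y_true - y_pred)^2))
}

#' Mean absolute error
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 1.
#' @return Scalar.
#' @export
mae <- function(y_true, y_pred) {
  check_lengths(y_true, y_pred, min_n = 1)
  mean(abs(y_true - y_pred))
}

#' Grouped evaluation report
#'
#' Computes R^2, PCC, RMSE and MAE per group (e.g. EC class, similarity
#' bin, or wild-type vs mutant) plus a pooled `all` row. Groups with
#' fewer than 2 observations, or with a constant truth or prediction
#' vector, are skipped with a warning.
#'
#' @param y_true,y_pred Numeric vectors.
#' @param groups Group label per observation.
#' @return Tibble with columns `group_label`, `n`, `r2`, `pcc`, `rmse`,
#'   `mae`, class `eval_report`.
#' @export
grouped_report <- function(y_true, y_pred, groups) {
  check_lengths(y_true, y_pred, min_n = 2)
  if (length(groups) != length(y_true)) {
    stop("groups must align with the value vectors", call. = FALSE)
  }
  one <- function(label, idx) {
    yt <- y_true[idx]; yp <- y_pred[idx]
    if (length(idx) < 2 || sd(yt) == 0 || sd(yp) == 0) {
      warning("group '", label, "' skipped (n < 2 or constant values)",
              call. = FALSE)
      return(NULL)
    }
    tibble::tibble(group_label = label, n = length(idx),
                   r2 = r_squared(yt, yp), pcc = pearson(yt, yp),
                   rmse = rmse(yt, yp), mae = mae(yt, yp))
  }
  parts <- c(
    lapply(sort(unique(as.character(groups))), function(g) {
      one(g, which(as.character(groups) == g))
    }),
    list(one("all", seq_along(y_true)))
  )
  out <- dplyr::bind_rows(parts)
  class(out) <- c("eval_report", class(out))
  out
}

#' Plot a grouped evaluation report
#'
#' Bar chart of one metric across groups (the pooled `all` row is drawn
#' last).
#'
#' @param object An `eval_report` from [grouped_report()].
#' @param metric One of `"r2"`, `"pcc"`, `"rmse"`, `"mae"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, metric = "r2", ...) {
  metric <- match.arg(metric, c("r2", "pcc", "rmse", "mae"))
  df <- object
  df$group_label <- factor(df$group_label,
                           levels = c(setdiff(unique(df$group_label), "all"),
                                      "all"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group_label,
                                   y = .data[[metric]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Group", y = toupper(metric))
}
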