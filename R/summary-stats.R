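#' Condition-by-receptor median binding matrix
#'
#' Reshapes a replicate-level measurement table into the matrix analysed by
#' PCA: one row per (valency, pair, composition) condition, one column per
#' receptor variant, each cell the median normalized RFU across replicates
#' and days. Incomplete condition x receptor coverage is rejected.
#'
#' @param tbl measurement table.
#' @return numeric matrix with condition labels as rownames.
#' @export
condition_matrix <- function(tbl) {
  med <- tbl |>
    dplyr::group_by(.data$valency, .data$pair, .data$frac1, .data$receptor) |>
    dplyr::summarise(m = stats::median(.data$rfu), .groups = "drop")
  wide <- tidyr::pivot_wider(med, names_from = "receptor", values_from = "m")
  mat <- as.matrix(wide[, -(1:3)])
  rownames(mat) <- paste0("f", wide$valency, ":", wide$pair, ":", wide$frac1)
  if (anyNA(mat)) rlang::abort("condition matrix incomplete: missing condition x receptor cells")
  mat
}

#' Fraction of variance explained by a rank-k PCA reconstruction
#'
#' \eqn{1 - \|X - \hat X_k\|_F^2 / \|X\|_F^2} where \eqn{\hat X_k} is the
#' rank-`k` truncated singular value decomposition of the (optionally
#' column-centered) matrix. Equals the cumulative squared-singular-value
#' fraction and is nondecreasing in `k`.
#'
#' @param mat numeric matrix (conditions x receptors).
#' @param k number of components, `k <= min(dim(mat))`.
#' @param center column-center before decomposing (default TRUE; standard
#'   PCA practice, which loading interpretation presumes).
#' @return fraction in \[0, 1\].
#' @export
pca_variance_explained <- function(mat, k, center = TRUE) {
  if (!length(mat)) rlang::abort("empty matrix")
  if (k < 0 || k > min(dim(mat))) rlang::abort("k out of range")
  x <- if (center) scale(mat, center = TRUE, scale = FALSE) else mat
  sv <- svd(x)
  xk <- if (k == 0) matrix(0, nrow(x), ncol(x))
        else sv$u[, 1:k, drop = FALSE] %*%
          (sv$d[1:k] * t(sv$v[, 1:k, drop = FALSE]))
  1 - sum((x - xk)^2) / sum(x^2)
}

#' PCA scores and loadings of the condition matrix
#'
#' @param mat condition matrix from [condition_matrix()].
#' @param center column-center before decomposing.
#' @return list with `scores`, `loadings` (tibbles) and `variance_explained`
#'   (cumulative, per number of components).
#' @export
pca_summary <- function(mat, center = TRUE) {
  x <- if (center) scale(mat, center = TRUE, scale = FALSE) else mat
  sv <- svd(x)
  k <- length(sv$d)
  scores <- tibble::as_tibble(sv$u %*% diag(sv$d, k),
                              .name_repair = ~ paste0("PC", seq_len(k)))
  scores$condition <- rownames(mat)
  loadings <- tibble::as_tibble(sv$v, .name_repair = ~ paste0("PC", seq_len(k)))
  loadings$receptor <- colnames(mat)
  list(scores = scores, loadings = loadings,
       variance_explained = cumsum(sv$d^2) / sum(x^2))
}

#' Between-condition fraction of total variance (one-way ANOVA layout)
#'
#' Between-condition sum of squares over total sum of squares, grouping
#' replicate measurements by condition label. Returns 0 when the total sum
#' of squares is zero (all values identical).
#'
#' @param values numeric replicate measurements.
#' @param condition condition label per measurement.
#' @return fraction in \[0, 1\].
#' @export
anova_between_fraction <- function(values, condition) {
  if (length(values) != length(condition)) rlang::abort("length mismatch")
  if (length(unique(condition)) < 2 && length(values) < 2) {
    rlang::abort("need >= 2 measurements")
  }
  grand <- mean(values)
  sst <- sum((values - grand)^2)
  if (sst == 0) return(0)
  gm <- tapply(values, condition, mean)
  gn <- tapply(values, condition, length)
  ssb <- sum(gn * (gm - grand)^2)
  ssb / sst
}

#' Intervalency binding ratios
#'
#' Ratio of median binding between the high- and low-valency arms of each
#' pure-composition (single subclass) condition. Low-affinity interactions
#' gain disproportionately from avidity, so this ratio anti-correlates with
#' monovalent affinity.
#'
#' @param tbl measurement table.
#' @param high,low valency labels of the two arms.
#' @return tibble (`receptor`, `subclass`, `ratio`).
#' @export
intervalency_ratio <- function(tbl, high = 33, low = 4) {
  pure <- tbl |>
    dplyr::filter(.data$frac1 %in% c(0, 1)) |>
    dplyr::mutate(subclass = {
      pm <- .split_pair(.data$pair)
      ifelse(.data$frac1 == 1, pm$first, pm$second)
    })
  med <- pure |>
    dplyr::group_by(.data$receptor, .data$subclass, .data$valency) |>
    dplyr::summarise(m = stats::median(.data$rfu), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "valency", values_from = "m",
                       names_prefix = "v")
  hi_col <- paste0("v", high); lo_col <- paste0("v", low)
  if (!all(c(hi_col, lo_col) %in% names(med)) ||
      anyNA(med[[hi_col]]) || anyNA(med[[lo_col]])) {
    rlang::abort("both valency arms must be present for every (receptor, subclass)")
  }
  dplyr::transmute(med, .data$receptor, .data$subclass,
                   ratio = .data[[hi_col]] / .data[[lo_col]])
}

#' Spearman rank correlation with t-statistic test
#'
#' Spearman's rho with a two-sided p value from
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom (the
#' large-sample t approximation). Ties receive average ranks.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return tibble (`rho`, `statistic`, `p_value`, `n`).
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) rlang::abort("need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("constant input vector")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    t_stat <- sign(rho) * Inf
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  tibble::tibble(rho = rho, statistic = t_stat, p_value = p, n = n)
}
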