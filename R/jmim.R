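#' Equal-frequency discretization of one feature
#'
#' Bins a continuous per-lesion feature into `B` approximately
#' equal-frequency bins by quantile cut points (stable under ties: tied
#' boundary values all fall in the same bin). A constant feature collapses
#' to a single bin and is flagged as carrying zero information.
#'
#' @param x numeric vector.
#' @param B requested bin count (>= 2).
#' @return Integer vector of 1-based bins with attributes `n_levels` and
#'   `zero_information`.
#' @export
discretize_feature <- function(x, B = 10) {
  if (B < 2) stop("B must be >= 2")
  if (length(unique(x)) == 1L) {
    return(structure(rep(1L, length(x)), n_levels = 1L, zero_information = TRUE))
  }
  cuts <- unique(stats::quantile(x, probs = seq_len(B - 1) / B,
                                 names = FALSE, type = 7))
  bins <- findInterval(x, cuts, left.open = TRUE) + 1L
  # compact to consecutive codes (ties can empty a bin)
  bins <- match(bins, sort(unique(bins)))
  structure(as.integer(bins), n_levels = max(bins), zero_information = FALSE)
}

#' Plug-in mutual information (bits)
#'
#' Empirical mutual information of two discrete vectors from their joint
#' contingency table, base-2 logarithm.
#'
#' @param a,b equal-length vectors (coerced to discrete codes).
#' @return Mutual information in bits (>= 0).
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  ia <- match(a, sort(unique(a)))
  ib <- match(b, sort(unique(b)))
  cpp_mi(ia, ib, max(ia), max(ib))
}

#' Joint mutual information I((F, S); Y) in bits
#'
#' Mutual information between the paired variable `(f, s)` and the label
#' `y`; the quantity maximin-ed by the JMIM selection criterion.
#'
#' @param f,s,y equal-length discrete vectors.
#' @return Joint mutual information in bits.
#' @export
joint_mi <- function(f, s, y) {
  if (length(f) != length(s) || length(f) != length(y))
    stop("length mismatch")
  mutual_information(paste(f, s, sep = "\r"), y)
}

# Discretize all feature columns of a numeric matrix; returns integer
# matrix plus per-column level counts.
discretize_matrix <- function(X, B) {
  D <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(X))
  nlev <- integer(ncol(X))
  for (j in seq_len(ncol(X))) {
    d <- discretize_feature(X[, j], B)
    D[, j] <- d
    nlev[j] <- attr(d, "n_levels")
  }
  list(D = D, nlev = nlev)
}

#' Greedy feature selection by joint mutual information maximization
#'
#' The first feature maximizes `I(f; Y)`. Each subsequent pick maximizes
#' `min over already-selected s of I((f, s); Y)` (the maximin JMIM
#' criterion). Continuous features are discretized to `bins`
#' equal-frequency bins; labels are used as-is. Ties break by column
#' order.
#'
#' @param table feature table (data frame or matrix); metadata columns
#'   `case_id`/`lesion_id`/`center_id`/`label` are ignored if present.
#' @param labels binary (or discrete) label vector.
#' @param k number of features to select.
#' @param bins equal-frequency bin count for the MI estimator.
#' @return A `jmim_selection`: list with `selected` (ordered feature names)
#'   and `criterion` (the per-step criterion value `J`).
#' @export
jmim_select <- function(table, labels, k, bins = 10) {
  if (k <= 0) stop("k must be >= 1")
  X <- as.matrix(table[, setdiff(colnames(table), feature_table_meta),
                       drop = FALSE])
  if (k > ncol(X)) stop("k exceeds the number of features")
  n <- nrow(X)
  if (length(labels) != n) stop("length mismatch")
  y <- match(labels, sort(unique(labels)))
  ny <- max(y)
  dm <- discretize_matrix(X, bins)
  rel <- cpp_mi_all(dm$D, y, dm$nlev, ny)

  selected <- integer(0)
  J <- numeric(0)
  minjoint <- rep(Inf, ncol(X))
  score <- rel
  for (step in seq_len(k)) {
    score[selected] <- -Inf
    pick <- which.max(score)  # ties: first (column order)
    selected <- c(selected, pick)
    J <- c(J, score[pick])
    if (step == k) break
    jm <- cpp_joint_mi_all(dm$D, dm$D[, pick], y, dm$nlev, dm$nlev[pick], ny)
    minjoint <- pmin(minjoint, jm)
    score <- minjoint
  }
  structure(list(selected = colnames(X)[selected], criterion = J),
            class = "jmim_selection")
}

#' @export
print.jmim_selection <- function(x, ...) {
  cat(sprintf("<jmim_selection: %d features>\n", length(x$selected)))
  print(utils::head(data.frame(feature = x$selected, J = x$criterion), 10))
  invisible(x)
}
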