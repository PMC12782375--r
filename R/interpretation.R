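#' 2x2 contingency table
#'
#' Cell counts for two binary variables: `n11` both positive, `n10` first
#' positive only, `n01` second positive only, `n00` both negative.
#'
#' @param n11,n10,n01,n00 nonnegative integer counts.
#' @return object of class `contingency_2x2` with the cells, marginals
#'   and total.
#' @export
contingency_2x2 <- function(n11, n10, n01, n00) {
  cells <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("counts must be nonnegative integers")
  n <- sum(cells)
  if (n == 0) stop("empty table")
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 n1. = n11 + n10, n0. = n01 + n00,
                 n.1 = n11 + n01, n.0 = n10 + n00, n = n),
            class = "contingency_2x2")
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Phi coefficient of a 2x2 table with chi-square significance
#'
#' The phi coefficient is the correlation of two binary variables,
#' \deqn{\phi = \frac{n_{11} n_{00} - n_{10} n_{01}}
#'   {\sqrt{n_{1\cdot} n_{0\cdot} n_{\cdot 1} n_{\cdot 0}}},}
#' ranging over \[-1, 1\]. Significance uses the Pearson chi-square
#' statistic with one degree of freedom and no continuity correction, via
#' the exact identity chi-square = n phi^2.
#'
#' @param t a [contingency_2x2()], or a 2x2 matrix of counts with rows =
#'   first variable (1 then 0) and columns = second variable (1 then 0).
#' @return object of class `phi_result`: `phi`, `chi2`, `p_value`, `n`,
#'   `stars`.
#' @export
phi_coefficient <- function(t) {
  if (is.matrix(t)) t <- contingency_2x2(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  if (!inherits(t, "contingency_2x2")) stop("t must be a contingency_2x2")
  marg <- c(t$n1., t$n0., t$n.1, t$n.0)
  if (any(marg == 0))
    stop("phi undefined: a marginal count is zero")
  phi <- (as.numeric(t$n11) * t$n00 - as.numeric(t$n10) * t$n01) /
    sqrt(prod(as.numeric(marg)))
  chi2 <- t$n * phi^2
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(phi = phi, chi2 = chi2, p_value = p, n = t$n,
                 stars = significance_stars(p)),
            class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf("phi = %.4f%s  (chi2 = %.3f, df = 1, p = %.3g, n = %d)\n",
              x$phi, x$stars, x$chi2, x$p_value, x$n))
  invisible(x)
}

#' Pairwise phi association matrix of binary endpoints
#'
#' Computes the phi coefficient and chi-square significance for every
#' pair of binary label columns (by default the five ADMET endpoints).
#' The matrix is symmetric with a unit diagonal. A constant column cannot
#' be tested: its row and column are reported as `NA` with a warning
#' naming the property.
#'
#' @param labels data.frame (optionally with a `compound_id` column) or
#'   matrix of 0/1 labels, one column per property.
#' @return object of class `phi_matrix`: `phi`, `chi2`, `p_value`,
#'   `stars` (all k x k), `n`.
#' @export
phi_association_matrix <- function(labels) {
  if (is.data.frame(labels))
    labels <- as.matrix(labels[, setdiff(names(labels), "compound_id"),
                               drop = FALSE])
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (nrow(labels) < 2L) stop("need at least 2 compounds")
  k <- ncol(labels)
  props <- colnames(labels) %||% paste0("P", seq_len(k))
  phi <- chi2 <- pval <- matrix(NA_real_, k, k, dimnames = list(props, props))
  stars <- matrix("", k, k, dimnames = list(props, props))
  const <- apply(labels, 2, function(x) length(unique(x)) < 2L)
  if (any(const))
    warning("constant propert(ies) reported as undefined: ",
            paste(props[const], collapse = ", "))
  diag(phi) <- ifelse(const, NA_real_, 1)
  diag(chi2) <- ifelse(const, NA_real_, as.numeric(nrow(labels)))
  diag(pval) <- ifelse(const, NA_real_, 0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (const[i] || const[j]) next
    a <- labels[, i]; b <- labels[, j]
    r <- phi_coefficient(contingency_2x2(sum(a & b), sum(a & !b),
                                         sum(!a & b), sum(!a & !b)))
    phi[i, j] <- phi[j, i] <- r$phi
    chi2[i, j] <- chi2[j, i] <- r$chi2
    pval[i, j] <- pval[j, i] <- r$p_value
    stars[i, j] <- stars[j, i] <- r$stars
  }
  structure(list(phi = phi, chi2 = chi2, p_value = pval, stars = stars,
                 n = nrow(labels)), class = "phi_matrix")
}

#' @export
print.phi_matrix <- function(x, digits = 4, ...) {
  cat("Pairwise phi association (n =", x$n, ")\n")
  shown <- matrix(paste0(format(round(x$phi, digits)), x$stars),
                  nrow(x$phi), dimnames = dimnames(x$phi))
  shown[is.na(x$phi)] <- "NA"
  print(shown, quote = FALSE)
  cat("Significance: *** p<0.001, ** p<0.01, * p<0.05\n")
  invisible(x)
}

# ---- Shapley attributions for boosted-tree regressors --------------------

# Flatten an xgboost booster into parallel node arrays for the C++ TreeSHAP
# kernel. Split semantics: go left ("Yes") when x < threshold.
parse_xgb_trees <- function(booster, feature_names) {
  dt <- xgboost::xgb.model.dt.tree(model = booster)
  dt <- as.data.frame(dt)
  trees <- split(dt, dt$Tree)
  off <- 0L
  offsets <- integer(length(trees))
  feat <- integer(0); thr <- numeric(0)
  left <- right <- integer(0); cov <- val <- numeric(0)
  for (t in seq_along(trees)) {
    tr <- trees[[t]]
    tr <- tr[order(tr$Node), ]
    offsets[t] <- off
    id2local <- setNames(seq_len(nrow(tr)) - 1L, tr$ID)
    is_leaf <- tr$Feature == "Leaf"
    fidx <- rep(-1L, nrow(tr))
    fidx[!is_leaf] <- match(tr$Feature[!is_leaf], feature_names) - 1L
    if (any(is.na(fidx)))
      stop("tree references unknown feature(s)")
    feat <- c(feat, fidx)
    thr <- c(thr, ifelse(is_leaf, 0, as.numeric(tr$Split)))
    left <- c(left, ifelse(is_leaf, -1L, id2local[tr$Yes]))
    right <- c(right, ifelse(is_leaf, -1L, id2local[tr$No]))
    cov <- c(cov, as.numeric(tr$Cover))
    val <- c(val, ifelse(is_leaf, as.numeric(tr$Gain), 0))
    off <- off + nrow(tr)
  }
  list(tree_offset = offsets, feature = as.integer(feat), threshold = thr,
       left = as.integer(left), right = as.integer(right),
       cover = cov, value = val)
}

#' Exact Shapley attributions for a boosted-tree activity model
#'
#' Computes per-compound, per-descriptor additive attributions (pIC50
#' units) for a fitted `boosted_trees` or `hist_boosted_trees` regressor
#' with the exact path-dependent tree-Shapley algorithm, run in double
#' precision over the parsed trees. The base value is the cover-weighted
#' (training-distribution) mean prediction. Local accuracy holds by
#' construction: for every row, `sum(attributions) + base_value` equals
#' the model prediction (double-precision tree traversal) to near machine
#' precision, and the operation verifies this before returning.
#'
#' Forest-type and SVM models are not supported and raise an error;
#' attribution targets the boosted activity model.
#'
#' @param model a `qsar_regressor` of family `boosted_trees` or
#'   `hist_boosted_trees`.
#' @param X a [descriptor_matrix()] (typically the held-out test
#'   partition) carrying the model's descriptors.
#' @param check_tol tolerance of the local-accuracy verification.
#' @return object of class `attribution_matrix`: `attributions` (n x p),
#'   `base_value`, `prediction` (double-precision model output),
#'   `feature_values`, `compound_ids`.
#' @export
compute_attributions <- function(model, X, check_tol = 1e-6) {
  if (!inherits(model, "qsar_regressor") ||
      !model$family %in% c("boosted_trees", "hist_boosted_trees"))
    stop("attributions are supported for boosted_trees / hist_boosted_trees ",
         "models only (got ",
         if (inherits(model, "qsar_regressor")) model$family else class(model)[1],
         ")")
  Xa <- align_features(model, X)
  parsed <- parse_xgb_trees(model$fit, model$feature_names)
  res <- .treeshap_cpp(Xa, parsed$tree_offset, parsed$feature,
                       parsed$threshold, parsed$left, parsed$right,
                       parsed$cover, parsed$value)
  phi <- res$phi
  dimnames(phi) <- list(rownames(Xa), colnames(Xa))
  base_value <- res$base_value + model$base_score
  prediction <- as.numeric(res$prediction) + model$base_score
  gap <- max(abs(rowSums(phi) + base_value - prediction))
  if (gap > check_tol)
    stop(sprintf("local accuracy violated: max gap %.3g > %.3g", gap, check_tol))
  structure(list(attributions = phi, base_value = base_value,
                 prediction = prediction, feature_values = Xa,
                 compound_ids = rownames(Xa)),
            class = "attribution_matrix")
}

#' Global importance from an attribution matrix
#'
#' Ranks descriptors by the mean absolute attribution across compounds
#' (the usual global-importance bar ordering) and exports the per-sample
#' (feature value, attribution) pairs needed for beeswarm/scatter
#' rendering.
#'
#' @param a an `attribution_matrix` from [compute_attributions()].
#' @return object of class `global_importance`: `importance` (data.frame
#'   of `descriptor`, `mean_abs_attribution`, descending; ties keep input
#'   order) and `beeswarm` (long data.frame of `descriptor`,
#'   `compound_id`, `feature_value`, `attribution`).
#' @export
global_importance <- function(a) {
  if (!inherits(a, "attribution_matrix")) stop("a must be an attribution_matrix")
  m <- colMeans(abs(a$attributions))
  ord <- order(-m)
  imp <- data.frame(descriptor = colnames(a$attributions)[ord],
                    mean_abs_attribution = as.numeric(m[ord]),
                    stringsAsFactors = FALSE)
  bs <- data.frame(
    descriptor = rep(colnames(a$attributions), each = nrow(a$attributions)),
    compound_id = rep(a$compound_ids, ncol(a$attributions)),
    feature_value = as.numeric(a$feature_values),
    attribution = as.numeric(a$attributions),
    stringsAsFactors = FALSE)
  structure(list(importance = imp, beeswarm = bs),
            class = "global_importance")
}

#' @export
print.global_importance <- function(x, n = 10, ...) {
  cat("Global importance (mean |attribution|):\n")
  print(head(x$importance, n), row.names = FALSE)
  invisible(x)
}

#' Plot global importance as a bar chart
#'
#' @param x a `global_importance`.
#' @param n number of top descriptors to show.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.global_importance <- function(x, n = 20, ...) {
  top <- head(x$importance, n)
  graphics::barplot(rev(top$mean_abs_attribution),
                    names.arg = rev(top$descriptor), horiz = TRUE,
                    las = 1, xlab = "mean |attribution| (pIC50)", ...)
  invisible(x)
}
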