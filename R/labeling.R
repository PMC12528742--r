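#' Hard component assignment
#'
#' Assigns each record to its maximum-responsibility component; ties go to the
#' lower component index.
#'
#' @param data a \code{\link{development_data}}.
#' @param model a \code{\link{weibull_mixture}}.
#' @return Integer vector of component indices, one per record.
#' @export
hard_assign <- function(data, model) {
  r <- e_step(data, model)
  apply(r, 1L, which.max)
}

#' Mann-Whitney U-test of body size between two components
#'
#' Two-sided Mann-Whitney U-test on body length between the records hard-
#' assigned to components \code{a} and \code{b}. The exact null distribution is
#' used when the combined sample size is at most 20 and there are no ties;
#' otherwise the normal approximation with tie correction. Records with
#' missing length are dropped pairwise.
#'
#' @param data a \code{\link{development_data}} with a \code{length} column.
#' @param assignment integer component index per record (see
#'   \code{\link{hard_assign}}).
#' @param a,b component indices to compare.
#' @return A list with \code{statistic} (U) and \code{p_value}.
#' @export
size_test <- function(data, assignment, a = 1L, b = 2L) {
  .assert_dataset(data)
  if (base::length(assignment) != nrow(data))
    stop("assignment must have one entry per record")
  xa <- data$length[assignment == a & !is.na(data$length)]
  xb <- data$length[assignment == b & !is.na(data$length)]
  if (base::length(xa) == 0L || base::length(xb) == 0L)
    stop("both groups need at least one record with length data")
  n_tot <- base::length(xa) + base::length(xb)
  exact <- n_tot <= 20L && !anyDuplicated(c(xa, xb))
  wt <- suppressWarnings(
    stats::wilcox.test(xa, xb, alternative = "two.sided", exact = exact,
                       correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Chi-squared test of sex ratio between two components
#'
#' 2x2 chi-squared test of sex (M/F) against component membership, without
#' continuity correction. Records with unknown sex are excluded.
#'
#' @inheritParams size_test
#' @return A list with \code{statistic} (chi-squared), \code{p_value} and the
#'   2x2 \code{table}.
#' @export
sex_test <- function(data, assignment, a = 1L, b = 2L) {
  .assert_dataset(data)
  if (base::length(assignment) != nrow(data))
    stop("assignment must have one entry per record")
  keep <- assignment %in% c(a, b) & !is.na(data$sex)
  if (!any(keep)) stop("no records with known sex in the two groups")
  tab <- table(factor(assignment[keep], levels = c(a, b)),
               factor(data$sex[keep], levels = c("M", "F")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    stop(paste("a sex or component category is empty; the chi-squared test",
               "is undefined (consider Fisher's exact test)"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, table = tab)
}

#' Label mixture components as biological populations
#'
#' Applies the decision rules used to interpret fitted components:
#' \enumerate{
#'   \item If one component dominates (weight ratio at least
#'     \code{dominance_ratio}) and neither body size (Mann-Whitney U) nor sex
#'     ratio (chi-squared) differs significantly between components, the
#'     dominant component represents regular experimental results and the
#'     others are outlier observations: labels \code{regular} / \code{outlier}.
#'   \item Otherwise, if body size differs significantly, the component with
#'     the smaller mean length is the \code{small_insect} population and the
#'     other the \code{large_insect} population.
#'   \item Otherwise components stay \code{unlabeled}.
#' }
#' A single-component model is labeled \code{regular}. Models with three or
#' more components are returned unlabeled with a warning. All test evidence is
#' recorded.
#'
#' @param data a \code{\link{development_data}}.
#' @param model a \code{\link{weibull_mixture}} with 1 or 2 components.
#' @param alpha significance level for the size and sex tests (default 0.05).
#' @param dominance_ratio minimum max/min weight ratio for the dominance rule
#'   (default 3).
#' @return A list of class \code{"labeled_mixture"}: \code{model},
#'   \code{labels} (one per component, in component order), and
#'   \code{evidence} (test statistics, p-values, which rule fired, and the
#'   informational weighted midpoint of component mean lengths).
#' @export
label_components <- function(data, model, alpha = 0.05,
                             dominance_ratio = 3.0) {
  .assert_dataset(data)
  .assert_mixture(model)
  L <- nrow(model$components)
  evidence <- list(rule = "none", alpha = alpha,
                   dominance_ratio = dominance_ratio)
  if (L == 1L) {
    evidence$rule <- "single_component"
    return(structure(list(model = model, labels = "regular",
                          evidence = evidence),
                     class = "labeled_mixture"))
  }
  if (L > 2L) {
    warning("labeling rules are defined for 1 or 2 components; returning unlabeled")
    return(structure(list(model = model, labels = rep("unlabeled", L),
                          evidence = evidence),
                     class = "labeled_mixture"))
  }
  assignment <- hard_assign(data, model)
  w <- model$components$weight
  ratio <- max(w) / min(w)
  evidence$weight_ratio <- ratio
  st <- tryCatch(size_test(data, assignment, 1L, 2L), error = function(e) NULL)
  xt <- tryCatch(sex_test(data, assignment, 1L, 2L), error = function(e) NULL)
  evidence$size_test <- st
  evidence$sex_test <- xt
  mean_len <- vapply(1:2, function(l)
    mean(data$length[assignment == l], na.rm = TRUE), numeric(1L))
  evidence$mean_length <- mean_len
  # informational only: weighted midpoint between component mean lengths
  evidence$length_midpoint <- if (all(is.finite(mean_len)))
    sum(w * mean_len) else NA_real_
  labels <- rep("unlabeled", 2L)
  if (ratio >= dominance_ratio && !is.null(st) && st$p_value > alpha &&
      !is.null(xt) && xt$p_value > alpha) {
    labels[which.max(w)] <- "regular"
    labels[which.min(w)] <- "outlier"
    evidence$rule <- "dominant_regular"
  } else if (!is.null(st) && st$p_value <= alpha && all(is.finite(mean_len))) {
    labels[which.min(mean_len)] <- "small_insect"
    labels[which.max(mean_len)] <- "large_insect"
    evidence$rule <- "size_split"
  } else {
    if (is.null(st))
      warning("size data unavailable; components left unlabeled")
    evidence$rule <- "none"
  }
  structure(list(model = model, labels = labels, evidence = evidence),
            class = "labeled_mixture")
}

#' @export
print.labeled_mixture <- function(x, ...) {
  cat("Labeled mixture components:\n")
  for (l in seq_along(x$labels))
    cat(sprintf("  component %d (weight %.3f): %s\n", l,
                x$model$components$weight[l], x$labels[l]))
  cat(sprintf("rule fired: %s\n", x$evidence$rule))
  invisible(x)
}
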