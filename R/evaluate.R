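#' Pearson spatial correlation between two maps
#'
#' @param map_a,map_b numeric vectors of equal length, both non-constant.
#' @param mask optional logical vector restricting the correlation to in-mask
#'   voxels.
#' @return Pearson r.
#' @export
spatial_correlation <- function(map_a, map_b, mask = NULL) {
  assert_that(length(map_a) == length(map_b), "maps must have equal length")
  if (!is.null(mask)) { map_a <- map_a[mask]; map_b <- map_b[mask] }
  if (pop_sd(map_a) == 0 || pop_sd(map_b) == 0)
    stop("correlation undefined for a constant map")
  cor(map_a, map_b)
}

# All-pairs correlation matrix: templates in rows, components in columns.
cross_correlations <- function(templates, estimated) {
  cor(t(templates), t(estimated))
}

as_map_matrix <- function(x) {
  if (inherits(x, "feature_map_set")) x$maps else as.matrix(x)
}

#' Match estimated components to templates
#'
#' Finds an injective assignment template -> component maximising absolute
#' correlation, overcoming the arbitrary order and sign of ICA components.
#' The default greedy strategy repeatedly takes the largest remaining |r|;
#' \code{method = "optimal"} searches all assignments (feasible for up to ~9
#' templates) maximising the total |r|.
#'
#' @param estimated,templates k x V matrices or \code{feature_map_set}s.
#' @param method "greedy" (default) or "optimal".
#' @return a \code{match_result}: list with \code{assignment} (component index
#'   per template, NA if unmatched), \code{correlations} (signed r of each
#'   matched pair), \code{unmatched_templates}, \code{unmatched_components}.
#' @export
match_components <- function(estimated, templates,
                             method = c("greedy", "optimal")) {
  method <- match.arg(method)
  est <- as_map_matrix(estimated)
  tem <- as_map_matrix(templates)
  assert_that(nrow(est) > 0 && nrow(tem) > 0, "empty input")
  assert_that(ncol(est) == ncol(tem), "voxel dimension mismatch")
  C <- cross_correlations(tem, est)
  nt <- nrow(C); ne <- ncol(C)
  assignment <- rep(NA_integer_, nt)
  if (method == "greedy") {
    A <- abs(C)
    for (step in seq_len(min(nt, ne))) {
      best <- arrayInd(which.max(A), dim(A))
      assignment[best[1]] <- best[2]
      A[best[1], ] <- -Inf
      A[, best[2]] <- -Inf
    }
  } else {
    if (nt > 9) stop("optimal matching supported for up to 9 templates")
    best_perm <- NULL; best_val <- -Inf
    comb <- utils::combn(ne, min(nt, ne), simplify = FALSE)
    for (cols in comb) {
      perms <- all_permutations(cols)
      for (p in perms) {
        rows <- seq_len(length(p))
        val <- sum(abs(C[cbind(rows, p)]))
        if (val > best_val) { best_val <- val; best_perm <- p }
      }
    }
    assignment[seq_along(best_perm)] <- best_perm
  }
  correlations <- ifelse(is.na(assignment), NA_real_,
                         C[cbind(seq_len(nt), assignment)])
  structure(list(assignment = assignment, correlations = correlations,
                 unmatched_templates = which(is.na(assignment)),
                 unmatched_components = setdiff(seq_len(ne),
                                                assignment[!is.na(assignment)])),
            class = "match_result")
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(all_permutations(x[-i]), function(p) c(x[i], p)))
  out
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %d matched (|r| %.3f..%.3f), %d unmatched template(s)>\n",
              sum(!is.na(x$assignment)),
              min(abs(x$correlations), na.rm = TRUE),
              max(abs(x$correlations), na.rm = TRUE),
              length(x$unmatched_templates)))
  invisible(x)
}

#' Ground-truth recovery report
#'
#' Matches estimated components to the known true sources and reports the
#' per-source correlation (absolute value of the matched r, since component
#' signs are arbitrary) with its mean and standard deviation.
#'
#' @param estimated,truth k x V matrices or \code{feature_map_set}s; rows of
#'   \code{truth} are the ground-truth sources.
#' @param ... passed to \code{\link{match_components}}.
#' @return list with \code{per_source} (|r| per true source), \code{mean},
#'   \code{sd}, \code{match} (the full \code{match_result}).
#' @export
recovery_report <- function(estimated, truth, ...) {
  m <- match_components(estimated, truth, ...)
  r <- abs(m$correlations)
  list(per_source = r, mean = mean(r, na.rm = TRUE),
       sd = sd(r[!is.na(r)]), match = m)
}

#' Two-sample contrast of correlation groups
#'
#' Welch two-sample t-test (two-sided) comparing e.g. across-session vs
#' across-subject correlation values.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return list with \code{t}, \code{p}, \code{mean_a}, \code{mean_b},
#'   \code{df}.
#' @export
contrast_ttest <- function(group_a, group_b, var_equal = FALSE) {
  assert_that(length(group_a) >= 2 && length(group_b) >= 2,
              "each group needs at least 2 values")
  if (sd(group_a) == 0 && sd(group_b) == 0)
    stop("degenerate groups: both have zero variance")
  ht <- t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_a = mean(group_a), mean_b = mean(group_b),
       df = unname(ht$parameter))
}
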