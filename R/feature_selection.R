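#' Feature-selection parameters
#'
#' A domain is class-associated when it is present in at least
#' `presence_threshold` of the class members, its in-class frequency exceeds
#' the pooled frequency in all other classes, and a two-tailed independent
#' t-test of the 0/1 indicators (class vs pooled rest) gives
#' `p < alpha`. No multiple-testing correction is applied.
#'
#' @param presence_threshold Minimum in-class presence fraction (default
#'   0.65).
#' @param alpha Two-tailed significance level (default 0.05).
#' @param var_equal Use the pooled-variance Student's t (default, the
#'   classical "independent t-test"); `FALSE` switches to Welch.
#' @return An object of class `"selection_params"`.
#' @export
selection_params <- function(presence_threshold = 0.65, alpha = 0.05,
                             var_equal = TRUE) {
  stopifnot(presence_threshold > 0, presence_threshold <= 1,
            alpha > 0, alpha < 1, is.logical(var_equal))
  structure(list(presence_threshold = presence_threshold, alpha = alpha,
                 var_equal = var_equal), class = "selection_params")
}

#' Per-class presence frequencies of every domain
#'
#' @param matrix Presence matrix (genomes x domains).
#' @param labels Named character vector of base class labels.
#' @param scheme A [class_scheme()]; genomes excluded by the scheme are
#'   dropped before counting.
#' @return Numeric matrix, domains x task classes:
#'   `frequency(d, C)` = (genomes of class C with d present) / (genomes of
#'   class C).
#' @export
class_frequencies <- function(matrix, labels, scheme = scheme_three_class()) {
  cc <- class_counts(matrix, labels, scheme)
  sweep(cc$counts, 2L, cc$n, "/")
}

# Per-class presence counts; shared by selection and the LOOCV fold updates.
class_counts <- function(matrix, labels, scheme) {
  matrix <- suppressWarnings(validate_presence_matrix(matrix))
  task <- apply_scheme(labels, scheme)
  keep <- intersect(rownames(matrix), names(task))
  unlabeled <- setdiff(rownames(matrix), names(labels))
  if (length(unlabeled))
    stop("genome(s) without a label: ", paste(unlabeled, collapse = ", "),
         call. = FALSE)
  m <- matrix[keep, , drop = FALSE]
  task <- task[keep]
  n <- vapply(scheme$classes, function(cl) sum(task == cl), integer(1L))
  if (any(n == 0L))
    stop("empty class: ", paste(scheme$classes[n == 0L], collapse = ", "),
         call. = FALSE)
  ind <- outer(task, scheme$classes, "==") + 0L
  counts <- crossprod(m, ind)           # domains x classes
  dimnames(counts) <- list(colnames(m), scheme$classes)
  list(counts = counts, n = n, task = task, matrix = m)
}

#' Two-sample t-test on binary indicator samples
#'
#' Student's (pooled-variance) or Welch two-sample t-test applied to two
#' groups of 0/1 observations summarised by their presence counts. Sample
#' variances use the n-1 denominator. Degenerate case: when both group
#' variances are zero the p-value is 1 if the proportions are equal and 0
#' otherwise. Vectorised over counts.
#'
#' @param count_x,count_y Number of 1s in each group.
#' @param n_x,n_y Group sizes (each >= 2).
#' @param var_equal Pooled-variance Student's t if `TRUE` (default), Welch
#'   otherwise.
#' @return A list with vectors `t` (statistic), `df` and `p` (two-tailed
#'   p-value).
#' @export
binary_t_test <- function(count_x, n_x, count_y, n_y, var_equal = TRUE) {
  stopifnot(all(n_x >= 2L), all(n_y >= 2L),
            all(count_x >= 0L & count_x <= n_x),
            all(count_y >= 0L & count_y <= n_y))
  px <- count_x / n_x
  py <- count_y / n_y
  # for 0/1 data: sum(x) = sum(x^2) = count, so s^2 = c(1 - c/n)/(n-1)
  vx <- count_x * (1 - px) / (n_x - 1)
  vy <- count_y * (1 - py) / (n_y - 1)
  if (var_equal) {
    df <- n_x + n_y - 2
    s2 <- ((n_x - 1) * vx + (n_y - 1) * vy) / df
    se <- sqrt(s2 * (1 / n_x + 1 / n_y))
  } else {
    se <- sqrt(vx / n_x + vy / n_y)
    df <- (vx / n_x + vy / n_y)^2 /
      ((vx / n_x)^2 / (n_x - 1) + (vy / n_y)^2 / (n_y - 1))
  }
  t <- (px - py) / se
  p <- 2 * stats::pt(-abs(t), df)
  zero <- !is.finite(t) | se == 0
  if (any(zero)) {
    t[zero] <- ifelse(px[zero] == py[zero], 0, sign(px - py)[zero] * Inf)
    p[zero] <- ifelse(px[zero] == py[zero], 1, 0)
  }
  list(t = as.numeric(t), df = as.numeric(df), p = as.numeric(p))
}

#' Select class-associated domains and build the likelihood table
#'
#' Identifies, for each task class, the domains overrepresented in that
#' class (see [selection_params()]) and records `p(domain present | class)`
#' for every task class — the trained model ("likelihood file"). A domain
#' that passes for more than one class (possible only with >= 3 task
#' classes) is assigned the class with the highest in-class frequency,
#' breaking ties by smaller p-value then canonical class order.
#'
#' @inheritParams class_frequencies
#' @param params A [selection_params()].
#' @return A `likelihood_table` (possibly empty, with a warning) carrying
#'   `t_stat` and `p_value` of the associated class's test.
#' @export
select_class_associated_domains <- function(matrix, labels,
                                            scheme = scheme_three_class(),
                                            params = selection_params()) {
  cc <- class_counts(matrix, labels, scheme)
  if (any(cc$n < 2L))
    stop("every task class needs >= 2 members; got ",
         paste(scheme$classes, cc$n, sep = "=", collapse = ", "),
         call. = FALSE)
  tab <- select_from_counts(cc$counts, cc$n, scheme$classes, params)
  if (!nrow(tab))
    warning("no class-associated domain passed selection", call. = FALSE)
  tab
}

# Vectorised selection from a domains x classes count matrix.
select_from_counts <- function(counts, n, classes, params) {
  freq <- sweep(counts, 2L, n, "/")
  K <- length(classes)
  pass <- tmat <- pmat <- matrix(NA_real_, nrow(counts), K)
  for (k in seq_len(K)) {
    rest_count <- rowSums(counts[, -k, drop = FALSE])
    rest_n <- sum(n[-k])
    tt <- binary_t_test(counts[, k], n[k], rest_count, rest_n,
                        var_equal = params$var_equal)
    tmat[, k] <- tt$t
    pmat[, k] <- tt$p
    pass[, k] <- (freq[, k] >= params$presence_threshold) &
      (tt$p < params$alpha) &
      (freq[, k] > rest_count / rest_n)
  }
  hit <- which(rowSums(pass) > 0)
  assoc <- integer(length(hit))
  for (i in seq_along(hit)) {
    d <- hit[i]
    cand <- which(pass[d, ] > 0)
    if (length(cand) > 1L)
      cand <- cand[order(-freq[d, cand], pmat[d, cand])]
    assoc[i] <- cand[1L]
  }
  df <- data.frame(domain_id = rownames(counts)[hit],
                   associated_class = classes[assoc],
                   stringsAsFactors = FALSE)
  for (k in seq_len(K)) df[[classes[k]]] <- freq[hit, k]
  df$t_stat <- tmat[cbind(hit, assoc)]
  df$p_value <- pmat[cbind(hit, assoc)]
  ord <- order(match(df$associated_class, classes), df$domain_id)
  new_likelihood_table(df[ord, , drop = FALSE], classes)
}
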