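#' Leave-one-out cross-validated prediction
#'
#' Every genome is predicted by a model trained on all other genomes
#' (N-fold cross-validation with N = number of genomes). By default both
#' feature selection and the likelihood frequencies are recomputed inside
#' every fold, so the held-out genome contributes nothing to its own model;
#' `per_fold_selection = FALSE` is a faster variant that fixes the selected
#' domain set on the full data and only refits the per-fold likelihoods.
#'
#' `predict_loocv()` runs a single-stage predictor under an arbitrary
#' [class_scheme()]; `predict_one_step_loocv()` is the flat three-class
#' network and `predict_two_step_loocv()` the nested dichotomy (step 1:
#' respiring vs anaerobe trained on all genomes; step 2: aerobe vs
#' facultative trained on the truly respiring genomes only). A genome
#' predicted anaerobe at step 1 is final and receives no step-2 posterior;
#' genomes predicted respiring — including mispredicted true anaerobes —
#' are classified by the step-2 model.
#'
#' @param matrix Presence matrix (genomes x domains).
#' @param labels Named base-class labels covering the matrix rows.
#' @param scheme A [class_scheme()]; genomes excluded by the scheme are not
#'   predicted (and not trained on).
#' @param params A [bayes_params()].
#' @param selection A [selection_params()].
#' @param per_fold_selection Recompute feature selection in every fold
#'   (default `TRUE`, the strict reading of cross-validation).
#' @return A `prediction_run` data frame, one row per predicted genome,
#'   with the true (task) label, per-class posteriors, the predicted class,
#'   a tie flag and the number of model domains in the fold. Two-step runs
#'   carry both stages' posteriors (`step2_*` is `NA` for genomes decided
#'   anaerobe at step 1).
#' @export
predict_loocv <- function(matrix, labels, scheme = scheme_three_class(),
                          params = bayes_params(),
                          selection = selection_params(),
                          per_fold_selection = TRUE) {
  run <- loocv_stage(matrix, labels, scheme, params, selection,
                     per_fold_selection)
  structure(run, mode = "single-stage", scheme = scheme,
            class = c("prediction_run", "data.frame"))
}

#' @rdname predict_loocv
#' @export
predict_one_step_loocv <- function(matrix, labels, params = bayes_params(),
                                   selection = selection_params(),
                                   per_fold_selection = TRUE) {
  run <- loocv_stage(matrix, labels, scheme_three_class(), params, selection,
                     per_fold_selection)
  structure(run, mode = "one-step", scheme = scheme_three_class(),
            class = c("prediction_run", "data.frame"))
}

#' @rdname predict_loocv
#' @export
predict_two_step_loocv <- function(matrix, labels, params = bayes_params(),
                                   selection = selection_params(),
                                   per_fold_selection = TRUE) {
  s1 <- loocv_stage(matrix, labels, scheme_respiration(), params, selection,
                    per_fold_selection)
  # step 2 trains on the truly respiring genomes only
  sch2 <- scheme_aerobe_facultative()
  respiring <- names(labels)[labels %in% c("aerobe", "facultative")]
  m2 <- matrix[intersect(rownames(matrix), respiring), , drop = FALSE]
  need2 <- s1$genome_id[s1$predicted == "respiring"]
  s2 <- loocv_stage(m2, labels, sch2, params, selection, per_fold_selection,
                    predict_ids = intersect(need2, rownames(m2)))
  # true anaerobes mispredicted respiring: classify with the full step-2
  # model (they are never in its training set)
  extra <- setdiff(need2, rownames(m2))
  if (length(extra)) {
    tab2 <- select_class_associated_domains(m2, labels, sch2, selection)
    X <- matrix[extra, tab2$domain_id, drop = FALSE]
    post <- posterior_matrix(X, tab2, params)
    s2 <- rbind(s2, stage_rows(extra, rep(NA_character_, length(extra)),
                               post, nrow(tab2)))
  }
  out <- data.frame(genome_id = s1$genome_id,
                    true = labels[s1$genome_id],
                    step1_p_respiring = s1$p_respiring,
                    step1_p_anaerobe = s1$p_anaerobe,
                    step1_predicted = s1$predicted,
                    step1_tie = s1$tie,
                    step2_p_aerobe = NA_real_,
                    step2_p_facultative = NA_real_,
                    predicted = NA_character_,
                    tie = s1$tie,
                    stringsAsFactors = FALSE, row.names = NULL)
  anaerobic <- out$step1_predicted == "anaerobe"
  out$predicted[anaerobic] <- "anaerobe"
  i2 <- match(out$genome_id, s2$genome_id)
  hit <- !anaerobic & !is.na(i2)
  out$step2_p_aerobe[hit] <- s2$p_aerobe[i2[hit]]
  out$step2_p_facultative[hit] <- s2$p_facultative[i2[hit]]
  out$predicted[hit] <- s2$predicted[i2[hit]]
  out$tie[hit] <- s2$tie[i2[hit]]
  structure(out, mode = "two-step",
            class = c("prediction_run", "data.frame"))
}

# Single-stage LOOCV under a scheme. predict_ids limits which genomes are
# scored (they must belong to the task); training always leaves out the
# scored genome when it is part of the task.
loocv_stage <- function(matrix, labels, scheme, params, selection,
                        per_fold_selection = TRUE, predict_ids = NULL) {
  cc <- class_counts(matrix, labels, scheme)
  m <- cc$matrix
  task <- cc$task
  classes <- scheme$classes
  ids <- if (is.null(predict_ids)) rownames(m)
         else intersect(predict_ids, rownames(m))
  if (!length(ids))
    return(stage_rows(character(0L), character(0L),
                      matrix(numeric(0L), 0L, length(classes),
                             dimnames = list(NULL, classes)), 0L))
  global_domains <- if (!per_fold_selection)
    suppressWarnings(select_from_counts(cc$counts, cc$n, classes,
                                        selection))$domain_id
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- ids[i]
    k <- match(task[[g]], classes)
    counts <- cc$counts
    n <- cc$n
    counts[, k] <- counts[, k] - m[g, ]
    n[k] <- n[k] - 1L
    if (any(n < 2L))
      stop("fold for genome ", g, " leaves class ",
           classes[which.min(n)], " with < 2 members", call. = FALSE)
    tab <- suppressWarnings(select_from_counts(counts, n, classes,
                                               selection))
    if (!per_fold_selection)
      tab <- restrict_table(tab, global_domains)
    X <- m[g, tab$domain_id, drop = FALSE]
    post <- posterior_matrix(X, tab, params)
    rows[[i]] <- stage_rows(g, task[[g]], post, nrow(tab))
  }
  do.call(rbind, rows)
}

# data-frame subsetting drops the classes attribute; keep it
restrict_table <- function(tab, domains) {
  classes <- attr(tab, "classes")
  out <- tab[tab$domain_id %in% domains, , drop = FALSE]
  new_likelihood_table(as.data.frame(out), classes)
}

stage_rows <- function(ids, true, post, n_domains) {
  df <- data.frame(genome_id = ids, true = true,
                   stringsAsFactors = FALSE, row.names = NULL)
  for (cl in colnames(post)) df[[paste0("p_", cl)]] <- post[, cl]
  dec <- lapply(seq_len(nrow(post)), function(i) decide(post[i, ]))
  df$predicted <- vapply(dec, `[[`, character(1L), "predicted")
  df$tie <- vapply(dec, `[[`, logical(1L), "tie")
  df$n_domains <- n_domains
  df
}

#' @export
print.prediction_run <- function(x, ...) {
  cat("<prediction_run> mode: ", attr(x, "mode"), ", ", nrow(x),
      " genome(s), ", sum(x$true == x$predicted, na.rm = TRUE),
      " predicted correctly\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4L)
  invisible(x)
}

#' Write per-genome predictions as TSV
#'
#' @param run A `prediction_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(run, path) {
  utils::write.table(as.data.frame(run), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
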