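#' Naive-Bayes parameters
#'
#' @param pseudo_count Probability floor applied to every per-domain
#'   likelihood (default 0.1): each likelihood is clamped into
#'   `[pseudo_count, 1 - pseudo_count]` so no single observation can zero a
#'   class posterior. `0` disables the floor.
#' @param prior Named per-task-class prior probabilities, summing to 1;
#'   `NULL` (default) means the flat prior `1/N_classes`.
#' @param pc_mode `"clamp"` (default) applies the floor as a clamp;
#'   `"add"` instead adds the pseudo-count to each likelihood factor
#'   (sensitivity-analysis variant).
#' @return An object of class `"bayes_params"`.
#' @export
bayes_params <- function(pseudo_count = 0.1, prior = NULL,
                         pc_mode = c("clamp", "add")) {
  stopifnot(pseudo_count >= 0, pseudo_count < 0.5)
  pc_mode <- match.arg(pc_mode)
  if (!is.null(prior)) {
    stopifnot(is.numeric(prior), !is.null(names(prior)), all(prior >= 0),
              abs(sum(prior) - 1) < 1e-9)
  }
  structure(list(pseudo_count = pseudo_count, prior = prior,
                 pc_mode = pc_mode), class = "bayes_params")
}

# Log-likelihood factors for presence and absence, domains x classes.
likelihood_factors <- function(P, params) {
  pc <- params$pseudo_count
  if (params$pc_mode == "add") {
    lp <- P + pc
    la <- (1 - P) + pc
  } else {
    lp <- pmin(pmax(P, pc), 1 - pc)
    la <- pmin(pmax(1 - P, pc), 1 - pc)
  }
  list(log_present = log(lp), log_absent = log(la))
}

prior_vector <- function(params, classes) {
  if (is.null(params$prior))
    return(stats::setNames(rep(1 / length(classes), length(classes)),
                           classes))
  missing <- setdiff(classes, names(params$prior))
  if (length(missing))
    stop("prior lacks class(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  params$prior[classes]
}

# Normalised posteriors for a batch of profiles.
# X: genomes x domains 0/1 over exactly the table's domains (same order);
# returns genomes x classes matrix of posteriors summing to 1 per row.
posterior_matrix <- function(X, table, params) {
  classes <- attr(table, "classes")
  prior <- prior_vector(params, classes)
  if (nrow(table) == 0L) {
    post <- matrix(rep(prior, each = nrow(X)), nrow = nrow(X),
                   dimnames = list(rownames(X), classes))
    return(post / rowSums(post))
  }
  P <- likelihoods(table)
  lf <- likelihood_factors(P, params)
  ls <- X %*% lf$log_present + (1 - X) %*% lf$log_absent
  ls <- sweep(ls, 2L, log(prior), "+")
  mx <- apply(ls, 1L, max)
  mx[!is.finite(mx)] <- 0              # all-(-Inf) row: fall back to flat
  w <- exp(ls - mx)
  post <- w / rowSums(w)
  dimnames(post) <- list(rownames(X), classes)
  post
}

# Expand a profile (character vector of present accessions, or a named
# 0/1/logical vector) into a 1 x D matrix over the table's domains.
profile_row <- function(profile, domains, genome_id = "query") {
  x <- matrix(0, nrow = 1L, ncol = length(domains),
              dimnames = list(genome_id, domains))
  if (is.character(profile)) {
    x[1L, intersect(domains, profile)] <- 1
  } else if (is.numeric(profile) || is.logical(profile)) {
    if (is.null(names(profile)))
      stop("numeric/logical profiles must be named by domain accession",
           call. = FALSE)
    hit <- intersect(domains, names(profile))
    x[1L, hit] <- as.numeric(profile[hit] > 0)
  } else {
    stop("profile must be a character vector of present accessions ",
         "or a named 0/1 vector", call. = FALSE)
  }
  x
}

decide <- function(post, tol = 1e-9) {
  top <- max(post)
  winners <- which(post >= top - tol)
  list(predicted = names(post)[winners[1L]], tie = length(winners) > 1L)
}

#' Posterior class probabilities of one domain profile
#'
#' Computes the naive-Bayes posterior over the table's task classes: for
#' each class C, `prior(C)` times the product over the table's domains of
#' the (pseudo-count-floored) likelihood of the observed presence or
#' absence, normalised across classes. Computation is in log space. Domains
#' in the profile but not in the table carry no information and are
#' ignored; an empty table returns the prior with a warning.
#'
#' @param profile Character vector of present Pfam accessions (as from
#'   [parse_hmmscan_table()]), or a named 0/1 vector over domains.
#' @param table A `likelihood_table`.
#' @param params A [bayes_params()].
#' @return A `posterior_result`: list with `posterior` (named, sums to 1),
#'   `predicted` (argmax class; ties broken towards the earlier class) and
#'   `tie` flag.
#' @export
posterior <- function(profile, table, params = bayes_params()) {
  stopifnot(inherits(table, "likelihood_table"))
  if (nrow(table) == 0L)
    warning("empty likelihood table: posterior equals the prior",
            call. = FALSE)
  X <- profile_row(profile, table$domain_id)
  post <- posterior_matrix(X, table, params)[1L, ]
  d <- decide(post)
  structure(list(posterior = post, predicted = d$predicted, tie = d$tie),
            class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, ...) {
  cat("<posterior_result> predicted: ", x$predicted,
      if (x$tie) " (tie)", "\n", sep = "")
  print(round(x$posterior, 4L))
  invisible(x)
}

#' Train an oxygen-requirement model
#'
#' Builds the likelihood file(s) for one of the three prediction networks:
#' `"one-step"` (a single three-class model), `"two-step"` (step 1:
#' respiring vs anaerobe on all genomes; step 2: aerobe vs facultative on
#' the respiring genomes only) or `"aa-only"` (aerobe vs anaerobe with
#' facultative genomes excluded — the literature comparison mode).
#'
#' @param matrix Presence matrix (genomes x domains).
#' @param labels Named base-class labels covering the matrix rows.
#' @param mode `"one-step"`, `"two-step"` or `"aa-only"`.
#' @param selection A [selection_params()].
#' @param params A [bayes_params()].
#' @return An `oxy_model`: list with `mode`, `tables` (one or two
#'   `likelihood_table`s) and `params`.
#' @export
train <- function(matrix, labels, mode = c("two-step", "one-step", "aa-only"),
                  selection = selection_params(), params = bayes_params()) {
  mode <- match.arg(mode)
  tables <- switch(mode,
    "one-step" = list(
      main = select_class_associated_domains(matrix, labels,
                                             scheme_three_class(),
                                             selection)),
    "aa-only" = list(
      main = select_class_associated_domains(matrix, labels, scheme_aa_only(),
                                             selection)),
    "two-step" = {
      step2_genomes <- names(labels)[labels %in% c("aerobe", "facultative")]
      m2 <- matrix[intersect(rownames(matrix), step2_genomes), ,
                   drop = FALSE]
      list(step1 = select_class_associated_domains(matrix, labels,
                                                   scheme_respiration(),
                                                   selection),
           step2 = select_class_associated_domains(m2, labels,
                                                   scheme_aerobe_facultative(),
                                                   selection))
    })
  structure(list(mode = mode, tables = tables, params = params),
            class = "oxy_model")
}

#' @export
print.oxy_model <- function(x, ...) {
  cat("<oxy_model> mode: ", x$mode, "\n", sep = "")
  for (nm in names(x$tables))
    cat("  ", nm, ": ", nrow(x$tables[[nm]]), " domain(s)\n", sep = "")
  invisible(x)
}

#' Classify a domain profile with a trained model
#'
#' Applies [posterior()] under the model's network. In two-step mode the
#' profile is first scored respiring-vs-anaerobe; a profile predicted
#' anaerobe stops there, otherwise the step-2 aerobe-vs-facultative model
#' decides the final class.
#'
#' @param profile As in [posterior()].
#' @param model An `oxy_model` from [train()], or a list of one/two
#'   `likelihood_table`s with matching names.
#' @return A `posterior_result` whose `posterior` is the final decision
#'   stage's; for two-step predictions the step-1 result is attached as
#'   `$step1`.
#' @export
classify <- function(profile, model) {
  stopifnot(inherits(model, "oxy_model"))
  params <- model$params
  if (model$mode != "two-step")
    return(posterior(profile, model$tables$main, params))
  if (is.null(model$tables$step2))
    stop("two-step model lacks a step-2 table", call. = FALSE)
  s1 <- suppressWarnings(posterior(profile, model$tables$step1, params))
  if (s1$predicted == "anaerobe") {
    out <- s1
    out$step1 <- s1
    return(out)
  }
  s2 <- suppressWarnings(posterior(profile, model$tables$step2, params))
  s2$step1 <- s1
  s2
}

#' Save / load a trained model as plain text
#'
#' A model is serialised as one likelihood-file TSV per step plus a small
#' key=value config recording the mode, pseudo-count and prior.
#'
#' @param model An `oxy_model`.
#' @param dir Directory to write into (created if needed).
#' @return `dir` (write) or an `oxy_model` (read), invisibly for write.
#' @export
write_model <- function(model, dir) {
  stopifnot(inherits(model, "oxy_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(model$tables))
    write_likelihood_table(model$tables[[nm]],
                           file.path(dir, paste0(nm, ".tsv")))
  prior <- model$params$prior
  cfg <- c(paste0("mode=", model$mode),
           paste0("pseudo_count=", format(model$params$pseudo_count)),
           paste0("pc_mode=", model$params$pc_mode),
           if (!is.null(prior))
             paste0("prior=", paste(names(prior), format(prior), sep = ":",
                                    collapse = ",")))
  writeLines(cfg, file.path(dir, "model.cfg"))
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  cfg_path <- file.path(dir, "model.cfg")
  if (!file.exists(cfg_path))
    stop("not a model directory (missing model.cfg): ", dir, call. = FALSE)
  cfg <- strsplit(readLines(cfg_path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(cfg, `[`, character(1L), 2L),
                          vapply(cfg, `[`, character(1L), 1L))
  prior <- NULL
  if (!is.na(vals["prior"])) {
    parts <- strsplit(strsplit(vals[["prior"]], ",")[[1L]], ":")
    prior <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                             vapply(parts, `[`, "", 1L))
  }
  params <- bayes_params(pseudo_count = as.numeric(vals[["pseudo_count"]]),
                         prior = prior, pc_mode = vals[["pc_mode"]])
  table_names <- if (vals[["mode"]] == "two-step") c("step1", "step2")
                 else "main"
  tables <- lapply(stats::setNames(nm = table_names), function(nm)
    read_likelihood_table(file.path(dir, paste0(nm, ".tsv"))))
  structure(list(mode = vals[["mode"]], tables = tables, params = params),
            class = "oxy_model")
}
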