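#' Specification of a synthetic presence/absence world
#'
#' Describes a class-conditional Bernoulli matrix matching the classifier's
#' generative assumptions: each class owns a block of associated domains
#' present with probability `p_in` inside the class and `p_out` outside,
#' plus uninformative background domains present everywhere with
#' probability `p_bg`. All cells are drawn independently.
#'
#' Two optional departures from independence probe realism: `p_fac_share`
#' raises the facultative-class presence probability on the
#' aerobe-associated block to an intermediate value, mimicking the
#' aerobe/facultative confusion seen in real genomes (both classes respire);
#' `n_duplicate` appends exact copies of the first associated domains of
#' each class (perfectly correlated features, violating naive-Bayes
#' independence).
#'
#' @param class_sizes Named integer vector of genomes per class; names must
#'   be base classes. Default 30 per class; the paper-scale configuration is
#'   `c(aerobe = 175, anaerobe = 112, facultative = 91)`.
#' @param n_associated Associated domains per class (default 40).
#' @param p_in,p_out Presence probability of an associated domain inside /
#'   outside its class (defaults 0.95 / 0.05).
#' @param n_background Background domains (default 100).
#' @param p_bg Background presence probability (default 0.5).
#' @param p_fac_share `NULL` (default) or the facultative-class presence
#'   probability on aerobe-associated domains.
#' @param n_duplicate Perfect copies appended per class (default 0).
#' @param seed Integer seed; identical spec => identical matrix.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(class_sizes = c(aerobe = 30L, anaerobe = 30L,
                                           facultative = 30L),
                           n_associated = 40L, p_in = 0.95, p_out = 0.05,
                           n_background = 100L, p_bg = 0.5,
                           p_fac_share = NULL, n_duplicate = 0L,
                           seed = 1L) {
  if (is.null(names(class_sizes)) ||
      !all(names(class_sizes) %in% oxy_classes()))
    stop("class_sizes must be named by base classes", call. = FALSE)
  if (any(class_sizes < 1L))
    stop("every class needs at least one genome", call. = FALSE)
  probs <- c(p_in, p_out, p_bg, p_fac_share)
  stopifnot(all(probs >= 0 & probs <= 1), n_associated >= 1L,
            n_background >= 0L, n_duplicate >= 0L,
            n_duplicate <= n_associated)
  structure(list(class_sizes = class_sizes, n_associated = n_associated,
                 p_in = p_in, p_out = p_out, n_background = n_background,
                 p_bg = p_bg, p_fac_share = p_fac_share,
                 n_duplicate = n_duplicate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labeled synthetic presence/absence matrix
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrix` (presence matrix; genome ids `g0001`...,
#'   associated domains `PFSYN####`, background `PFBG####`, duplicates
#'   `PFDUP####`), `labels` (named base-class labels) and `truth`
#'   (data frame mapping each associated domain to its planted class).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  classes <- names(spec$class_sizes)
  n_genomes <- sum(spec$class_sizes)
  labels <- rep(classes, spec$class_sizes)
  ids <- sprintf("g%04d", seq_len(n_genomes))
  names(labels) <- ids

  n_assoc_total <- spec$n_associated * length(classes)
  assoc_ids <- sprintf("PFSYN%04d", seq_len(n_assoc_total))
  assoc_class <- rep(classes, each = spec$n_associated)
  bg_ids <- if (spec$n_background > 0L)
    sprintf("PFBG%04d", seq_len(spec$n_background)) else character(0L)

  # presence probability per (genome, domain): class-conditional Bernoulli
  P <- matrix(spec$p_out, nrow = n_genomes, ncol = n_assoc_total)
  for (k in seq_along(classes))
    P[labels == classes[k], assoc_class == classes[k]] <- spec$p_in
  if (!is.null(spec$p_fac_share) && all(c("aerobe", "facultative") %in%
                                        classes))
    P[labels == "facultative", assoc_class == "aerobe"] <- spec$p_fac_share

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  m <- matrix(stats::rbinom(length(P), 1L, P), nrow = n_genomes)
  if (spec$n_background > 0L)
    m <- cbind(m, matrix(stats::rbinom(n_genomes * spec$n_background, 1L,
                                       spec$p_bg), nrow = n_genomes))
  colnames(m) <- c(assoc_ids, bg_ids)
  rownames(m) <- ids
  truth <- data.frame(domain_id = assoc_ids, class = assoc_class,
                      stringsAsFactors = FALSE)
  if (spec$n_duplicate > 0L) {
    src <- unlist(lapply(classes, function(cl)
      truth$domain_id[truth$class == cl][seq_len(spec$n_duplicate)]))
    dup <- m[, src, drop = FALSE]
    colnames(dup) <- sprintf("PFDUP%04d", seq_along(src))
    m <- cbind(m, dup)
  }
  storage.mode(m) <- "integer"
  list(matrix = suppressWarnings(validate_presence_matrix(m)),
       labels = labels, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
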