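#' Canonical oxygen-requirement class labels
#'
#' The three base classes, in canonical order. All multi-class outputs
#' (likelihood tables, confusion tables, posterior columns) follow this
#' order, and ties in posterior probability are broken towards the earlier
#' class.
#'
#' @return Character vector `c("aerobe", "anaerobe", "facultative")`.
#' @export
oxy_classes <- function() c("aerobe", "anaerobe", "facultative")

#' Define a classification task over the base oxygen classes
#'
#' A class scheme names the ordered task classes and, optionally, how the
#' three base labels map onto them. Base labels mapped to `NA` are excluded
#' from the task (e.g. facultative genomes in the aerobe-vs-anaerobe
#' comparison mode).
#'
#' @param classes Ordered character vector of task class names (>= 2).
#' @param merge Named character vector mapping every base label
#'   (`oxy_classes()`) to a task class or `NA_character_`. `NULL` means the
#'   identity map restricted to `classes`: base labels among `classes` map to
#'   themselves, others to `NA`.
#' @return An object of class `"class_scheme"`.
#' @seealso [scheme_three_class()], [scheme_respiration()],
#'   [scheme_aerobe_facultative()], [scheme_aa_only()]
#' @export
class_scheme <- function(classes, merge = NULL) {
  classes <- as.character(classes)
  if (length(classes) < 2L || anyDuplicated(classes))
    stop("a class scheme needs >= 2 distinct task classes", call. = FALSE)
  base <- oxy_classes()
  if (is.null(merge)) {
    merge <- ifelse(base %in% classes, base, NA_character_)
    names(merge) <- base
  }
  if (!setequal(names(merge), base))
    stop("merge rule must be total over the base labels: ",
         paste(base, collapse = ", "), call. = FALSE)
  merge <- merge[base]
  bad <- !is.na(merge) & !(merge %in% classes)
  if (any(bad))
    stop("merge rule maps to unknown task class: ",
         paste(unique(merge[bad]), collapse = ", "), call. = FALSE)
  structure(list(classes = classes, merge = merge), class = "class_scheme")
}

#' @describeIn class_scheme The flat three-class task
#'   (aerobe / anaerobe / facultative), used by the one-step network.
#' @export
scheme_three_class <- function() class_scheme(oxy_classes())

#' @describeIn class_scheme Step 1 of the two-step network: respiring
#'   (aerobe + facultative) vs anaerobe.
#' @export
scheme_respiration <- function() {
  class_scheme(c("respiring", "anaerobe"),
               merge = c(aerobe = "respiring", anaerobe = "anaerobe",
                         facultative = "respiring"))
}

#' @describeIn class_scheme Step 2 of the two-step network: aerobe vs
#'   facultative, anaerobes excluded.
#' @export
scheme_aerobe_facultative <- function() {
  class_scheme(c("aerobe", "facultative"),
               merge = c(aerobe = "aerobe", anaerobe = NA_character_,
                         facultative = "facultative"))
}

#' @describeIn class_scheme The aerobe-vs-anaerobe comparison task with
#'   facultative genomes excluded (literature comparison mode).
#' @export
scheme_aa_only <- function() {
  class_scheme(c("aerobe", "anaerobe"),
               merge = c(aerobe = "aerobe", anaerobe = "anaerobe",
                         facultative = NA_character_))
}

#' Map base genome labels onto a task's classes
#'
#' Applies the scheme's merge rule to a label map. Genomes whose base label
#' maps to `NA` (not part of the task) are dropped.
#'
#' @param labels Named character vector: genome id -> base class label.
#' @param scheme A [class_scheme()].
#' @return Named character vector of task labels, possibly shorter than the
#'   input.
#' @export
apply_scheme <- function(labels, scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  validate_labels(labels)
  task <- scheme$merge[labels]
  names(task) <- names(labels)
  task[!is.na(task)]
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("<class_scheme> ", paste(x$classes, collapse = " | "), "\n", sep = "")
  kept <- !is.na(x$merge)
  cat("  merge: ",
      paste(names(x$merge)[kept], "->", x$merge[kept], collapse = ", "),
      if (any(!kept))
        paste0(" (", paste(names(x$merge)[!kept], collapse = ", "),
               " excluded)"),
      "\n", sep = "")
  invisible(x)
}

validate_labels <- function(labels) {
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("labels must be a named vector (genome_id -> class)", call. = FALSE)
  if (anyDuplicated(names(labels)))
    stop("duplicate genome ids in labels: ",
         paste(unique(names(labels)[duplicated(names(labels))]),
               collapse = ", "), call. = FALSE)
  bad <- !(labels %in% oxy_classes())
  if (any(bad))
    stop("unknown class label(s): ", paste(unique(labels[bad]),
         collapse = ", "), "; expected one of ",
         paste(oxy_classes(), collapse = ", "), call. = FALSE)
  invisible(labels)
}
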