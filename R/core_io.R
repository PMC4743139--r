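#' Read a genome x Pfam-domain presence/absence matrix
#'
#' The matrix format is tab-separated text: a header row `genome_id` followed
#' by domain accessions, then one row per genome with 0/1 entries. Genomes
#' are rows, domains columns; row and column order is preserved.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix of 0/1 with genome ids as rownames and domain
#'   accessions as colnames.
#' @export
read_presence_matrix <- function(path) {
  lines <- read_nonempty_lines(path)
  if (length(lines) < 2L)
    stop("presence matrix file needs a header and at least one genome row: ",
         path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L)
    stop("presence matrix header must contain at least one domain column",
         call. = FALSE)
  domains <- header[-1L]
  if (anyDuplicated(domains))
    stop("duplicate domain identifier(s): ",
         paste(unique(domains[duplicated(domains)]), collapse = ", "),
         call. = FALSE)
  body <- fields[-1L]
  nf <- lengths(body)
  if (any(nf != length(header)))
    stop("ragged row(s) in presence matrix (expected ", length(header),
         " fields): line(s) ",
         paste(which(nf != length(header)) + 1L, collapse = ", "),
         call. = FALSE)
  genomes <- vapply(body, `[`, character(1L), 1L)
  if (anyDuplicated(genomes))
    stop("duplicate genome identifier(s): ",
         paste(unique(genomes[duplicated(genomes)]), collapse = ", "),
         call. = FALSE)
  cells <- matrix(unlist(body, use.names = FALSE),
                  nrow = length(body), byrow = TRUE)[, -1L, drop = FALSE]
  bad <- which(!(cells %in% c("0", "1")))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(cells)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(cells)) + 1L
    stop("non-binary value \"", cells[bad[1L]], "\" for genome ", genomes[i],
         ", domain ", domains[j], call. = FALSE)
  }
  m <- matrix(as.integer(cells), nrow = length(genomes),
              dimnames = list(genomes, domains))
  validate_presence_matrix(m)
}

#' Write a presence/absence matrix
#'
#' @param matrix Integer 0/1 matrix with genome rownames and domain colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @rdname read_presence_matrix
#' @export
write_presence_matrix <- function(matrix, path) {
  matrix <- validate_presence_matrix(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("genome_id", colnames(matrix)), collapse = "\t"), con)
  writeLines(paste(rownames(matrix),
                   apply(matrix, 1L, paste, collapse = "\t"), sep = "\t"),
             con)
  invisible(path)
}

validate_presence_matrix <- function(m) {
  if (!is.matrix(m))
    stop("presence matrix must be a matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("presence matrix needs genome rownames and domain colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("duplicate genome or domain identifiers in presence matrix",
         call. = FALSE)
  if (!all(m %in% c(0L, 1L)))
    stop("presence matrix values must be 0 or 1", call. = FALSE)
  storage.mode(m) <- "integer"
  empty <- rownames(m)[rowSums(m) == 0L]
  if (length(empty))
    warning("genome(s) with no domains present: ",
            paste(empty, collapse = ", "), call. = FALSE)
  m
}

#' Read / write genome class labels
#'
#' Labels live in a two-column TSV (`genome_id`, `class`) separate from the
#' matrix, so one matrix can serve several classification tasks.
#'
#' @param path Path to a TSV file with header `genome_id<TAB>class`.
#' @return Named character vector: genome id -> class label.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (!all(c("genome_id", "class") %in% names(df)))
    stop("label file must have columns genome_id and class: ", path,
         call. = FALSE)
  labels <- stats::setNames(df$class, df$genome_id)
  validate_labels(labels)
  labels
}

#' @param labels Named character vector as returned by [read_labels()].
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  validate_labels(labels)
  utils::write.table(
    data.frame(genome_id = names(labels), class = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse hmmscan tabular output into a set of Pfam accessions
#'
#' Accepts both the `--tblout` and `--domtblout` dialects: `#` lines are
#' comments and data fields are whitespace-delimited, with the Pfam model
#' accession (e.g. `PF00001.21`) in the second field. Version suffixes are
#' stripped so profiles are stable across Pfam releases, and repeated hits
#' collapse to a single presence call.
#'
#' @param path Path to an hmmscan tblout/domtblout file.
#' @return Character vector of unique versionless accessions, in first-seen
#'   order. Empty (with a warning) if the file has no data lines; lines whose
#'   accession field is malformed are skipped with a warning reporting the
#'   count.
#' @export
parse_hmmscan_table <- function(path) {
  lines <- read_nonempty_lines(path)
  lines <- lines[!startsWith(trimws(lines, "left"), "#")]
  if (!length(lines)) {
    warning("no data lines in hmmscan output: ", path, call. = FALSE)
    return(character(0L))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  acc <- vapply(fields, function(f)
    if (length(f) >= 2L) f[[2L]] else NA_character_, character(1L))
  ok <- !is.na(acc) & grepl("^PF\\d+(\\.\\d+)?$", acc)
  if (any(!ok))
    warning(sum(!ok), " line(s) with malformed accession field skipped in ",
            path, call. = FALSE)
  unique(sub("\\.\\d+$", "", acc[ok]))
}

#' Assemble a presence matrix from per-genome hmmscan outputs
#'
#' @param paths Named character vector of hmmscan tblout/domtblout paths; the
#'   names are used as genome ids (basenames without extension if unnamed).
#' @return Presence matrix over the union of observed accessions (sorted).
#' @export
build_presence_matrix <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  hits <- lapply(paths, parse_hmmscan_table)
  domains <- sort(unique(unlist(hits, use.names = FALSE)))
  if (!length(domains))
    stop("no Pfam accessions found in any input file", call. = FALSE)
  m <- matrix(0L, nrow = length(paths), ncol = length(domains),
              dimnames = list(names(paths), domains))
  for (g in names(paths)) m[g, hits[[g]]] <- 1L
  suppressWarnings(validate_presence_matrix(m))
}

#' Read / write a likelihood file
#'
#' The likelihood file is the trained model: one row per class-associated
#' domain with the class it is associated to and `p(domain present | class)`
#' for every task class, at full precision. Selection metadata columns
#' (`t_stat`, `p_value`) follow the likelihood columns when present.
#'
#' @param path Path to a TSV likelihood file.
#' @return A `likelihood_table`: data frame with columns `domain_id`,
#'   `associated_class`, one numeric column per task class, and optional
#'   `t_stat`/`p_value`; attribute `classes` holds the ordered task classes.
#' @export
read_likelihood_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  if (!all(c("domain_id", "associated_class") %in% names(df)[1:2]))
    stop("likelihood file must start with columns domain_id, ",
         "associated_class: ", path, call. = FALSE)
  meta <- intersect(c("t_stat", "p_value"), names(df))
  classes <- setdiff(names(df), c("domain_id", "associated_class", meta))
  new_likelihood_table(df, classes)
}

#' @param table A `likelihood_table`.
#' @rdname read_likelihood_table
#' @export
write_likelihood_table <- function(table, path) {
  stopifnot(inherits(table, "likelihood_table"))
  df <- as.data.frame(table)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_likelihood_table <- function(df, classes) {
  classes <- as.character(classes)
  if (length(classes) < 2L)
    stop("likelihood table needs >= 2 task-class columns", call. = FALSE)
  missing <- setdiff(classes, names(df))
  if (length(missing))
    stop("unknown class column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (cl in classes) {
    v <- as.numeric(df[[cl]])
    if (anyNA(v) || any(v < 0 | v > 1))
      stop("likelihood outside [0,1] in column ", cl, call. = FALSE)
    df[[cl]] <- v
  }
  if (nrow(df) && any(!(df$associated_class %in% classes)))
    stop("associated_class outside the task classes: ",
         paste(setdiff(df$associated_class, classes), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$domain_id))
    stop("duplicate domain id(s) in likelihood table", call. = FALSE)
  rownames(df) <- NULL
  structure(df, classes = classes,
            class = c("likelihood_table", "data.frame"))
}

#' @export
print.likelihood_table <- function(x, ...) {
  cat("<likelihood_table> ", nrow(x), " domain(s), classes: ",
      paste(attr(x, "classes"), collapse = " | "), "\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  invisible(x)
}

#' Likelihood matrix of a table
#'
#' @param table A `likelihood_table`.
#' @return Numeric matrix, domains x task classes, of
#'   `p(domain present | class)`.
#' @export
likelihoods <- function(table) {
  stopifnot(inherits(table, "likelihood_table"))
  classes <- attr(table, "classes")
  m <- as.matrix(as.data.frame(table)[, classes, drop = FALSE])
  rownames(m) <- table$domain_id
  m
}

read_nonempty_lines <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines)]
}
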