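# Shared fixtures, all built in code.

# Confusion table from a counts matrix laid out rows = true class,
# cols = predicted class. Exercises the public constructor by expanding to
# per-genome label vectors.
ct_from_counts <- function(counts) {
  classes <- rownames(counts)
  truth <- pred <- character(0L)
  for (t in classes) for (p in classes) {
    k <- counts[t, p]
    truth <- c(truth, rep(t, k))
    pred <- c(pred, rep(p, k))
  }
  ids <- sprintf("g%04d", seq_along(truth))
  confusion_table(stats::setNames(truth, ids), stats::setNames(pred, ids),
                  classes = classes)
}

# Published one-step confusion counts (363 genomes).
table_one_step <- function() {
  ct_from_counts(matrix(
    c(137, 3, 17,
      6, 95, 7,
      43, 21, 34),
    nrow = 3, byrow = TRUE,
    dimnames = list(oxy_classes(), oxy_classes())))
}

# Published two-step confusion counts (362 genomes).
table_two_step <- function() {
  ct_from_counts(matrix(
    c(141, 8, 8,
      8, 96, 4,
      47, 18, 32),
    nrow = 3, byrow = TRUE,
    dimnames = list(oxy_classes(), oxy_classes())))
}

# Independent MCC oracle: MCC is the Pearson phi coefficient of the 0/1
# truth and prediction indicator vectors.
mcc_oracle <- function(bc) {
  truth <- c(rep(1, bc$TP + bc$FN), rep(0, bc$FP + bc$TN))
  pred <- c(rep(1, bc$TP), rep(0, bc$FN), rep(1, bc$FP), rep(0, bc$TN))
  if (stats::sd(truth) == 0 || stats::sd(pred) == 0) return(0)
  stats::cor(truth, pred)
}

# Deterministic tiny matrix with exact planted per-class frequencies:
# 10 genomes per class; domain d1 present in 9/10 aerobes, 1/10 anaerobes,
# 5/10 facultatives; d2 absent everywhere; d3 present everywhere.
exact_freq_fixture <- function() {
  labels <- stats::setNames(rep(oxy_classes(), each = 10L),
                            sprintf("g%02d", 1:30))
  m <- matrix(0L, 30L, 3L,
              dimnames = list(names(labels), c("d1", "d2", "d3")))
  m[1:9, "d1"] <- 1L     # 9/10 aerobes
  m[11, "d1"] <- 1L      # 1/10 anaerobes
  m[21:25, "d1"] <- 1L   # 5/10 facultatives
  m[, "d3"] <- 1L
  list(matrix = m, labels = labels)
}

# Two-class planted fixture: one informative domain at 9/10 vs 1/10 plus
# an uninformative one.
two_class_fixture <- function() {
  labels <- stats::setNames(rep(c("aerobe", "anaerobe"), each = 10L),
                            sprintf("g%02d", 1:20))
  m <- matrix(0L, 20L, 2L,
              dimnames = list(names(labels), c("PF00001", "PF00002")))
  m[c(1:9, 11), "PF00001"] <- 1L
  m[, "PF00002"] <- 1L
  list(matrix = m, labels = labels)
}

# Small likelihood table built directly.
toy_table <- function(p_a, p_b, classes = c("aerobe", "anaerobe"),
                      domains = sprintf("PF%05d", seq_along(p_a))) {
  df <- data.frame(domain_id = domains,
                   associated_class = ifelse(p_a >= p_b, classes[1L],
                                             classes[2L]),
                   stringsAsFactors = FALSE)
  df[[classes[1L]]] <- p_a
  df[[classes[2L]]] <- p_b
  tab <- df
  class(tab) <- c("likelihood_table", "data.frame")
  attr(tab, "classes") <- classes
  tab
}

# hmmscan tblout-style data line for a given model accession.
hmmscan_line <- function(acc, target = "dom", query = "prot_001") {
  paste(target, acc, query, "-", "1.2e-30", "105.3", "0.1",
        "1e-28", "100.1", "0.1", "1.1", "1", "1", "0", "0", "0", "0",
        "description of target")
}

standard_planted_run <- function(seed = 7L) {
  generate_synthetic(synthetic_spec(seed = seed))
}
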