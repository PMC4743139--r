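test_that("single-domain posterior matches the hand computation", {
  tab <- toy_table(0.9, 0.2)
  res <- posterior("PF00001", tab)
  # flat prior: 0.5*0.9 vs 0.5*0.2, normalised
  expect_equal(unname(res$posterior["aerobe"]), 0.45 / 0.55,
               tolerance = 1e-12)
  expect_identical(res$predicted, "aerobe")
  expect_false(res$tie)
  expect_equal(sum(res$posterior), 1, tolerance = 1e-12)
})

test_that("an empty table returns the prior with a tie", {
  empty <- toy_table(numeric(0L), numeric(0L))
  expect_warning(res <- posterior(character(0L), empty), "empty")
  expect_equal(unname(res$posterior), c(0.5, 0.5))
  expect_true(res$tie)
  expect_identical(res$predicted, "aerobe")  # canonical order tie-break
})

test_that("the pseudo-count floors contradictory evidence", {
  tab <- toy_table(1.0, 0.5)
  # domain absent although p(present|aerobe) = 1: factor is PC, not 0
  res <- posterior(character(0L), tab, bayes_params(pseudo_count = 0.1))
  expect_gt(res$posterior["aerobe"], 0)
  expect_equal(unname(res$posterior["aerobe"]), 0.1 / 0.6,
               tolerance = 1e-12)
  # with PC = 0 the contradiction zeroes the class
  res0 <- posterior(character(0L), tab, bayes_params(pseudo_count = 0))
  expect_equal(unname(res0$posterior["aerobe"]), 0)
  expect_identical(res0$predicted, "anaerobe")
})

test_that("with the default pseudo-count no posterior is ever exactly 0", {
  set.seed(21)
  for (i in 1:20) {
    nd <- sample(1:30, 1L)
    tab <- toy_table(sample(c(0, 1, runif(nd)))[1:nd],
                     sample(c(0, 1, runif(nd)))[1:nd])
    profile <- stats::setNames(rbinom(nd, 1L, 0.5), tab$domain_id)
    res <- posterior(profile, tab)
    expect_true(all(res$posterior > 0))
    expect_equal(sum(res$posterior), 1, tolerance = 1e-12)
  }
})

test_that("log-space computation agrees with the direct product", {
  set.seed(31)
  for (i in 1:25) {
    nd <- sample(1:20, 1L)
    p_a <- runif(nd)
    p_b <- runif(nd)
    tab <- toy_table(p_a, p_b)
    x <- rbinom(nd, 1L, 0.5)
    res <- posterior(stats::setNames(x, tab$domain_id), tab)
    clamp <- function(p) pmin(pmax(p, 0.1), 0.9)
    direct <- function(p) 0.5 * prod(ifelse(x == 1, clamp(p),
                                            clamp(1 - p)))
    scores <- c(direct(p_a), direct(p_b))
    expect_equal(unname(res$posterior), scores / sum(scores),
                 tolerance = 1e-9)
  }
})

test_that("posteriors swap exactly under class symmetry", {
  set.seed(41)
  p_a <- runif(12)
  p_b <- runif(12)
  tab <- toy_table(p_a, p_b)
  swapped <- toy_table(p_b, p_a)
  x <- rbinom(12, 1L, 0.5)
  profile <- stats::setNames(x, tab$domain_id)
  r1 <- posterior(profile, tab)
  r2 <- posterior(profile, swapped)
  expect_equal(unname(r1$posterior["aerobe"]),
               unname(r2$posterior["anaerobe"]), tolerance = 1e-12)
})

test_that("posterior is invariant to domain order and ignores unknown
           domains", {
  set.seed(51)
  tab <- toy_table(runif(8), runif(8))
  profile <- c("PF00002", "PF00005", "PF00007", "PF99999")
  r1 <- posterior(profile, tab)
  perm <- sample(nrow(tab))
  tab2 <- tab[perm, ]
  attr(tab2, "classes") <- attr(tab, "classes")
  class(tab2) <- class(tab)
  r2 <- posterior(rev(profile), tab2)
  expect_equal(r1$posterior, r2$posterior, tolerance = 1e-12)
})

test_that("one-step LOOCV recovers planted structure almost perfectly", {
  sim <- standard_planted_run(seed = 7L)
  run <- predict_one_step_loocv(sim$matrix, sim$labels)
  expect_identical(nrow(run), 90L)
  expect_identical(sort(unique(run$true)), oxy_classes())
  acc <- mean(run$predicted == run$true)
  expect_gt(acc, 0.95)
  expect_equal(rowSums(as.matrix(run[, paste0("p_", oxy_classes())])),
               rep(1, nrow(run)), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("identical genomes give empty fold tables and canonical
           tie-breaks", {
  labels <- stats::setNames(rep(oxy_classes(), each = 3L),
                            sprintf("g%02d", 1:9))
  m <- matrix(1L, 9L, 4L,
              dimnames = list(names(labels), sprintf("PF%05d", 1:4)))
  run <- predict_one_step_loocv(m, labels)
  expect_true(all(run$predicted == "aerobe"))
  expect_true(all(run$tie))
  expect_true(all(run$n_domains == 0L))
})

test_that("LOOCV predictions are invariant to genome order", {
  sim <- generate_synthetic(synthetic_spec(
    class_sizes = c(aerobe = 8L, anaerobe = 8L, facultative = 8L),
    n_associated = 10L, n_background = 20L, seed = 17L))
  run1 <- predict_one_step_loocv(sim$matrix, sim$labels)
  set.seed(61)
  m2 <- sim$matrix[sample(nrow(sim$matrix)), ]
  run2 <- predict_one_step_loocv(m2, sim$labels)
  i <- match(run1$genome_id, run2$genome_id)
  expect_identical(run1$predicted, run2$predicted[i])
  expect_equal(run1$p_aerobe, run2$p_aerobe[i], tolerance = 1e-12)
})

test_that("each LOOCV fold is equivalent to training without the held-out
           genome", {
  sim <- generate_synthetic(synthetic_spec(
    class_sizes = c(aerobe = 6L, anaerobe = 6L, facultative = 6L),
    n_associated = 8L, n_background = 10L, seed = 19L))
  run <- predict_one_step_loocv(sim$matrix, sim$labels)
  for (g in sim$matrix |> rownames() |> head(4L)) {
    keep <- setdiff(rownames(sim$matrix), g)
    tab <- suppressWarnings(select_class_associated_domains(
      sim$matrix[keep, , drop = FALSE], sim$labels[keep]))
    profile <- colnames(sim$matrix)[sim$matrix[g, ] == 1L]
    res <- suppressWarnings(posterior(profile, tab))
    row <- run[run$genome_id == g, ]
    expect_equal(unname(res$posterior),
                 as.numeric(row[paste0("p_", oxy_classes())]),
                 tolerance = 1e-12)
    expect_identical(res$predicted, row$predicted)
  }
})

test_that("two-step LOOCV recovers planted structure and respects the
           network topology", {
  sim <- standard_planted_run(seed = 7L)
  run <- predict_two_step_loocv(sim$matrix, sim$labels)
  expect_identical(nrow(run), 90L)
  expect_gt(mean(run$predicted == run$true), 0.95)
  # genomes decided anaerobe at step 1 carry no step-2 posterior
  an1 <- run$step1_predicted == "anaerobe"
  expect_true(any(an1))
  expect_true(all(is.na(run$step2_p_aerobe[an1])))
  expect_true(all(run$predicted[an1] == "anaerobe"))
  expect_true(all(!is.na(run$step2_p_aerobe[!an1])))
  expect_true(all(run$predicted[!an1] %in% c("aerobe", "facultative")))
  # step-1 dichotomy at least as accurate as the one-step anaerobe-vs-rest
  one <- predict_one_step_loocv(sim$matrix, sim$labels)
  s1_acc <- mean((run$step1_predicted == "anaerobe") ==
                   (run$true == "anaerobe"))
  one_acc <- mean((one$predicted == "anaerobe") == (one$true == "anaerobe"))
  expect_gte(s1_acc, one_acc)
})

test_that("the respiration dichotomy equals the aerobe/anaerobe dichotomy
           when only those classes are present", {
  sim <- generate_synthetic(synthetic_spec(
    class_sizes = c(aerobe = 10L, anaerobe = 10L),
    n_associated = 10L, n_background = 20L, seed = 23L))
  r1 <- predict_loocv(sim$matrix, sim$labels, scheme_respiration())
  r2 <- predict_loocv(sim$matrix, sim$labels, scheme_aa_only())
  i <- match(r1$genome_id, r2$genome_id)
  expect_identical(ifelse(r1$predicted == "respiring", "aerobe",
                          "anaerobe"),
                   r2$predicted[i])
  expect_equal(r1$p_respiring, r2$p_aerobe[i], tolerance = 1e-12)
})

test_that("a fold that empties a class is an error", {
  labels <- stats::setNames(c(rep("aerobe", 2L), rep("anaerobe", 5L)),
                            sprintf("g%02d", 1:7))
  m <- matrix(rbinom(7 * 4, 1L, 0.5), 7L, 4L,
              dimnames = list(names(labels), sprintf("PF%05d", 1:4)))
  expect_error(predict_loocv(m, labels, scheme_aa_only()), "< 2 members")
})

test_that("train + classify recover a planted profile end to end", {
  sim <- standard_planted_run(seed = 29L)
  model <- train(sim$matrix, sim$labels, mode = "two-step")
  expect_gt(nrow(model$tables$step1), 0L)
  expect_gt(nrow(model$tables$step2), 0L)
  # fresh profiles drawn from each class signature
  for (cl in oxy_classes()) {
    present <- sim$truth$domain_id[sim$truth$class == cl]
    res <- classify(present, model)
    expect_identical(res$predicted, cl)
  }
  # the empty profile still yields a normalised posterior
  res0 <- classify(character(0L), model)
  expect_equal(sum(res0$posterior), 1, tolerance = 1e-12)
  # missing step-2 table is a configuration error for respiring profiles
  broken <- model
  broken$tables$step2 <- NULL
  expect_error(classify(sim$truth$domain_id[1L], broken), "step-2")
})

test_that("one-step and aa-only models round-trip through write_model /
           read_model", {
  sim <- standard_planted_run(seed = 29L)
  model <- train(sim$matrix, sim$labels, mode = "two-step")
  d <- withr::local_tempdir()
  write_model(model, d)
  back <- read_model(d)
  expect_identical(back$mode, "two-step")
  profile <- sim$truth$domain_id[sim$truth$class == "facultative"]
  expect_equal(classify(profile, back)$posterior,
               classify(profile, model)$posterior, tolerance = 1e-12)
})
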