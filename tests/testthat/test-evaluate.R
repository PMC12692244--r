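test_that("confusion counts are exact on hand-checked cases", {
  cc <- confusion_counts(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  pc <- cc$per_class
  expect_equal(pc$TP, c(1, 1))
  expect_equal(pc$FN[pc$class == "A"], 1)
  expect_equal(pc$FP[pc$class == "B"], 1)
  expect_equal(pc$TP + pc$FP + pc$FN + pc$TN, c(3, 3))
  expect_equal(rowSums(cc$matrix), c(A = 2, B = 1))
  expect_error(confusion_counts(c("A"), c("A", "B"), c("A", "B")), "length")

  perfect <- confusion_counts(c("x", "y", "z"), c("x", "y", "z"))
  expect_equal(sum(perfect$matrix) - sum(diag(perfect$matrix)), 0)
  m <- classification_metrics(perfect)
  expect_equal(m$accuracy, 1)
  expect_equal(unname(m$macro), c(1, 1, 1))
})

test_that("metrics reproduce the hand-worked 2x2 alternating case", {
  m <- classification_metrics(
    confusion_counts(c("A", "A", "B", "B"), c("A", "B", "A", "B"), c("A", "B")))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$per_class$precision, c(0.5, 0.5))
  expect_equal(m$per_class$recall, c(0.5, 0.5))
  expect_equal(m$per_class$f1, c(0.5, 0.5))
})

test_that("metrics agree with the brute-force oracle on random instances", {
  withr::with_seed(123, {
    for (i in 1:100) {
      K <- sample(2:5, 1)
      classes <- LETTERS[1:K]
      n <- sample(5:60, 1)
      truth <- sample(classes, n, replace = TRUE)
      pred <- sample(classes, n, replace = TRUE)
      got <- classification_metrics(confusion_counts(truth, pred, classes))
      want <- brute_metrics(truth, pred, classes)
      expect_equal(got$accuracy, want$accuracy)
      expect_equal(got$per_class$precision, unname(want$precision))
      expect_equal(got$per_class$recall, unname(want$recall))
      expect_equal(got$per_class$f1, unname(want$f1))
      expect_equal(unname(got$macro["f1"]), mean(want$f1))
    }
  })
})

test_that("degenerate classes are zeroed and flagged", {
  m <- classification_metrics(
    confusion_counts(c("A", "A", "B"), c("A", "A", "A"), c("A", "B")))
  expect_equal(m$per_class$recall[m$per_class$class == "B"], 0)
  expect_true("B" %in% m$flagged)
})

test_that("sliced evaluation is consistent with its pooled counterpart", {
  cfg <- tiny_sim_config(n_eggs = 8L, scans = 1L, n_bands = 30L, seed = 31)
  tab <- snv_table(simulate_dataset(cfg))
  sp <- stratified_egg_split(tab, 0.25, seed = 2)
  tr <- st_subset(tab, tab$egg_id %in% sp$train_eggs)
  te <- st_subset(tab, tab$egg_id %in% sp$test_eggs)
  bands <- seq(2, 30, length.out = 7)
  net <- build_network(tiny_model_config(), "mt_ctse", seed = 1)
  net <- fit_network(net, tr, bands,
                     train_config(epochs = 8, seed = 1, batch_size = 16))
  ev <- evaluate_sliced(net, te, "by_day")
  expect_named(ev$slices, as.character(sort(unique(te$day))))
  ns <- vapply(ev$slices, `[[`, 0, "n")
  accs <- vapply(ev$slices, `[[`, 0, "accuracy")
  # pooled accuracy = scan-count-weighted mean of slice accuracies
  expect_equal(ev$pooled$accuracy, sum(ns * accs) / sum(ns))
  ev2 <- evaluate_sliced(net, te, "by_variety")
  expect_named(ev2$slices, sort(unique(te$variety)))
  st <- build_network(tiny_model_config(), "st_ctse_task1", seed = 1)
  st <- fit_network(st, tr, bands,
                    train_config(epochs = 4, seed = 1, batch_size = 16))
  expect_error(evaluate_sliced(st, te, "by_variety"), "head")
})

test_that("run comparison tables aggregate mean and sd over seeds", {
  fake_eval <- function(acc) {
    rep_ <- function(a) {
      structure(list(accuracy = a, macro = c(precision = a, recall = a, f1 = a),
                     n = 10), class = "eval_report")
    }
    list(pooled = rep_(acc), slices = list(`1` = rep_(acc), `40` = rep_(acc + 0.1)))
  }
  runs <- list(
    list(variant = "mt_ctse", seed = 1, eval = fake_eval(0.8)),
    list(variant = "mt_ctse", seed = 2, eval = fake_eval(0.9)),
    list(variant = "mt_transformer", seed = 1, eval = fake_eval(0.7)))
  cmp <- compare_runs(runs)
  expect_equal(nrow(cmp$per_run), 9)
  row <- cmp$summary[cmp$summary$variant == "mt_ctse" &
                       cmp$summary$slice == "pooled", ]
  expect_equal(row$accuracy_mean, 0.85)
  expect_equal(row$accuracy_sd, sd(c(0.8, 0.9)))
  expect_equal(row$n_seeds, 2)
  # comparing a run with itself: zero sd
  cmp2 <- compare_runs(list(runs[[1]], runs[[1]]))
  expect_true(all(cmp2$summary$accuracy_sd == 0))
})
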